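# Brute-force graph oracles, independent of the package implementation
# (and of igraph): plain matrix / loop computations.

# Floyd-Warshall hop distances on a binary adjacency matrix.
oracle_distances <- function(adj) {
  n <- nrow(adj)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[adj == 1] <- 1
  for (k in seq_len(n)) {
    d <- pmin(d, outer(d[, k], d[k, ], "+"))
  }
  d
}

oracle_distance_metrics <- function(adj) {
  n <- nrow(adj)
  d <- oracle_distances(adj)
  off <- d[upper.tri(d)]
  eff <- if (n < 2) 0 else mean(ifelse(is.finite(off), 1 / off, 0))
  # component membership by reachability
  memb <- integer(n)
  comp <- 0L
  for (i in seq_len(n)) {
    if (memb[i] == 0L) {
      comp <- comp + 1L
      memb[is.finite(d[i, ])] <- comp
    }
  }
  sizes <- tabulate(memb)
  keep <- which(memb == which.max(sizes))
  dl <- d[keep, keep, drop = FALSE]
  if (length(keep) < 2) {
    return(list(path_length = NA_real_, radius = NA_real_,
                diameter = NA_real_, global_efficiency = eff,
                disconnected = max(memb) > 1L || sum(adj) == 0))
  }
  ecc <- apply(dl, 1, max)
  list(path_length = mean(dl[upper.tri(dl)]), radius = min(ecc),
       diameter = max(ecc), global_efficiency = eff,
       disconnected = comp > 1L)
}

# Exhaustive triangle counting per node.
oracle_clustering <- function(adj) {
  n <- nrow(adj)
  if (n == 0 || sum(adj) == 0) return(0)
  local <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(adj[i, ] == 1)
    k <- length(nb)
    if (k < 2) { local[i] <- 0; next }
    tri <- 0
    for (a in seq_len(k - 1)) for (b in (a + 1):k) {
      tri <- tri + adj[nb[a], nb[b]]
    }
    local[i] <- tri / (k * (k - 1) / 2)
  }
  mean(local)
}

# Pearson correlation over edge endpoint degrees, both orientations.
oracle_assortativity <- function(adj) {
  deg <- rowSums(adj)
  el <- which(upper.tri(adj) & adj == 1, arr.ind = TRUE)
  if (nrow(el) < 2) return(NA_real_)
  x <- c(deg[el[, 1]], deg[el[, 2]])
  y <- c(deg[el[, 2]], deg[el[, 1]])
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

# Newman modularity of a given partition.
oracle_modularity_q <- function(adj, membership) {
  m2 <- sum(adj)              # 2m
  if (m2 == 0) return(NA_real_)
  deg <- rowSums(adj)
  q <- 0
  for (i in seq_len(nrow(adj))) for (j in seq_len(nrow(adj))) {
    if (membership[i] == membership[j]) {
      q <- q + adj[i, j] - deg[i] * deg[j] / m2
    }
  }
  q / m2
}

# All set partitions of n elements (restricted growth strings).
oracle_all_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) {
      out[[length(out) + 1L]] <<- prefix
      return()
    }
    for (v in seq_len(mx + 1L)) rec(c(prefix, v), max(mx, v))
  }
  rec(integer(0), 0L)
  out
}

# Maximum modularity over all partitions (tiny n only).
oracle_max_modularity <- function(adj) {
  parts <- oracle_all_partitions(nrow(adj))
  max(vapply(parts, function(p) oracle_modularity_q(adj, p), 0))
}

# Adjacency matrix from an integer bitmask over the upper triangle.
adj_from_mask <- function(n, mask) {
  adj <- matrix(0L, n, n)
  pairs <- which(upper.tri(adj), arr.ind = TRUE)
  bits <- as.integer(intToBits(mask))[seq_len(nrow(pairs))]
  adj[pairs[bits == 1L, , drop = FALSE]] <- 1L
  adj + t(adj)
}

random_adjacency <- function(n, p = 0.5) {
  adj <- matrix(0L, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- stats::rbinom(sum(ut), 1L, p)
  adj + t(adj)
}

# Exhaustive concordant/discordant pair counting AUC with half-credit ties.
oracle_pair_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
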