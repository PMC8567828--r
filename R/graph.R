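#' Build a brain graph from a band iCoh matrix
#'
#' Edge weights are `|iCoh|` (the sign of iCoh encodes lead/lag, the
#' magnitude coupling strength). The binary adjacency is obtained either by
#' an absolute cutoff (edge iff weight >= tau) or proportionally (the top k%
#' strongest node pairs).
#'
#' @param band_icoh square matrix of iCoh values (signed allowed; magnitudes
#'   are taken). `NA` entries are treated as absent (weight 0).
#' @param threshold_rule `list(mode = "absolute"|"proportional", value = )`:
#'   cutoff tau for `"absolute"` (default 0.1) or the retained fraction of
#'   pairs for `"proportional"`.
#' @return object of class `brain_graph`: `nodes`, `weights` (symmetric,
#'   nonnegative, zero diagonal), `adjacency` (binary), `threshold_rule`.
#'   A threshold leaving no edge yields an empty graph with attribute
#'   `"empty" = TRUE`.
#' @export
build_graph <- function(band_icoh,
                        threshold_rule = list(mode = "absolute", value = 0.1)) {
  w <- abs(as.matrix(band_icoh))
  if (nrow(w) != ncol(w)) stop("band iCoh matrix must be square")
  w[is.na(w)] <- 0
  w <- (w + t(w)) / 2
  diag(w) <- 0
  n <- nrow(w)
  nodes <- rownames(w)
  if (is.null(nodes)) nodes <- paste0("n", seq_len(n))
  ut <- upper.tri(w)
  adj <- matrix(0L, n, n)
  if (threshold_rule$mode == "absolute") {
    adj[ut] <- as.integer(w[ut] >= threshold_rule$value & w[ut] > 0)
  } else if (threshold_rule$mode == "proportional") {
    k <- ceiling(threshold_rule$value * sum(ut))
    ord <- order(w[ut], decreasing = TRUE)
    sel <- ord[seq_len(min(k, sum(w[ut] > 0)))]
    v <- integer(sum(ut)); v[sel] <- 1L
    adj[ut] <- v
  } else stop("unknown threshold mode: ", threshold_rule$mode)
  adj <- adj + t(adj)
  dimnames(adj) <- dimnames(w) <- list(nodes, nodes)
  g <- structure(list(nodes = nodes, weights = w, adjacency = adj,
                      threshold_rule = threshold_rule),
                 class = "brain_graph")
  attr(g, "empty") <- sum(adj) == 0
  g
}

as_igraph <- function(graph) {
  igraph::graph_from_adjacency_matrix(graph$adjacency, mode = "undirected")
}

#' Hop-distance metrics of a brain graph
#'
#' Breadth-first shortest-path distances in edge hops.
#' Characteristic path length is the mean distance over connected node
#' pairs; eccentricity is a node's greatest distance to any reachable node;
#' radius and diameter are the minimum and maximum eccentricity. Global
#' efficiency is the mean of `1/d` over all pairs with `1/Inf = 0`, computed
#' on the full graph. On a disconnected graph the distance statistics are
#' computed on the largest connected component (flagged via `disconnected`).
#'
#' @param graph a `brain_graph`.
#' @return list: `path_length`, `radius`, `diameter`, `global_efficiency`,
#'   `disconnected`.
#' @export
distance_metrics <- function(graph) {
  n <- length(graph$nodes)
  if (n < 2L || sum(graph$adjacency) == 0)
    return(list(path_length = NA_real_, radius = NA_real_,
                diameter = NA_real_, global_efficiency = 0,
                disconnected = TRUE))
  g <- as_igraph(graph)
  d <- igraph::distances(g)
  off <- d[upper.tri(d)]
  efficiency <- mean(ifelse(is.finite(off), 1 / off, 0))
  comp <- igraph::components(g)
  disconnected <- comp$no > 1L
  if (disconnected) {
    keep <- which(comp$membership == which.max(comp$csize))
    d <- d[keep, keep, drop = FALSE]
  }
  off_c <- d[upper.tri(d)]
  ecc <- apply(d, 1, max)
  list(path_length = mean(off_c), radius = min(ecc), diameter = max(ecc),
       global_efficiency = efficiency, disconnected = disconnected)
}

#' Average local clustering coefficient
#'
#' Per node: closed triangles over possible neighbor pairs, 0 for degree < 2;
#' averaged over all nodes. An empty graph scores 0.
#'
#' @param graph a `brain_graph`.
#' @return scalar in \[0, 1\].
#' @export
clustering_coefficient <- function(graph) {
  n <- length(graph$nodes)
  if (n == 0L) return(0)
  if (sum(graph$adjacency) == 0) return(0)
  g <- as_igraph(graph)
  local <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  mean(local)
}

#' Newman modularity via the Louvain method
#'
#' Community partition by multilevel (Louvain) optimization under a fixed
#' seed, with the modularity Q of that partition.
#'
#' @param graph a `brain_graph` with at least one edge.
#' @param seed RNG seed for the (stochastic) Louvain sweep.
#' @return list: `Q`, `membership` (integer community per node).
#' @export
graph_modularity <- function(graph, seed = 1L) {
  if (sum(graph$adjacency) == 0) stop("modularity requires at least one edge")
  g <- as_igraph(graph)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  cl <- igraph::cluster_louvain(g)
  list(Q = igraph::modularity(g, igraph::membership(cl)),
       membership = as.integer(igraph::membership(cl)))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Degree assortativity
#'
#' Pearson correlation of the degrees at the two endpoints of each edge
#' (Newman's formula). Undefined when all degrees are equal (zero variance);
#' returned as `NA` and excluded downstream.
#'
#' @param graph a `brain_graph`.
#' @return scalar in \[-1, 1\] or `NA`.
#' @export
assortativity_coefficient <- function(graph) {
  m <- sum(graph$adjacency) / 2
  if (m < 2) return(NA_real_)
  deg <- rowSums(graph$adjacency)
  if (stats::var(deg[deg > 0]) == 0 || length(unique(deg)) == 1L) {
    # check endpoint-degree variance over edges
    el <- which(upper.tri(graph$adjacency) & graph$adjacency == 1L, arr.ind = TRUE)
    if (stats::var(c(deg[el[, 1]], deg[el[, 2]])) == 0) return(NA_real_)
  }
  r <- suppressWarnings(igraph::assortativity_degree(as_igraph(graph)))
  if (is.nan(r)) NA_real_ else r
}

#' Density and mean coherence
#'
#' Density defaults to the standard normalization `m / (n(n-1)/2)`; the
#' literal edges-per-node variant `m / n` is selectable. Mean coherence is
#' the mean magnitude of the raw band iCoh over all off-diagonal pairs,
#' independent of thresholding.
#'
#' @param graph a `brain_graph`.
#' @param band_icoh raw band iCoh matrix the graph was built from (defaults
#'   to the stored weights).
#' @param density_variant `"standard"` (default) or `"per_node"`.
#' @return list: `density`, `mean_coherence`.
#' @export
density_and_mean_coherence <- function(graph, band_icoh = graph$weights,
                                       density_variant = c("standard", "per_node")) {
  density_variant <- match.arg(density_variant)
  n <- length(graph$nodes)
  if (n < 2L) stop("density requires at least 2 nodes")
  m <- sum(graph$adjacency) / 2
  dens <- if (density_variant == "standard") m / (n * (n - 1) / 2) else m / n
  w <- abs(as.matrix(band_icoh))
  mc <- mean(w[upper.tri(w)], na.rm = TRUE)
  list(density = dens, mean_coherence = mc)
}

#' All graph metrics of one band matrix
#'
#' Builds the thresholded graph and evaluates the network measures:
#' clustering, global efficiency, path length, radius, diameter, modularity,
#' density, mean coherence, plus degree assortativity (not part of the
#' default feature set).
#'
#' @param band_icoh square band iCoh matrix (signed).
#' @param threshold_rule see [build_graph()].
#' @param seed Louvain seed.
#' @param density_variant see [density_and_mean_coherence()].
#' @return named numeric vector of 9 metrics (NA where undefined).
#' @export
graph_metrics <- function(band_icoh,
                          threshold_rule = list(mode = "absolute", value = 0.1),
                          seed = 1L,
                          density_variant = "standard") {
  g <- build_graph(band_icoh, threshold_rule)
  dm <- distance_metrics(g)
  q <- if (sum(g$adjacency) > 0) graph_modularity(g, seed)$Q else NA_real_
  dc <- density_and_mean_coherence(g, band_icoh, density_variant)
  c(clustering = clustering_coefficient(g),
    global_efficiency = dm$global_efficiency,
    path_length = dm$path_length,
    radius = dm$radius,
    diameter = dm$diameter,
    modularity = q,
    density = dc$density,
    mean_coherence = dc$mean_coherence,
    assortativity = assortativity_coefficient(g))
}

#' Stimulation-induced 48-dimensional feature vector
#'
#' For each of the six bands, builds graphs for the baseline and analysis
#' windows, computes the eight feature metrics in each, and emits the
#' post-minus-pre change per metric: 48 values named `<metric>_<band>`.
#'
#' @param pre,post `band_coherence` objects for the baseline and analysis
#'   windows.
#' @param threshold_rule see [build_graph()].
#' @param seed Louvain seed.
#' @return named numeric vector of length 48 (missing metrics propagate as
#'   `NA`).
#' @export
compute_feature_vector <- function(pre, post,
                                   threshold_rule = list(mode = "absolute", value = 0.1),
                                   seed = 1L) {
  stopifnot(inherits(pre, "band_coherence"), inherits(post, "band_coherence"))
  band_names <- names(eeg_bands())
  if (!all(band_names %in% names(pre$bands)) ||
      !all(band_names %in% names(post$bands)))
    stop("all six bands must be present in both windows")
  metrics <- feature_metrics()
  out <- numeric(0)
  for (b in band_names) {
    mp <- graph_metrics(pre$icoh[, , b], threshold_rule, seed)[metrics]
    ma <- graph_metrics(post$icoh[, , b], threshold_rule, seed)[metrics]
    d <- ma - mp
    names(d) <- paste(metrics, b, sep = "_")
    out <- c(out, d)
  }
  out[feature_names()]
}
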