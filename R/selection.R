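#' Remove collinear features
#'
#' Iteratively finds the pair of features with the highest absolute Pearson
#' correlation at or above the threshold and drops the member with the
#' higher mean absolute correlation with all other features, until no pair
#' exceeds the threshold. Constant columns (undefined correlation) are
#' dropped first.
#'
#' @param features data.frame or matrix of numeric feature columns.
#' @param r_threshold correlation cutoff (default 0.8).
#' @return list: `features` (reduced), `removed` (character, in removal
#'   order), `constant` (constant columns dropped up front).
#' @export
remove_collinear <- function(features, r_threshold = 0.8) {
  x <- as.matrix(features)
  stopifnot(ncol(x) >= 1L, nrow(x) >= 3L)
  sds <- apply(x, 2, stats::sd)
  constant <- colnames(x)[sds == 0 | is.na(sds)]
  x <- x[, sds > 0 & !is.na(sds), drop = FALSE]
  removed <- character(0)
  while (ncol(x) >= 2L) {
    r <- abs(stats::cor(x))
    diag(r) <- 0
    if (max(r) < r_threshold) break
    idx <- which(r == max(r), arr.ind = TRUE)[1, ]
    mean_abs <- rowMeans(r) * ncol(x) / (ncol(x) - 1)  # exclude self (0 on diag)
    drop_i <- idx[which.max(mean_abs[idx])]
    removed <- c(removed, colnames(x)[drop_i])
    x <- x[, -drop_i, drop = FALSE]
  }
  list(features = as.data.frame(x), removed = removed, constant = constant)
}

#' Univariate feature filter
#'
#' Classification mode: per-feature dependent t test between conditions
#' (rows paired by participant); features with `|t|` below the threshold
#' (default 1) are removed. Regression mode: per-feature Pearson correlation
#' with a continuous target; features with `|r|` below the threshold
#' (default 0.1) are removed.
#'
#' @param features numeric data.frame/matrix.
#' @param target condition labels (`paired_t`) or numeric target
#'   (`pearson_r`).
#' @param mode `"paired_t"` or `"pearson_r"`.
#' @param threshold statistic cutoff; kept when `|stat| >= threshold`.
#' @param participant participant ids aligning rows (required for
#'   `paired_t`).
#' @return list: `features` (reduced), `removed`, `stats` (named statistic
#'   per input feature).
#' @export
univariate_filter <- function(features, target,
                              mode = c("paired_t", "pearson_r"),
                              threshold = if (match.arg(mode) == "paired_t") 1 else 0.1,
                              participant = NULL) {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  if (mode == "paired_t") {
    stopifnot(!is.null(participant))
    conds <- sort(unique(as.character(target)))
    if (length(conds) != 2L) stop("paired_t mode needs exactly 2 conditions")
    ia <- target == conds[1]; ib <- target == conds[2]
    pa <- participant[ia]; pb <- participant[ib]
    if (!setequal(pa, pb)) stop("conditions are not paired by participant")
    ord_b <- match(pa, pb)
    if (sum(ia) < 3L) stop("too few pairs for a paired t statistic")
    stats_v <- apply(x, 2, function(col) {
      d <- col[ia] - col[ib][ord_b]
      if (stats::sd(d) == 0) return(0)
      mean(d) / (stats::sd(d) / sqrt(length(d)))
    })
  } else {
    y <- as.numeric(target)
    if (length(y) != nrow(x)) stop("target length mismatch")
    if (nrow(x) < 4L) stop("too few rows for a correlation statistic")
    stats_v <- apply(x, 2, function(col) {
      if (stats::sd(col) == 0) return(0)
      stats::cor(col, y)
    })
  }
  keep <- abs(stats_v) >= threshold
  list(features = as.data.frame(x[, keep, drop = FALSE]),
       removed = colnames(x)[!keep], stats = stats_v)
}

#' Shadow-feature random-forest selection
#'
#' All-relevant feature selection: at each iteration every feature is paired
#' with a "shadow" copy whose values are permuted across rows, a random
#' forest is fit on the real-plus-shadow design, and permutation importance
#' is expressed as a Z score. A real feature scores a hit when its Z exceeds
#' the iteration's maximum shadow Z. After all iterations, features whose
#' hit counts are significantly above the Binomial(n, 1/2) null (two-sided
#' test at `alpha`) are confirmed, significantly below are rejected, and the
#' rest remain tentative.
#'
#' @param features numeric data.frame/matrix (>= 2 columns).
#' @param target factor/labels (`task = "classify"`) or numeric
#'   (`task = "regress"`).
#' @param task `"classify"` or `"regress"`.
#' @param n_iterations shadow permutation rounds (default 100).
#' @param n_trees trees per forest (default 500).
#' @param alpha two-sided binomial significance level (default 0.05).
#' @param seed RNG seed; fixes permutations and forests.
#' @return list of class `selection_result`: `confirmed`, `rejected`,
#'   `tentative` (character), `hits` (named counts), `n_iterations`,
#'   `importance_history` (iterations x features matrix of Z scores, plus a
#'   `shadow_max` column), `top_feature` (highest mean Z among confirmed,
#'   else among all).
#' @export
boruta_select <- function(features, target, task = c("classify", "regress"),
                          n_iterations = 100L, n_trees = 500L,
                          alpha = 0.05, seed = 1L) {
  task <- match.arg(task)
  x <- as.matrix(features)
  stopifnot(ncol(x) >= 2L)
  if (task == "classify") {
    y <- factor(target)
    if (nlevels(y) < 2L) stop("degenerate target: single class")
  } else {
    y <- as.numeric(target)
    if (stats::sd(y) == 0) stop("degenerate target: zero variance")
  }
  p <- ncol(x)
  fnames <- colnames(x)
  if (is.null(fnames)) fnames <- paste0("f", seq_len(p))
  set.seed(seed)
  hist <- matrix(NA_real_, n_iterations, p + 1L,
                 dimnames = list(NULL, c(fnames, "shadow_max")))
  hits <- stats::setNames(integer(p), fnames)
  for (it in seq_len(n_iterations)) {
    shadow <- apply(x, 2, sample)
    design <- cbind(x, shadow)
    colnames(design) <- c(fnames, paste0("shadow_", fnames))
    rf <- randomForest::randomForest(design, y, ntree = n_trees,
                                     importance = TRUE)
    z <- randomForest::importance(rf, type = 1, scale = TRUE)[, 1]
    z[!is.finite(z)] <- 0
    z_real <- z[seq_len(p)]
    z_sh_max <- max(z[(p + 1L):(2L * p)])
    hits <- hits + as.integer(z_real > z_sh_max)
    hist[it, ] <- c(z_real, z_sh_max)
  }
  p_two <- vapply(hits, function(h) {
    stats::binom.test(h, n_iterations, 0.5)$p.value
  }, 0)
  confirmed <- fnames[p_two < alpha & hits > n_iterations / 2]
  rejected <- fnames[p_two < alpha & hits < n_iterations / 2]
  tentative <- setdiff(fnames, c(confirmed, rejected))
  mean_z <- colMeans(hist[, seq_len(p), drop = FALSE])
  top_pool <- if (length(confirmed) > 0) confirmed else fnames
  top_feature <- top_pool[which.max(mean_z[top_pool])]
  structure(
    list(confirmed = confirmed, rejected = rejected, tentative = tentative,
         hits = hits, n_iterations = n_iterations,
         importance_history = hist, top_feature = top_feature),
    class = "selection_result"
  )
}

#' Repeated random-split folds with coverage guarantee
#'
#' Each fold holds out 1-3 participants drawn at random; the set of folds is
#' resampled (bounded retries) until every participant appears in at least
#' one holdout.
#'
#' @param participants vector of participant ids (>= 4).
#' @param n_folds number of folds (default 35).
#' @param holdout_sizes candidate holdout sizes (default `1:3`).
#' @param seed RNG seed.
#' @param max_retries resampling bound for the coverage guarantee.
#' @return list of class `fold_spec`: `holdouts` (list of id vectors),
#'   `n_folds`, `seed`.
#' @export
make_folds <- function(participants, n_folds = 35L, holdout_sizes = 1:3,
                       seed = 1L, max_retries = 100L) {
  participants <- unique(participants)
  stopifnot(length(participants) >= 4L)
  set.seed(seed)
  for (try in seq_len(max_retries)) {
    sizes <- holdout_sizes[sample.int(length(holdout_sizes), n_folds,
                                      replace = TRUE)]
    holdouts <- lapply(sizes, function(k)
      participants[sample.int(length(participants), k)])
    if (setequal(unique(unlist(holdouts)), participants)) {
      return(structure(list(holdouts = holdouts, n_folds = n_folds,
                            seed = seed),
                       class = "fold_spec"))
    }
  }
  stop("could not cover every participant within the retry bound")
}

#' Fit a model on training data and score held-out data
#'
#' Features are standardized with training statistics only. Models:
#' `logistic` (binomial GLM), `ridge_logistic` (L2 penalty, lambda chosen by
#' inner k-fold cross-validation over a 20-point log grid 1e-3..1e3),
#' `linear` (OLS), `ridge_linear`. The ridge lambda follows the parsimony
#' (`lambda.1se`) rule by default: at the sample sizes this stage is built
#' for, the inner CV curve is noisy and the one-standard-error rule guards
#' against the slope over-confidence that selection-then-fit induces.
#'
#' @param x_train,x_test numeric matrices/data.frames with identical columns.
#' @param y_train labels (classification: 2 levels) or numeric target.
#' @param model one of `"logistic"`, `"ridge_logistic"`, `"linear"`,
#'   `"ridge_linear"`.
#' @param seed seed for the inner CV fold assignment.
#' @param inner_folds inner CV folds for the ridge lambda (default 5).
#' @param ridge_s which CV lambda to use: `"lambda.1se"` (default) or
#'   `"lambda.min"`.
#' @return numeric vector: class-1 probabilities (classification) or
#'   predictions (regression) for the rows of `x_test`.
#' @export
fit_predict <- function(x_train, y_train, x_test,
                        model = c("logistic", "ridge_logistic", "linear",
                                  "ridge_linear"),
                        seed = 1L, inner_folds = 5L,
                        ridge_s = c("lambda.1se", "lambda.min")) {
  model <- match.arg(model)
  x_train <- as.matrix(x_train); x_test <- as.matrix(x_test)
  stopifnot(identical(colnames(x_train), colnames(x_test)))
  mu <- colMeans(x_train)
  sdv <- apply(x_train, 2, stats::sd)
  sdv[sdv == 0] <- 1
  x_tr <- sweep(sweep(x_train, 2, mu), 2, sdv, "/")
  x_te <- sweep(sweep(x_test, 2, mu), 2, sdv, "/")
  classify <- model %in% c("logistic", "ridge_logistic")
  if (classify) {
    y <- factor(y_train)
    if (nlevels(y) != 2L) stop("classification requires exactly 2 classes")
    y_num <- as.integer(y) - 1L
  } else {
    y_num <- as.numeric(y_train)
  }
  if (model == "logistic") {
    df_tr <- as.data.frame(x_tr)
    fit <- suppressWarnings(
      stats::glm(y_num ~ ., data = cbind(df_tr, y_num = y_num),
                 family = stats::binomial()))
    p <- suppressWarnings(
      stats::predict(fit, newdata = as.data.frame(x_te), type = "response"))
    return(unname(p))
  }
  if (model == "linear") {
    df_tr <- as.data.frame(x_tr)
    fit <- stats::lm(y_num ~ ., data = cbind(df_tr, y_num = y_num))
    if (anyNA(stats::coef(fit)))
      warning("singular design in unregularized fit; rank-deficient columns dropped")
    return(unname(stats::predict(fit, newdata = as.data.frame(x_te))))
  }
  # ridge models via glmnet (pad a zero column: glmnet needs >= 2 columns)
  pad <- ncol(x_tr) < 2L
  if (pad) {
    x_tr <- cbind(x_tr, .pad = 0)
    x_te <- cbind(x_te, .pad = 0)
  }
  lambda_grid <- 10^seq(3, -3, length.out = 20)
  fam <- if (classify) "binomial" else "gaussian"
  set.seed(seed)
  nf <- min(inner_folds, nrow(x_tr))
  foldid <- sample(rep_len(seq_len(nf), nrow(x_tr)))
  ridge_s <- match.arg(ridge_s)
  cv <- glmnet::cv.glmnet(x_tr, y_num, alpha = 0, lambda = lambda_grid,
                          family = fam, foldid = foldid,
                          standardize = FALSE)
  p <- stats::predict(cv, newx = x_te, s = ridge_s, type = "response")
  unname(as.numeric(p))
}

#' AUC of a score vector against binary labels
#'
#' Rank-statistic (Mann-Whitney) AUC with half credit for ties; identical to
#' the trapezoidal area under the empirical ROC.
#'
#' @param scores numeric scores (higher = more class-1).
#' @param labels binary labels (0/1, logical, or 2-level factor).
#' @return AUC in \[0, 1\].
#' @export
auc_from_scores <- function(scores, labels) {
  y <- as.integer(as.factor(labels)) - 1L
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  stopifnot(n1 > 0, n0 > 0)
  r <- rank(scores)
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate out-of-fold classification scores
#'
#' AUC of the concatenated out-of-fold probabilities, a one-sided
#' Mann-Whitney U test for performance above chance (AUC > 0.5), and a 95%
#' percentile confidence interval from class-stratified bootstrap
#' resampling of the scores.
#'
#' Repeated random splits score the same example several times; treating
#' those duplicates as independent observations inflates the U test's size
#' several-fold and makes the bootstrap CI spuriously narrow. When `groups`
#' identifies the underlying examples (participant x condition), scores are
#' averaged within group first, so inference runs on approximately
#' independent units and the test holds its nominal size under the null.
#'
#' @param scores out-of-fold class-1 probabilities.
#' @param labels matching binary labels.
#' @param groups optional example identifiers; scores sharing a group are
#'   averaged into one unit before AUC, U test and bootstrap.
#' @param n_boot bootstrap replications (default 10000).
#' @param conf confidence level (default 0.95).
#' @param seed bootstrap seed.
#' @return list of class `cv_outcome`: `auc`, `ci_low`, `ci_high`,
#'   `u_test_p`, `n`, `scores`, `labels`.
#' @export
evaluate_classification <- function(scores, labels, groups = NULL,
                                    n_boot = 10000L,
                                    conf = 0.95, seed = 1L) {
  if (!is.null(groups)) {
    stopifnot(length(groups) == length(scores))
    agg_s <- tapply(scores, groups, mean)
    agg_l <- tapply(as.integer(as.factor(labels)) - 1L, groups, function(v) {
      if (length(unique(v)) != 1L) stop("inconsistent labels within a group")
      v[1]
    })
    scores <- as.numeric(agg_s)
    labels <- as.integer(agg_l[names(agg_s)])
  }
  y <- as.integer(as.factor(labels)) - 1L
  if (length(unique(y)) < 2L) stop("both classes must be present")
  auc <- auc_from_scores(scores, y)
  u_p <- suppressWarnings(
    stats::wilcox.test(scores[y == 1L], scores[y == 0L],
                       alternative = "greater", exact = FALSE)$p.value)
  i1 <- which(y == 1L); i0 <- which(y == 0L)
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(b) {
    s1 <- i1[sample.int(length(i1), length(i1), replace = TRUE)]
    s0 <- i0[sample.int(length(i0), length(i0), replace = TRUE)]
    idx <- c(s1, s0)
    auc_from_scores(scores[idx], y[idx])
  }, 0)
  qs <- stats::quantile(boots, c((1 - conf) / 2, 1 - (1 - conf) / 2),
                        names = FALSE)
  structure(list(auc = auc, ci_low = qs[1], ci_high = qs[2], u_test_p = u_p,
                 n = length(y), scores = scores, labels = y),
            class = "cv_outcome")
}

#' Evaluate out-of-fold regression predictions
#'
#' Per-fold RMSE averaged across folds, compared with the RMSE of an
#' intercept-only baseline (each fold's training-target mean).
#'
#' @param predictions out-of-fold predictions.
#' @param truth matching targets.
#' @param fold integer fold id per prediction.
#' @param train_means named/indexed numeric: each fold's training-target
#'   mean (the intercept-only prediction).
#' @return list of class `cv_outcome`: `rmse`, `baseline_rmse`,
#'   `improvement` (baseline - model, positive is better), `per_fold`
#'   (data.frame).
#' @export
evaluate_regression <- function(predictions, truth, fold, train_means) {
  stopifnot(length(predictions) == length(truth),
            length(fold) == length(truth))
  folds <- sort(unique(fold))
  per <- lapply(folds, function(f) {
    sel <- fold == f
    if (!any(sel)) stop("empty fold ", f)
    data.frame(
      fold = f,
      rmse = sqrt(mean((predictions[sel] - truth[sel])^2)),
      baseline_rmse = sqrt(mean((train_means[[as.character(f)]] - truth[sel])^2))
    )
  })
  per <- do.call(rbind, per)
  structure(list(rmse = mean(per$rmse), baseline_rmse = mean(per$baseline_rmse),
                 improvement = mean(per$baseline_rmse) - mean(per$rmse),
                 per_fold = per),
            class = "cv_outcome")
}

#' Per-band group test on mean coherence
#'
#' One-tailed dependent t tests (Active > Sham) on mean coherence per band,
#' with Benjamini-Hochberg false-discovery-rate adjustment across the bands.
#'
#' @param active,sham participants x bands numeric matrices/data.frames,
#'   rows paired by participant, identical column order.
#' @param fdr_alpha significance level applied to adjusted p values.
#' @return data.frame `(band, t, df, p_raw, p_adjusted, significant)`.
#' @export
group_coherence_test <- function(active, sham, fdr_alpha = 0.05) {
  a <- as.matrix(active); s <- as.matrix(sham)
  stopifnot(identical(dim(a), dim(s)), nrow(a) >= 3L)
  res <- lapply(seq_len(ncol(a)), function(j) {
    d <- a[, j] - s[, j]
    if (stats::sd(d) <= 1e-12 * (stats::sd(a[, j]) + 1)) {
      # zero-variance differences: p = 0.5 when identical (no evidence),
      # saturated t for a constant nonzero shift
      deg <- if (abs(mean(d)) <= 1e-12 * (stats::sd(a[, j]) + 1)) {
        data.frame(band = colnames(a)[j], t = 0, df = nrow(a) - 1,
                   p_raw = 0.5)
      } else {
        data.frame(band = colnames(a)[j], t = sign(mean(d)) * Inf,
                   df = nrow(a) - 1, p_raw = if (mean(d) > 0) 0 else 1)
      }
      return(deg)
    }
    tt <- stats::t.test(a[, j], s[, j], paired = TRUE,
                        alternative = "greater")
    data.frame(band = colnames(a)[j], t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  out <- do.call(rbind, res)
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out$significant <- out$p_adjusted < fdr_alpha
  out
}
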