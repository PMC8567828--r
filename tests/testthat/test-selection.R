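test_that("collinearity pruning follows the mean-absolute-correlation rule", {
  set.seed(30)
  # two identical columns: exactly one dropped
  x <- data.frame(a = rnorm(20))
  x$b <- x$a
  x$c <- rnorm(20)
  rc <- remove_collinear(x)
  expect_length(rc$removed, 1L)
  expect_true(rc$removed %in% c("a", "b"))
  expect_equal(ncol(rc$features), 2L)
  # A-B correlated 0.9; A also tracks C, B does not: A is dropped
  n <- 400
  a <- rnorm(n)
  b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  c <- 0.55 * a + sqrt(1 - 0.3) * rnorm(n)
  tab <- data.frame(A = a, B = b, C = c)
  r <- abs(cor(tab))
  expect_gt(r["A", "B"], 0.8)
  expect_gt(mean(r["A", c("B", "C")]), mean(r["B", c("A", "C")]))
  rc2 <- remove_collinear(tab)
  expect_identical(rc2$removed, "A")
  # all pairwise |r| < 0.8: unchanged
  set.seed(31)
  indep <- as.data.frame(matrix(rnorm(300), 50))
  rc3 <- remove_collinear(indep)
  expect_length(rc3$removed, 0L)
  expect_equal(ncol(rc3$features), 6L)
  # constant columns dropped first
  indep$const <- 1
  expect_identical(remove_collinear(indep)$constant, "const")
})

test_that("univariate filters match hand-computed statistics", {
  # paired t: constructed difference with known t
  participant <- rep(1:5, 2)
  condition <- rep(c("Active", "Sham"), each = 5)
  d <- c(0.5, 1.0, 1.5, 2.0, 2.5)       # mean 1.5, sd 0.7906
  x_sham <- c(0.3, -0.1, 0.2, 0.0, 0.1)
  tab <- data.frame(f1 = c(x_sham + d, x_sham),  # t = 1.5/(0.7906/sqrt(5))
                    f2 = c(x_sham, x_sham))      # identical across conditions
  uf <- univariate_filter(tab, condition, "paired_t", participant = participant)
  expect_equal(unname(uf$stats["f1"]), mean(d) / (sd(d) / sqrt(5)),
               tolerance = 1e-12)
  expect_equal(unname(uf$stats["f2"]), 0)
  expect_identical(uf$removed, "f2")
  # |t| threshold keeps a feature at t = 1.5 on a 5-row toy table
  d2 <- c(-0.3, 0.55, 0.1, 0.9, 0.43)
  t_hand <- mean(d2) / (sd(d2) / sqrt(5))
  expect_gt(abs(t_hand), 1)
  tab2 <- data.frame(g = c(x_sham + d2, x_sham))
  tab2$h <- rnorm(10, sd = 0.001) + rep(c(0.01, 0), each = 5)
  uf2 <- univariate_filter(tab2, condition, "paired_t",
                           participant = participant)
  expect_true("g" %in% colnames(uf2$features))
  # pearson mode: feature equal to the target is kept with r = 1
  y <- rnorm(12)
  tab3 <- data.frame(same = y, junk = rnorm(12, sd = 1e-6) + 0)
  uf3 <- univariate_filter(tab3, y, "pearson_r")
  expect_equal(unname(uf3$stats["same"]), 1, tolerance = 1e-12)
  expect_true("same" %in% colnames(uf3$features))
})

test_that("shadow-feature selection finds strong features and rejects noise", {
  set.seed(33)
  n <- 40
  y <- factor(rep(c("a", "b"), each = n / 2))
  hits <- 0L
  false_sel <- 0L
  for (s in 1:5) {
    x <- as.data.frame(matrix(rnorm(n * 12), n))
    names(x) <- paste0("f", 1:12)
    x$signal <- ifelse(y == "a", 0, 3) + rnorm(n, sd = 0.3)
    bs <- boruta_select(x, y, "classify", n_iterations = 20, n_trees = 100,
                        seed = s)
    hits <- hits + ("signal" %in% bs$confirmed)
    false_sel <- false_sel + length(setdiff(bs$confirmed, "signal"))
    expect_identical(bs$top_feature, "signal")
  }
  expect_gte(hits, 4L)
  expect_lte(false_sel, 2L)
  # pure noise: confirmed set empty almost always
  set.seed(34)
  empty <- vapply(1:5, function(s) {
    x <- as.data.frame(matrix(rnorm(30 * 8), 30))
    bs <- boruta_select(x, factor(rep(c("a", "b"), 15)), "classify",
                        n_iterations = 20, n_trees = 60, seed = s)
    length(bs$confirmed) == 0L
  }, logical(1))
  expect_gte(mean(empty), 0.8)
  # determinism and bookkeeping
  x <- as.data.frame(matrix(rnorm(30 * 5), 30))
  yy <- rnorm(30)
  b1 <- boruta_select(x, yy, "regress", n_iterations = 10, n_trees = 50,
                      seed = 5)
  b2 <- boruta_select(x, yy, "regress", n_iterations = 10, n_trees = 50,
                      seed = 5)
  expect_identical(b1$hits, b2$hits)
  expect_identical(b1$confirmed, b2$confirmed)
  expect_equal(dim(b1$importance_history), c(10L, 6L))
  expect_error(boruta_select(x, factor(rep("a", 30)), "classify"), "single class")
})

test_that("folds cover every participant with holdouts of size 1-3", {
  for (s in 1:20) {
    fs <- make_folds(1:18, 35, seed = s)
    expect_length(fs$holdouts, 35L)
    sizes <- lengths(fs$holdouts)
    expect_true(all(sizes %in% 1:3))
    expect_setequal(unique(unlist(fs$holdouts)), 1:18)
  }
  f1 <- make_folds(1:18, 35, seed = 3)
  f2 <- make_folds(1:18, 35, seed = 3)
  expect_identical(f1$holdouts, f2$holdouts)
  expect_error(make_folds(1:3, 35), "4")
})

test_that("models standardize on training data and behave in known limits", {
  set.seed(36)
  # OLS recovers slope 2 within its confidence interval
  x <- matrix(rnorm(60), dimnames = list(NULL, "x"))
  y <- 2 * x[, 1] + rnorm(60, sd = 0.3)
  fit <- lm(y ~ x)
  expect_true(abs(coef(fit)[2] - 2) < 2.5 * summary(fit)$coefficients[2, 2])
  pred <- fit_predict(x[1:40, , drop = FALSE], y[1:40],
                      x[41:60, , drop = FALSE], "linear")
  expect_gt(cor(pred, y[41:60]), 0.9)
  # ridge with huge lambda shrinks towards the training mean / prevalence
  xr <- matrix(rnorm(80), 40, 2, dimnames = list(NULL, c("a", "b")))
  yr <- rnorm(40, mean = 5)
  pr <- fit_predict(xr[1:30, ], yr[1:30], xr[31:40, ], "ridge_linear")
  # lambda.min may be small; force the shrinkage limit via the grid top
  mu <- colMeans(xr[1:30, ]); sdv <- apply(xr[1:30, ], 2, sd)
  xs <- sweep(sweep(xr[1:30, ], 2, mu), 2, sdv, "/")
  big <- glmnet::glmnet(xs, yr[1:30], alpha = 0, lambda = 1e6)
  pred_big <- predict(big, newx = sweep(sweep(xr[31:40, ], 2, mu), 2, sdv, "/"))
  expect_equal(unname(pred_big[, 1]), rep(mean(yr[1:30]), 10),
               tolerance = 0.01)
  # separable classes: holdout probabilities fall on the correct side
  xs2 <- matrix(c(rnorm(20, -3), rnorm(20, 3)), ncol = 1,
                dimnames = list(NULL, "f"))
  ys2 <- rep(0:1, each = 20)
  ps <- fit_predict(xs2[c(1:15, 21:35), , drop = FALSE],
                    ys2[c(1:15, 21:35)],
                    xs2[c(16:20, 36:40), , drop = FALSE], "logistic")
  expect_true(all(ps[1:5] < 0.5) && all(ps[6:10] > 0.5))
  ps_r <- fit_predict(xs2[c(1:15, 21:35), , drop = FALSE],
                      ys2[c(1:15, 21:35)],
                      xs2[c(16:20, 36:40), , drop = FALSE], "ridge_logistic")
  expect_true(all(ps_r[1:5] < 0.5) && all(ps_r[6:10] > 0.5))
})

test_that("classification evaluation matches exhaustive pair counting", {
  # 4-example toy set
  expect_equal(auc_from_scores(c(.9, .8, .3, .1), c(1, 1, 0, 0)), 1)
  expect_equal(auc_from_scores(c(.9, .3, .8, .1), c(1, 1, 0, 0)), 0.75)
  set.seed(37)
  for (rep in 1:50) {
    n <- sample(4:8, 1)
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- round(runif(n), 1)
    expect_equal(auc_from_scores(scores, labels),
                 oracle_pair_auc(scores, labels), tolerance = 1e-12)
  }
  ev <- evaluate_classification(c(.9, .8, .3, .1), c(1, 1, 0, 0),
                                n_boot = 500, seed = 1)
  expect_equal(ev$auc, 1)
  expect_equal(ev$ci_low, 1)
  expect_equal(ev$ci_high, 1)
  expect_error(evaluate_classification(c(.1, .2), c(1, 1), n_boot = 10),
               "both classes")
  # agreement with an independent ROC implementation
  set.seed(38)
  sc <- runif(40); lb <- rbinom(40, 1, 0.5 + 0.3 * (sc > 0.5))
  if (length(unique(lb)) == 2) {
    ref <- as.numeric(pROC::auc(pROC::roc(lb, sc, quiet = TRUE)))
    expect_equal(auc_from_scores(sc, lb), ref, tolerance = 1e-12)
  }
})

test_that("regression evaluation compares against the intercept baseline", {
  truth <- c(1, 2, 3, 4)
  ev <- evaluate_regression(truth, truth, fold = c(1, 1, 2, 2),
                            train_means = list(`1` = 2.5, `2` = 2.5))
  expect_equal(ev$rmse, 0)
  expect_gt(ev$baseline_rmse, 0)
  # intercept-only predictions on centered targets: baseline ~ sd(truth)
  set.seed(39)
  y <- rnorm(200)
  ev2 <- evaluate_regression(rep(0, 200), y, fold = rep(1:4, each = 50),
                             train_means = list(`1` = 0, `2` = 0, `3` = 0,
                                                `4` = 0))
  expect_equal(ev2$baseline_rmse, sd(y), tolerance = 0.1)
})

test_that("per-band coherence test applies one-tailed t with BH adjustment", {
  # BH hand example
  expect_equal(p.adjust(c(0.01, 0.02, 0.2, 0.5, 0.7, 0.9), method = "BH"),
               c(0.06, 0.06, 0.4, 0.75, 0.84, 0.9))
  # identical conditions: all one-tailed p = 0.5
  set.seed(40)
  a <- matrix(rnorm(60), 10, 6, dimnames = list(NULL, names(eeg_bands())))
  res <- group_coherence_test(a, a)
  expect_true(all(res$p_raw == 0.5))
  expect_false(any(res$significant))
  # a genuine theta shift survives FDR
  b <- a; b[, "theta"] <- b[, "theta"] + 3
  res2 <- group_coherence_test(b, a)
  expect_true(res2$significant[res2$band == "theta"])
  expect_false(any(res2$significant[res2$band != "theta"]))
})

test_that("training-side selection never touches held-out rows", {
  eff <- c(mean_coherence_theta = 1.2, density_theta = 1.2)
  ft <- generate_feature_table(12, eff, seed = 44)
  cfg <- pipeline_config(boruta_iterations = 10L, boruta_trees = 60L,
                         seed = 44)
  hold <- c(11, 12)
  tr <- !(ft$participant %in% hold)
  sel1 <- upstate:::select_features_classification(
    ft[tr, -(1:2)], ft$condition[tr], ft$participant[tr], cfg, seed = 1)
  # corrupt the held-out rows arbitrarily; selection must be unchanged
  ft2 <- ft
  ft2[!tr, -(1:2)] <- 1e6
  tr2 <- !(ft2$participant %in% hold)
  sel2 <- upstate:::select_features_classification(
    ft2[tr2, -(1:2)], ft2$condition[tr2], ft2$participant[tr2], cfg, seed = 1)
  expect_identical(sel1, sel2)
})

test_that("the full pipeline recovers injected structure end to end", {
  eff <- c(mean_coherence_theta = 1, density_theta = 1,
           path_length_spindle = -1, radius_spindle = -1)
  ft <- generate_feature_table(18, eff, seed = 1)
  beh <- generate_behavior(ft$path_length_beta[ft$condition == "Active"],
                           rho = -0.66, seed = 1)
  dd <- overnight_dauc(beh$trials)
  cfg <- pipeline_config(boruta_iterations = 15L, boruta_trees = 120L,
                         n_boot = 300L, seed = 1)
  rep <- run_full_pipeline(ft, data.frame(participant = dd$participant,
                                          dauc = dd$dauc), cfg)
  expect_s3_class(rep, "pipeline_report")
  # the injected features dominate the selection frequencies
  freq <- rep$selection$classification_frequency
  expect_true(any(names(eff) %in% names(freq)[1:3]))
  # out-of-fold classification beats chance
  expect_gt(rep$classification$selected_ridge$auc, 0.5)
  # follow-up block exists with FDR-adjusted feature tests
  expect_true(!is.null(rep$followup$condition_tests))
  expect_true(all(c("p_raw", "p_adjusted") %in%
                    names(rep$followup$condition_tests)))
  # input validation
  expect_error(run_full_pipeline(ft[ft$participant <= 4, ],
                                 data.frame(participant = 1:4, dauc = rnorm(4)),
                                 cfg), "participants")
})

test_that("AUC inference holds its nominal size on independent null scores", {
  # calibration of the U test and bootstrap CI themselves, free of any
  # cross-validation structure: iid scores, balanced classes
  set.seed(61)
  rej <- cov <- logical(100)
  for (k in 1:100) {
    sc <- runif(36)
    lb <- rep(0:1, 18)
    ev <- evaluate_classification(sc, lb, n_boot = 200L, seed = k)
    rej[k] <- ev$u_test_p < 0.05
    cov[k] <- ev$ci_low <= 0.5 && ev$ci_high >= 0.5
  }
  expect_lte(mean(rej), 0.10)
  expect_gte(mean(cov), 0.90)
  # aggregation by groups averages duplicate scores before inference
  ev2 <- evaluate_classification(c(0.8, 0.6, 0.2), c(1, 1, 0),
                                 groups = c("a", "a", "b"),
                                 n_boot = 50L, seed = 1)
  expect_equal(ev2$n, 2L)
  expect_equal(ev2$auc, 1)
})
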