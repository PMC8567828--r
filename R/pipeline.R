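#' Configuration for the cross-validated selection and prediction pipeline
#'
#' @param n_folds repeated random-split folds (default 35).
#' @param holdout_sizes participants left out per fold (default 1-3).
#' @param r_collinear collinearity pruning threshold (default 0.8).
#' @param t_filter paired-t filter threshold for classification (default 1).
#' @param r_filter correlation filter threshold for regression (default 0.1).
#' @param boruta_iterations,boruta_trees per-fold shadow-selection effort.
#'   The pipeline defaults (30 iterations, 150 trees) trade a little
#'   selection stability for running 2 x 35 selections per analysis;
#'   [boruta_select()] keeps the larger single-run defaults (100, 500).
#' @param n_boot bootstrap replications for the AUC confidence interval.
#' @param alpha selection significance level.
#' @param run_followup run the whole-sample follow-up tests (final
#'   selection, per-feature condition t tests with FDR, per-band mean
#'   coherence test).
#' @param tasks which analyses to run: `"classify"`, `"regress"` or both
#'   (default). The combined and top-of-each feature sets require both.
#' @param seed master seed; every random stage derives from it.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(n_folds = 35L, holdout_sizes = 1:3,
                            r_collinear = 0.8, t_filter = 1, r_filter = 0.1,
                            boruta_iterations = 30L, boruta_trees = 150L,
                            n_boot = 10000L, alpha = 0.05,
                            run_followup = TRUE,
                            tasks = c("classify", "regress"), seed = 1L) {
  stopifnot(all(tasks %in% c("classify", "regress")), length(tasks) >= 1L)
  structure(list(n_folds = as.integer(n_folds), holdout_sizes = holdout_sizes,
                 r_collinear = r_collinear, t_filter = t_filter,
                 r_filter = r_filter,
                 boruta_iterations = as.integer(boruta_iterations),
                 boruta_trees = as.integer(boruta_trees),
                 n_boot = as.integer(n_boot), alpha = alpha,
                 run_followup = run_followup, tasks = tasks,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

# Training-side feature selection for the classification task.
# Returns selected feature names, the top feature, and the filter statistics.
select_features_classification <- function(x, condition, participant, cfg,
                                           seed) {
  rc <- remove_collinear(x, cfg$r_collinear)
  uf <- univariate_filter(rc$features, condition, mode = "paired_t",
                          threshold = cfg$t_filter, participant = participant)
  if (ncol(uf$features) >= 2L) {
    bs <- boruta_select(uf$features, condition, task = "classify",
                        n_iterations = cfg$boruta_iterations,
                        n_trees = cfg$boruta_trees, alpha = cfg$alpha,
                        seed = seed)
    selected <- bs$confirmed
    top <- bs$top_feature
  } else {
    selected <- colnames(uf$features)
    top <- selected[1]
  }
  surviving <- colnames(uf$features)
  if (length(selected) == 0L) {
    # fall back to the strongest filter statistic so every fold can predict
    top <- surviving[which.max(abs(uf$stats[surviving]))]
    selected <- top
    fallback <- TRUE
  } else fallback <- FALSE
  if (is.na(top) || length(top) == 0L) top <- surviving[1]
  list(selected = selected, top = top, fallback = fallback,
       surviving_after_collinearity = colnames(rc$features),
       surviving_after_filter = surviving)
}

# Training-side feature selection for the regression task.
select_features_regression <- function(x, y, cfg, seed) {
  rc <- remove_collinear(x, cfg$r_collinear)
  uf <- univariate_filter(rc$features, y, mode = "pearson_r",
                          threshold = cfg$r_filter)
  if (ncol(uf$features) >= 2L) {
    bs <- boruta_select(uf$features, y, task = "regress",
                        n_iterations = cfg$boruta_iterations,
                        n_trees = cfg$boruta_trees, alpha = cfg$alpha,
                        seed = seed)
    selected <- bs$confirmed
    top <- bs$top_feature
  } else {
    selected <- colnames(uf$features)
    top <- selected[1]
  }
  surviving <- colnames(uf$features)
  if (length(selected) == 0L) {
    top <- surviving[which.max(abs(uf$stats[surviving]))]
    selected <- top
    fallback <- TRUE
  } else fallback <- FALSE
  if (is.na(top) || length(top) == 0L) top <- surviving[1]
  list(selected = selected, top = top, fallback = fallback,
       surviving_after_collinearity = colnames(rc$features),
       surviving_after_filter = surviving)
}

#' Run the full cross-validated selection and prediction pipeline
#'
#' Per fold, strictly on the training participants: collinearity pruning,
#' the univariate filter, shadow-feature selection, then model fits; the
#' held-out participants are only ever scored. Classification (Active vs
#' Sham) and regression (overnight change in type-2 AUC, Active condition)
#' run inside the same folds; the combined and top-of-each feature sets are
#' re-fit per fold from the two selections. Out-of-fold scores are
#' concatenated across folds and evaluated with AUC + stratified-bootstrap
#' CI + one-sided Mann-Whitney test (classification) and mean per-fold RMSE
#' against the intercept-only baseline (regression).
#'
#' @param features feature table: data.frame with `participant`,
#'   `condition` (`"Active"`/`"Sham"`) and numeric feature columns
#'   (post-minus-pre changes), e.g. from [generate_feature_table()] or
#'   [cohort_feature_table()].
#' @param dauc data.frame `(participant, dauc)`: overnight change in type-2
#'   AUC per participant (Active condition), e.g. from
#'   [sensitivity_table()] + [overnight_change()].
#' @param config a [pipeline_config()].
#' @return list of class `pipeline_report`: `classification` and
#'   `regression` (each a list of `cv_outcome` by feature set:
#'   `selected`, `selected_ridge`, `top_pair` / `top`, `combined`),
#'   `selection` (per-fold selected/top features and fallback counts),
#'   `followup` (whole-sample tests) and `folds`.
#' @export
run_full_pipeline <- function(features, dauc, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  fcols <- setdiff(names(features), c("participant", "condition"))
  if (length(fcols) < 2L) stop("pipeline stage 'input': need >= 2 feature columns")
  participants <- sort(unique(features$participant))
  if (length(participants) < 6L)
    stop("pipeline stage 'input': need >= 6 participants")
  if (!all(dauc$participant %in% participants))
    stop("pipeline stage 'input': behavior targets for unknown participants")
  dauc <- dauc[match(participants, dauc$participant), ]
  active <- features[features$condition == "Active", ]
  active <- active[match(participants, active$participant), ]
  y_reg <- dauc$dauc

  do_cls <- is.null(config$tasks) || "classify" %in% config$tasks
  do_reg <- is.null(config$tasks) || "regress" %in% config$tasks
  folds <- make_folds(participants, config$n_folds, config$holdout_sizes,
                      seed = config$seed)
  oof <- list(cls = list(), reg = list())
  sel_log <- list()
  train_means <- list()
  for (f in seq_len(folds$n_folds)) {
    hold <- folds$holdouts[[f]]
    tr_rows <- !(features$participant %in% hold)
    te_rows <- features$participant %in% hold
    fx_tr <- features[tr_rows, fcols, drop = FALSE]
    fx_te <- features[te_rows, fcols, drop = FALSE]
    cond_tr <- features$condition[tr_rows]
    cond_te <- features$condition[te_rows]
    part_tr <- features$participant[tr_rows]
    fold_seed <- derive_seed(config$seed, f, 1L)

    cls_sel <- if (do_cls)
      select_features_classification(fx_tr, cond_tr, part_tr, config,
                                     fold_seed) else NULL
    tr_act <- !(active$participant %in% hold)
    ax_tr <- active[tr_act, fcols, drop = FALSE]
    ax_te <- active[!tr_act, fcols, drop = FALSE]
    yr_tr <- y_reg[tr_act]
    yr_te <- y_reg[!tr_act]
    reg_sel <- if (do_reg)
      select_features_regression(ax_tr, yr_tr, config,
                                 derive_seed(config$seed, f, 2L)) else NULL

    y_cls_tr <- as.integer(cond_tr == "Active")
    score_cls <- function(cols, model) {
      fit_predict(fx_tr[, cols, drop = FALSE], y_cls_tr,
                  fx_te[, cols, drop = FALSE], model, seed = fold_seed)
    }
    score_reg <- function(cols, model) {
      fit_predict(ax_tr[, cols, drop = FALSE], yr_tr,
                  ax_te[, cols, drop = FALSE], model, seed = fold_seed)
    }
    if (do_cls) {
      df <- data.frame(
        fold = f, participant = features$participant[te_rows],
        label = as.integer(cond_te == "Active"),
        selected = score_cls(cls_sel$selected, "logistic"),
        selected_ridge = score_cls(cls_sel$selected, "ridge_logistic"))
      if (do_reg) {
        df$top_pair <- score_cls(unique(c(cls_sel$top, reg_sel$top)),
                                 "logistic")
        df$combined <- score_cls(union(cls_sel$selected, reg_sel$selected),
                                 "logistic")
      }
      oof$cls[[f]] <- df
    }
    if (do_reg) {
      df <- data.frame(
        fold = f, participant = active$participant[!tr_act], truth = yr_te,
        selected = score_reg(reg_sel$selected, "linear"),
        selected_ridge = score_reg(reg_sel$selected, "ridge_linear"),
        top = score_reg(reg_sel$top, "linear"))
      if (do_cls) {
        df$combined <- score_reg(union(cls_sel$selected, reg_sel$selected),
                                 "linear")
      }
      oof$reg[[f]] <- df
    }
    train_means[[as.character(f)]] <- mean(yr_tr)
    sel_log[[f]] <- list(classification = cls_sel, regression = reg_sel)
  }
  classification <- regression <- NULL
  if (do_cls) {
    cls <- do.call(rbind, oof$cls)
    eval_cls <- function(col, k) {
      evaluate_classification(cls[[col]], cls$label,
                              groups = paste(cls$participant, cls$label),
                              n_boot = config$n_boot,
                              seed = derive_seed(config$seed, 9000L + k))
    }
    classification <- list(selected = eval_cls("selected", 1L),
                           selected_ridge = eval_cls("selected_ridge", 2L))
    if (do_reg) {
      classification$top_pair <- eval_cls("top_pair", 3L)
      classification$combined <- eval_cls("combined", 4L)
    }
  }
  if (do_reg) {
    reg <- do.call(rbind, oof$reg)
    eval_reg <- function(col) {
      evaluate_regression(reg[[col]], reg$truth, reg$fold, train_means)
    }
    regression <- list(selected = eval_reg("selected"),
                       selected_ridge = eval_reg("selected_ridge"),
                       top = eval_reg("top"))
    if (do_cls) regression$combined <- eval_reg("combined")
  }

  sel_freq <- function(which) {
    sel <- lapply(sel_log, function(s) s[[which]]$selected)
    tab <- table(unlist(sel))
    sort(tab / folds$n_folds, decreasing = TRUE)
  }
  selection <- list(per_fold = sel_log)
  if (do_cls) {
    selection$classification_frequency <- sel_freq("classification")
    selection$n_fallback_classification <- sum(vapply(sel_log, function(s)
      s$classification$fallback, logical(1)))
  }
  if (do_reg) {
    selection$regression_frequency <- sel_freq("regression")
    selection$n_fallback_regression <- sum(vapply(sel_log, function(s)
      s$regression$fallback, logical(1)))
  }

  followup <- NULL
  if (isTRUE(config$run_followup) && do_cls) {
    followup <- pipeline_followup(features, fcols, participants, config)
  }
  structure(list(classification = classification, regression = regression,
                 selection = selection, followup = followup, folds = folds,
                 config = config),
            class = "pipeline_report")
}

# Whole-sample follow-up tests: final selection + per-feature condition t
# tests (FDR-adjusted) and the per-band mean coherence group test.
pipeline_followup <- function(features, fcols, participants, config) {
  act <- features[features$condition == "Active", ]
  shm <- features[features$condition == "Sham", ]
  act <- act[match(participants, act$participant), ]
  shm <- shm[match(participants, shm$participant), ]
  sel <- select_features_classification(features[, fcols, drop = FALSE],
                                        features$condition,
                                        features$participant, config,
                                        derive_seed(config$seed, 4242L))
  tests <- lapply(sel$selected, function(fc) {
    tt <- stats::t.test(act[[fc]], shm[[fc]], paired = TRUE)
    data.frame(feature = fc, t = unname(tt$statistic),
               df = unname(tt$parameter), p_raw = tt$p.value)
  })
  tests <- do.call(rbind, tests)
  tests$p_adjusted <- stats::p.adjust(tests$p_raw, method = "BH")
  mc_cols <- grep("^mean_coherence_", fcols, value = TRUE)
  band_test <- NULL
  if (length(mc_cols) > 0) {
    band_test <- group_coherence_test(act[, mc_cols, drop = FALSE],
                                      shm[, mc_cols, drop = FALSE])
  }
  list(final_selected = sel$selected, condition_tests = tests,
       mean_coherence_bands = band_test)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>\n")
  if (!is.null(x$classification)) {
    cat(" classification AUC (95% CI):\n")
    for (nm in names(x$classification)) {
      o <- x$classification[[nm]]
      cat(sprintf("   %-15s %.3f (%.3f-%.3f), U-test p = %.3g\n",
                  nm, o$auc, o$ci_low, o$ci_high, o$u_test_p))
    }
  }
  if (!is.null(x$regression)) {
    cat(" regression RMSE (baseline):\n")
    for (nm in names(x$regression)) {
      o <- x$regression[[nm]]
      cat(sprintf("   %-15s %.3f (%.3f)\n", nm, o$rmse, o$baseline_rmse))
    }
  }
  invisible(x)
}
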