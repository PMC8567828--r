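#' Extract the stimulation-induced feature vector from one recording
#'
#' The full signal chain for one night: preprocessing (250 Hz, average
#' reference, 0.1-70 Hz), baseline/analysis epoching around the events,
#' Welch cross-spectra, imaginary coherency, band averaging, graph
#' construction, and the post-minus-pre change of the eight metrics per
#' band.
#'
#' @param recording raw [eeg_recording()].
#' @param events event table (`onset_s`, `offset_s`).
#' @param threshold_rule graph threshold, see [build_graph()].
#' @param seed Louvain seed.
#' @return named numeric vector of 48 features; attributes `"pre"` and
#'   `"post"` hold the `band_coherence` objects.
#' @export
extract_features <- function(recording, events,
                             threshold_rule = list(mode = "absolute",
                                                   value = 0.1),
                             seed = 1L) {
  pp <- preprocess(recording)
  eps <- extract_epochs(pp, events)
  pre <- band_icoh(eps$baseline)
  post <- band_icoh(eps$analysis)
  fv <- compute_feature_vector(pre, post, threshold_rule, seed)
  attr(fv, "pre") <- pre
  attr(fv, "post") <- post
  fv
}

#' Feature table for a synthetic cohort
#'
#' Runs [extract_features()] on every participant x condition recording of
#' a [generate_cohort()] result.
#'
#' @param cohort a `synthetic_cohort`.
#' @param threshold_rule see [build_graph()].
#' @param seed Louvain seed.
#' @return data.frame `(participant, condition, <48 features>)`.
#' @export
cohort_feature_table <- function(cohort,
                                 threshold_rule = list(mode = "absolute",
                                                       value = 0.1),
                                 seed = 1L) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- list()
  for (i in seq_along(cohort$recordings)) {
    for (cond in c("Active", "Sham")) {
      fv <- extract_features(cohort$recordings[[i]][[cond]]$recording,
                             cohort$events[[i]][[cond]],
                             threshold_rule, seed)
      rows[[length(rows) + 1L]] <-
        cbind(data.frame(participant = i, condition = cond),
              as.data.frame(t(fv)))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Overnight sensitivity changes for a cohort's behavior
#'
#' Computes the per-participant type-2 AUC for the pre- and post-sleep
#' sessions and their overnight change.
#'
#' @param trials behavior trials (`participant`, `session` with levels
#'   `"presleep"`/`"postsleep"`, `correct`, `confidence`).
#' @return data.frame `(participant, auc_pre, auc_post, dauc)`.
#' @export
overnight_dauc <- function(trials) {
  st <- sensitivity_table(trials)
  pre <- st[st$session == "presleep", ]
  post <- st[st$session == "postsleep", ]
  m <- match(pre$participant, post$participant)
  data.frame(participant = pre$participant, auc_pre = pre$auc,
             auc_post = post$auc[m],
             dauc = post$auc[m] - pre$auc)
}
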