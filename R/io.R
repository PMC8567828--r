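#' Write / read an EEG recording as TSV plus JSON sidecar
#'
#' Plain-text interchange: a samples x channels TSV matrix (header = channel
#' labels, microvolts) and a JSON sidecar holding the sampling rate, labels,
#' units and reference. A ground-truth block (e.g. the simulated SWO phase)
#' may ride along in the sidecar.
#'
#' @param recording an [eeg_recording()].
#' @param path TSV path; the sidecar is `<path>.json`.
#' @param ground_truth optional list serialized into the sidecar.
#' @param digits signal precision in the TSV (default 4 decimal places).
#' @return `path`, invisibly.
#' @export
write_eeg <- function(recording, path, ground_truth = NULL, digits = 4L) {
  stopifnot(inherits(recording, "eeg_recording"))
  m <- round(t(recording$data), digits)
  utils::write.table(m, path, sep = "\t", row.names = FALSE,
                     col.names = recording$labels, quote = FALSE)
  meta <- list(sampling_rate = recording$srate, labels = recording$labels,
               units = recording$units, reference = recording$reference,
               n_samples = ncol(recording$data))
  if (!is.null(ground_truth)) meta$ground_truth <- ground_truth
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_eeg
#' @param units_expected error unless the sidecar declares these units
#'   (default `"uV"`); set `NULL` to accept anything.
#' @return `read_eeg`: the [eeg_recording()]; the sidecar's ground-truth
#'   block, if any, is attached as attribute `"ground_truth"`.
#' @export
read_eeg <- function(path, units_expected = "uV") {
  if (!file.exists(path)) stop("EEG file not found: ", path)
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) stop("missing JSON sidecar: ", sidecar)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  for (field in c("sampling_rate", "labels", "units", "n_samples")) {
    if (is.null(meta[[field]])) stop("malformed sidecar: missing ", field)
  }
  if (!is.null(units_expected) && !identical(meta$units, units_expected))
    stop("unit mismatch: file declares '", meta$units, "'")
  m <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  if (!identical(colnames(m), as.character(meta$labels)))
    stop("channel labels in TSV do not match the sidecar")
  if (nrow(m) != meta$n_samples)
    stop("truncated EEG file: expected ", meta$n_samples, " samples, found ",
         nrow(m))
  rec <- eeg_recording(t(as.matrix(m)), meta$sampling_rate, meta$labels,
                       meta$units, meta$reference)
  if (!is.null(meta$ground_truth))
    attr(rec, "ground_truth") <- meta$ground_truth
  rec
}

#' Event-table TSV I/O
#'
#' Events are stored as tab-separated `(onset_s, offset_s, condition)` plus
#' any extra detector columns.
#'
#' @param events event data.frame.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  need <- c("onset_s", "offset_s")
  miss <- setdiff(need, names(ev))
  if (length(miss) > 0)
    stop("event table missing columns: ", paste(miss, collapse = ", "))
  ev[order(ev$onset_s), , drop = FALSE]
}

#' Behavior-trial CSV I/O
#'
#' Columns: `participant, session, trial, correct` (0/1), `confidence`
#' (1-10).
#'
#' @param trials trial data.frame.
#' @param path CSV path.
#' @export
write_behavior <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_behavior
#' @export
read_behavior <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant", "session", "correct", "confidence")
  miss <- setdiff(need, names(tr))
  if (length(miss) > 0)
    stop("behavior table missing columns: ", paste(miss, collapse = ", "))
  if (any(!tr$confidence %in% 1:10))
    stop("confidence ratings must lie in 1..10")
  if (any(!tr$correct %in% 0:1)) stop("correct must be 0/1")
  tr
}

#' Feature-table CSV I/O
#' @param features feature data.frame (`participant`, `condition`, features).
#' @param path CSV path.
#' @export
write_features <- function(features, path) {
  utils::write.csv(features, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
}

#' Provenance record for an output artifact
#'
#' A serializable block recording the configuration, seeds and counts that
#' make a run reproducible; written alongside reports.
#'
#' @param config any configuration list.
#' @param seeds named list of seeds used.
#' @param counts named list of row/epoch/exclusion counts.
#' @return list with a config digest, package version and the inputs.
#' @export
provenance_record <- function(config, seeds = list(), counts = list()) {
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA, force = TRUE)
  list(config_digest = sprintf("%08x", sum(utf8ToInt(cfg_json) *
                                             seq_along(utf8ToInt(cfg_json)))
                               %% 4294967291),
       package_version = as.character(utils::packageVersion("upstate")),
       r_version = R.version.string,
       seeds = seeds, counts = counts, config = unclass(config))
}
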