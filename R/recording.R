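#' EEG recording container
#'
#' A lightweight S3 container for multichannel EEG: a channels x samples
#' numeric matrix plus sampling rate, channel labels and units.
#'
#' @param data channels x samples numeric matrix.
#' @param srate sampling rate in Hz.
#' @param labels channel labels; defaults to the matrix rownames.
#' @param units amplitude units (default microvolts, `"uV"`).
#' @param reference reference description (free text).
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, srate, labels = rownames(data),
                          units = "uV", reference = "unknown") {
  data <- as.matrix(data)
  if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(data)))
  stopifnot(is.numeric(data), srate > 0, length(labels) == nrow(data))
  rownames(data) <- labels
  structure(
    list(data = data, srate = as.numeric(srate), labels = labels,
         units = units, reference = reference),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%s), ref: %s\n",
              nrow(x$data), ncol(x$data), x$srate, x$units, x$reference))
  invisible(x)
}

#' Number of seconds in a recording
#' @param x an `eeg_recording`.
#' @export
recording_duration <- function(x) ncol(x$data) / x$srate

# Sample index (1-based) of a time in seconds; t = 0 is the first sample.
time_to_sample <- function(t, srate) as.integer(round(t * srate)) + 1L
sample_to_time <- function(i, srate) (i - 1L) / srate
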