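#' Preprocess a recording for connectivity analysis
#'
#' Anti-aliased decimation to the target rate (zero-phase 4th-order
#' Butterworth lowpass at 80% of the new Nyquist before subsampling),
#' re-referencing to the average of all electrodes, and a zero-phase
#' Butterworth bandpass 0.1-70 Hz with a 24 dB/oct rolloff (second-order
#' design run forward-backward). A pluggable artifact-rejection hook
#' (identity by default) stands in for manual component-based cleaning.
#'
#' @param recording an [eeg_recording()] at a native rate >= 250 Hz.
#' @param target_rate output rate in Hz (default 250; must divide the native
#'   rate).
#' @param band bandpass edges in Hz (default `c(0.1, 70)`).
#' @param artifact_hook function `(matrix, srate) -> matrix` applied after
#'   filtering; identity by default.
#' @return preprocessed `eeg_recording`.
#' @export
preprocess <- function(recording, target_rate = 250, band = c(0.1, 70),
                       artifact_hook = NULL) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (nrow(recording$data) < 2L)
    stop("average reference requires at least 2 channels")
  srate <- recording$srate
  if (srate < target_rate) stop("native rate below target rate")
  q <- srate / target_rate
  if (abs(q - round(q)) > 1e-9)
    stop("target rate must divide the native rate")
  q <- as.integer(round(q))
  data <- recording$data
  if (q > 1L) {
    nyq_new <- target_rate / 2
    bf <- signal::butter(4, (0.8 * nyq_new) / (srate / 2), type = "low")
    data <- t(apply(data, 1, function(x) signal::filtfilt(bf, x)))
    data <- data[, seq(1L, ncol(data), by = q), drop = FALSE]
  }
  data <- sweep(data, 2, colMeans(data))       # average reference
  data <- t(apply(data, 1, function(x)
    bandpass_zerophase(x, band[1], band[2], target_rate, order = 2L)))
  if (!is.null(artifact_hook)) data <- artifact_hook(data, target_rate)
  eeg_recording(data, target_rate, recording$labels, recording$units,
                reference = "average")
}

#' Extract baseline and analysis epochs around stimulation events
#'
#' One baseline epoch (-6.4 to -2.4 s before stimulation onset) and one
#' analysis epoch (+3 to +7 s after stimulation offset) per event. Epochs
#' that run outside the recording, or that intersect any event's stimulation
#' interval, are dropped and counted.
#'
#' @param recording preprocessed [eeg_recording()].
#' @param events data.frame with `onset_s`, `offset_s` (sorted by onset).
#' @param baseline_window seconds relative to onset, default `c(-6.4, -2.4)`.
#' @param analysis_window seconds relative to offset, default `c(3, 7)`.
#' @return list of two `epoch_set` objects (`baseline`, `analysis`), each
#'   with `epochs` (trials x channels x samples array), `window_role`,
#'   `window_def`, `srate`, `n_dropped`, `event_index`.
#' @export
extract_epochs <- function(recording, events,
                           baseline_window = c(-6.4, -2.4),
                           analysis_window = c(3, 7)) {
  stopifnot(inherits(recording, "eeg_recording"))
  if (is.unsorted(events$onset_s)) stop("events must be sorted by onset")
  srate <- recording$srate
  dur <- recording_duration(recording)
  stim_iv <- cbind(events$onset_s, events$offset_s)
  grab <- function(lo, hi, role, window_def) {
    len <- as.integer(round((hi[1] - lo[1]) * srate))
    keep <- logical(length(lo))
    for (i in seq_along(lo)) {
      in_range <- lo[i] >= 0 && hi[i] <= dur
      overlaps <- any(lo[i] < stim_iv[, 2] & hi[i] > stim_iv[, 1])
      keep[i] <- in_range && !overlaps
    }
    idx <- which(keep)
    if (length(idx) == 0) stop("no surviving ", role, " epochs")
    arr <- array(NA_real_,
                 dim = c(length(idx), nrow(recording$data), len),
                 dimnames = list(NULL, recording$labels, NULL))
    for (k in seq_along(idx)) {
      i0 <- time_to_sample(lo[idx[k]], srate)
      arr[k, , ] <- recording$data[, i0:(i0 + len - 1L), drop = FALSE]
    }
    structure(list(epochs = arr, window_role = role, window_def = window_def,
                   srate = srate, n_dropped = sum(!keep),
                   event_index = idx),
              class = "epoch_set")
  }
  list(
    baseline = grab(events$onset_s + baseline_window[1],
                    events$onset_s + baseline_window[2],
                    "baseline", baseline_window),
    analysis = grab(events$offset_s + analysis_window[1],
                    events$offset_s + analysis_window[2],
                    "analysis", analysis_window)
  )
}

#' Welch cross-spectral matrices
#'
#' Cross-spectra between all channel pairs by Welch's method: Hamming-tapered
#' segments (2048 ms, i.e. 512 samples at 250 Hz) with 50% overlap, averaged
#' over segments within each epoch and over epochs. Frequency resolution is
#' `srate / nfft` (about 0.488 Hz at 250 Hz).
#'
#' @param epoch_set an `epoch_set` from [extract_epochs()].
#' @param seg_len_s segment length in seconds (default 2.048).
#' @param overlap fractional overlap between segments (default 0.5).
#' @return list of class `cross_spectra`: `S` (channels x channels x
#'   frequency complex array, Hermitian in the channel pair), `freqs` (Hz),
#'   `n_segments` (total averaged segments).
#' @export
welch_cross_spectra <- function(epoch_set, seg_len_s = 2.048, overlap = 0.5) {
  stopifnot(inherits(epoch_set, "epoch_set"))
  srate <- epoch_set$srate
  nseg <- as.integer(round(seg_len_s * srate))
  dims <- dim(epoch_set$epochs)
  n_trials <- dims[1]; n_ch <- dims[2]; n_samp <- dims[3]
  if (n_samp < nseg) stop("epoch shorter than one Welch segment")
  step <- max(1L, as.integer(round(nseg * (1 - overlap))))
  starts <- seq(1L, n_samp - nseg + 1L, by = step)
  win <- hamming_window(nseg)
  norm <- sum(win^2) * srate
  nfreq <- nseg %/% 2L + 1L
  freqs <- (seq_len(nfreq) - 1L) * srate / nseg
  S <- array(0 + 0i, dim = c(n_ch, n_ch, nfreq),
             dimnames = list(dimnames(epoch_set$epochs)[[2]],
                             dimnames(epoch_set$epochs)[[2]], NULL))
  total <- 0L
  for (tr in seq_len(n_trials)) {
    for (s0 in starts) {
      seg <- epoch_set$epochs[tr, , s0:(s0 + nseg - 1L), drop = FALSE]
      seg <- matrix(seg, nrow = n_ch)          # channels x nseg
      seg <- seg - rowMeans(seg)               # remove per-segment DC
      Fm <- stats::mvfft(t(seg * rep(win, each = n_ch)))  # nseg x channels
      Fm <- Fm[seq_len(nfreq), , drop = FALSE]
      for (f in seq_len(nfreq)) {
        v <- Fm[f, ]
        S[, , f] <- S[, , f] + (v %o% Conj(v)) / norm
      }
      total <- total + 1L
    }
  }
  S <- S / total
  structure(list(S = S, freqs = freqs, n_segments = total),
            class = "cross_spectra")
}

hamming_window <- function(n) {
  0.54 - 0.46 * cos(2 * pi * (0:(n - 1)) / (n - 1))
}

#' Imaginary part of coherency
#'
#' `iCoh_xy(f) = Im( S_xy(f) / sqrt(S_xx(f) S_yy(f)) )`. Insensitive to
#' zero-lag (volume-conducted) coupling: any instantaneous linear mixture of
#' sources has real coherency, so its imaginary part vanishes.
#'
#' @param cs a `cross_spectra` object.
#' @return channels x channels x frequency real array (antisymmetric in the
#'   channel pair, zero diagonal). Pairs involving a zero-power channel at a
#'   frequency are `NA` and flagged via the `"n_undefined"` attribute.
#' @export
imaginary_coherence <- function(cs) {
  stopifnot(inherits(cs, "cross_spectra"))
  dims <- dim(cs$S)
  icoh <- array(NA_real_, dim = dims, dimnames = dimnames(cs$S))
  n_undef <- 0L
  for (f in seq_len(dims[3])) {
    p <- Re(diag(cs$S[, , f]))
    denom <- sqrt(p %o% p)
    bad <- denom <= 0
    n_undef <- n_undef + sum(bad & !diag(TRUE, dims[1])) / 2
    v <- Im(cs$S[, , f]) / denom
    v[bad] <- NA_real_
    diag(v) <- 0
    icoh[, , f] <- v
  }
  attr(icoh, "freqs") <- cs$freqs
  attr(icoh, "n_undefined") <- n_undef
  icoh
}

#' Average iCoh over canonical frequency bands
#'
#' Mean over the frequency bins whose centers lie inside each half-open band
#' `[low, high)`.
#'
#' @param icoh per-frequency iCoh array from [imaginary_coherence()], with a
#'   `"freqs"` attribute (or supply `freqs`).
#' @param bands named list of band edges; default [eeg_bands()].
#' @param freqs bin center frequencies in Hz.
#' @param window_role stored role label (`"baseline"` or `"analysis"`).
#' @return object of class `band_coherence`: `icoh` (channels x channels x
#'   band), `bands`, `window_role`.
#' @export
band_average <- function(icoh, bands = eeg_bands(),
                         freqs = attr(icoh, "freqs"),
                         window_role = "analysis") {
  stopifnot(!is.null(freqs))
  nch <- dim(icoh)[1]
  out <- array(NA_real_, dim = c(nch, nch, length(bands)),
               dimnames = list(dimnames(icoh)[[1]], dimnames(icoh)[[2]],
                               names(bands)))
  for (b in seq_along(bands)) {
    sel <- freqs >= bands[[b]][1] & freqs < bands[[b]][2]
    if (!any(sel)) stop("band ", names(bands)[b], " contains no frequency bins")
    out[, , b] <- apply(icoh[, , sel, drop = FALSE], c(1, 2), mean)
  }
  structure(list(icoh = out, bands = bands, window_role = window_role),
            class = "band_coherence")
}

#' Baseline correction: post minus pre
#'
#' Elementwise difference of analysis-window values and baseline-window
#' values (band coherence arrays or named metric vectors).
#'
#' @param post,pre matching `band_coherence` objects or numeric structures.
#' @return same shape as the inputs.
#' @export
baseline_correct <- function(post, pre) {
  if (inherits(post, "band_coherence") && inherits(pre, "band_coherence")) {
    if (!identical(names(post$bands), names(pre$bands)))
      stop("band mismatch between post and pre")
    if (!identical(dim(post$icoh), dim(pre$icoh)))
      stop("shape mismatch between post and pre")
    out <- post
    out$icoh <- post$icoh - pre$icoh
    out$window_role <- "post_minus_pre"
    return(out)
  }
  if (!identical(length(post), length(pre)))
    stop("shape mismatch between post and pre")
  if (!is.null(names(post)) && !is.null(names(pre)) &&
      !identical(names(post), names(pre)))
    stop("band mismatch between post and pre")
  post - pre
}

#' Band iCoh for one epoch set (convenience wrapper)
#'
#' Welch cross-spectra, imaginary coherency and band averaging in one step.
#'
#' @param epoch_set an `epoch_set`.
#' @param bands band list, default [eeg_bands()].
#' @return `band_coherence` object.
#' @export
band_icoh <- function(epoch_set, bands = eeg_bands()) {
  cs <- welch_cross_spectra(epoch_set)
  ic <- imaginary_coherence(cs)
  band_average(ic, bands, window_role = epoch_set$window_role)
}
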