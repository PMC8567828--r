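#' Configuration for the closed-loop slow-wave detector
#'
#' Mirrors an online up-state detector: a running 5-s buffer of 13
#' fronto-parieto-central channels, 1-s moving-average detrending, 500 uV
#' min-to-max artifact rejection, a 0.3 slow-wave/broadband power-ratio gate,
#' second-order Butterworth filtering with a 1-Hz bandwidth around the
#' detected center frequency, and sine fitting with forward projection to the
#' next zero phase (the start of the up-state).
#'
#' @param buffer_len running buffer length in seconds.
#' @param clean_window moving-average detrending window in seconds.
#' @param reject_amp min-to-max artifact rejection threshold in microvolts.
#' @param channel_subset labels averaged into the virtual channel.
#' @param swo_band slow-wave band in Hz.
#' @param broadband broadband range in Hz (upper edge capped at Nyquist).
#' @param power_ratio_threshold gate on band/broadband power (in (0, 1)).
#' @param filter_order Butterworth order of the one-pass design.
#' @param filter_bandwidth bandpass width around the center frequency in Hz.
#' @param min_low_cutoff minimum lower band edge in Hz.
#' @param ramp stimulation ramp up/down time in seconds.
#' @param hop streaming update cadence in seconds.
#' @param refractory minimum separation between markers in seconds; `NULL`
#'   defaults at detection time to one period of the detected frequency.
#' @param defer_one_cycle if `TRUE`, schedule stimulation at the up-state
#'   after the one immediately detected (emulates hardware delay).
#' @return a validated `detector_config` list.
#' @export
detector_config <- function(buffer_len = 5, clean_window = 1,
                            reject_amp = 500,
                            channel_subset = detector_channels(),
                            swo_band = c(0.5, 1.2),
                            broadband = c(0.1, Inf),
                            power_ratio_threshold = 0.3,
                            filter_order = 2L, filter_bandwidth = 1,
                            min_low_cutoff = 0.1, ramp = 0.1,
                            hop = 0.1, refractory = NULL,
                            defer_one_cycle = FALSE) {
  stopifnot(buffer_len > clean_window,
            power_ratio_threshold > 0, power_ratio_threshold < 1,
            filter_bandwidth > 0, hop > 0)
  structure(
    list(buffer_len = buffer_len, clean_window = clean_window,
         reject_amp = reject_amp, channel_subset = channel_subset,
         swo_band = swo_band, broadband = broadband,
         power_ratio_threshold = power_ratio_threshold,
         filter_order = as.integer(filter_order),
         filter_bandwidth = filter_bandwidth,
         min_low_cutoff = min_low_cutoff, ramp = ramp, hop = hop,
         refractory = refractory, defer_one_cycle = defer_one_cycle),
    class = "detector_config"
  )
}

#' Clean a buffer and form the virtual channel
#'
#' Subtracts a trailing (causal) moving average from each channel - the
#' detrending a real-time loop can actually apply, which also leaves the
#' buffer's most recent samples undistorted - drops channels whose
#' min-to-max range exceeds the artifact threshold, and averages the
#' survivors into a single virtual channel.
#'
#' @param buffer channels x samples numeric matrix (one buffer of the
#'   channel subset).
#' @param config a [detector_config()].
#' @param srate sampling rate of the buffer in Hz.
#' @return list: `virtual` (numeric vector, `NULL` if every channel was
#'   rejected), `kept` (logical per channel), `n_rejected`.
#' @export
clean_buffer <- function(buffer, config, srate) {
  buffer <- as.matrix(buffer)
  width <- max(1L, as.integer(round(config$clean_window * srate)))
  cleaned <- t(apply(buffer, 1, function(x)
    x - moving_average(x, width, sides = 1L)))
  if (ncol(buffer) == 1L) cleaned <- t(cleaned)
  ranges <- apply(cleaned, 1, function(x) diff(range(x)))
  kept <- ranges <= config$reject_amp
  virtual <- if (any(kept)) colMeans(cleaned[kept, , drop = FALSE]) else NULL
  list(virtual = virtual, kept = kept, n_rejected = sum(!kept))
}

#' Slow-wave power ratio and center frequency
#'
#' Periodogram of the virtual channel, zero-padded to at least 0.1-Hz
#' resolution. The ratio is slow-wave-band power over broadband power; the
#' center frequency is the power peak inside the slow-wave band.
#'
#' @param virtual numeric vector (one buffer of the virtual channel).
#' @param config a [detector_config()].
#' @param srate sampling rate in Hz.
#' @return list: `ratio` (0 for an all-zero signal), `center_freq` (Hz, `NA`
#'   when the ratio is undefined), `passed` (ratio above threshold).
#' @export
swo_power_ratio <- function(virtual, config, srate) {
  n <- length(virtual)
  nfft <- 2^ceiling(log2(max(n, srate / 0.1)))
  X <- stats::fft(c(virtual, numeric(nfft - n)))
  nhalf <- nfft %/% 2L
  pw <- Mod(X[seq_len(nhalf + 1L)])^2
  freqs <- (0:nhalf) * srate / nfft
  bb_hi <- min(config$broadband[2], srate / 2)
  in_bb <- freqs >= config$broadband[1] & freqs <= bb_hi
  in_swo <- freqs >= config$swo_band[1] & freqs <= config$swo_band[2]
  total <- sum(pw[in_bb])
  if (total <= 0) {
    return(list(ratio = 0, center_freq = NA_real_, passed = FALSE))
  }
  ratio <- sum(pw[in_swo]) / total
  swo_idx <- which(in_swo)
  k <- swo_idx[which.max(pw[swo_idx])]
  cf <- freqs[k]
  # parabolic sub-bin refinement of the peak (log-power), clamped to the band
  if (k > 1L && k < length(freqs)) {
    lp <- log(pmax(pw[(k - 1L):(k + 1L)], .Machine$double.xmin))
    denom <- lp[1] - 2 * lp[2] + lp[3]
    if (is.finite(denom) && denom < 0) {
      delta <- 0.5 * (lp[1] - lp[3]) / denom
      cf <- cf + max(-0.5, min(0.5, delta)) * srate / nfft
      cf <- min(max(cf, config$swo_band[1]), config$swo_band[2])
    }
  }
  list(ratio = ratio, center_freq = cf,
       passed = ratio > config$power_ratio_threshold)
}

#' Band-filter around the center frequency and extract instantaneous phase
#'
#' Zero-phase (forward-backward) second-order Butterworth bandpass of width
#' `filter_bandwidth` centered on `center_freq` (lower edge clamped at
#' `min_low_cutoff`), followed by the Hilbert analytic signal. Phase follows
#' the upcrossing convention: phase 0 at the positive-going zero crossing, so
#' `sin` has phase 0 at t = 0 and `cos` has phase `+pi/2`.
#'
#' @param virtual numeric vector.
#' @param center_freq detected center frequency in Hz.
#' @param config a [detector_config()].
#' @param srate sampling rate in Hz.
#' @param causal if `TRUE`, use the causal one-pass filter (streaming path).
#' @return list: `filtered`, `phase` (radians).
#' @export
instantaneous_phase <- function(virtual, center_freq, config, srate,
                                causal = FALSE) {
  if (center_freq < config$swo_band[1] || center_freq > config$swo_band[2])
    stop("center frequency outside the slow-wave band")
  half <- config$filter_bandwidth / 2
  lo <- max(config$min_low_cutoff, center_freq - half)
  hi <- center_freq + half
  filt <- if (causal) bandpass_causal(virtual, lo, hi, srate, config$filter_order)
          else bandpass_zerophase(virtual, lo, hi, srate, config$filter_order)
  list(filtered = filt, phase = upcrossing_phase(filt))
}

#' Phase response of the causal detector chain at one frequency
#'
#' The streaming path is linear and time-invariant once settled: trailing
#' moving-average subtraction followed by the causal Butterworth bandpass.
#' Its steady-state phase at the center frequency is known in closed form
#' and is subtracted from the fitted sine phase before forward projection,
#' exactly as a deployed closed-loop system compensates its own filters.
#'
#' @param center_freq frequency in Hz.
#' @param config a [detector_config()].
#' @param srate sampling rate in Hz.
#' @return phase of the chain's transfer function in radians.
#' @export
causal_chain_phase <- function(center_freq, config, srate) {
  omega <- 2 * pi * center_freq / srate
  w <- max(1L, as.integer(round(config$clean_window * srate)))
  h_ma <- mean(exp(-1i * omega * (0:(w - 1L))))
  h_detrend <- 1 - h_ma
  half <- config$filter_bandwidth / 2
  lo <- max(config$min_low_cutoff, center_freq - half)
  hi <- center_freq + half
  bf <- signal::butter(config$filter_order, c(lo, hi) / (srate / 2),
                       type = "pass")
  z <- exp(-1i * omega * (seq_along(bf$b) - 1L))
  h_filt <- sum(bf$b * z) / sum(bf$a * exp(-1i * omega * (seq_along(bf$a) - 1L)))
  Arg(h_detrend * h_filt)
}

#' Fit a sine to the filtered buffer and project the next up-state
#'
#' Least-squares fit of `A * sin(2*pi*f_c*t + phi) + c` with the center
#' frequency fixed, then forward projection to the next time after `t_now`
#' where the total phase is 0 (mod 2 pi) - the predicted start of the
#' up-state. The stimulation window covers the predicted up-state (half a
#' period) with the configured ramps inside it.
#'
#' @param filtered filtered buffer (numeric vector).
#' @param center_freq fixed sine frequency in Hz.
#' @param t_now time (s) of the last buffer sample in recording time.
#' @param config a [detector_config()].
#' @param srate sampling rate in Hz.
#' @param power_ratio stored in the event row.
#' @param amp_tol minimum fitted amplitude (microvolts) for a valid event.
#' @param fit_window seconds at the end of the buffer used for the fit
#'   (default 3.5); the leading part of a causally filtered buffer carries
#'   the filter's startup transient and would bias the phase estimate.
#' @param phase_correction known phase of the filtering chain at
#'   `center_freq` (radians, see [causal_chain_phase()]); subtracted from
#'   the fitted phase so the projection refers to the underlying signal,
#'   not the filter output. 0 for zero-phase (offline) filtering.
#' @return one-row data.frame (a detection event) or `NULL` for a degenerate
#'   fit: `marker_time_s, center_freq_hz, stim_onset_s, stim_offset_s,
#'   ramp_s, amplitude, phase, offset, power_ratio`.
#' @export
fit_and_project <- function(filtered, center_freq, t_now, config, srate,
                            power_ratio = NA_real_, amp_tol = 1e-8,
                            fit_window = 3.5, phase_correction = 0) {
  keep <- min(length(filtered), as.integer(round(fit_window * srate)))
  filtered <- filtered[(length(filtered) - keep + 1L):length(filtered)]
  n <- length(filtered)
  t <- t_now - (n - 1:n) / srate            # recording-time axis of the buffer
  w <- 2 * pi * center_freq
  X <- cbind(sin(w * t), cos(w * t), 1)
  beta <- stats::.lm.fit(X, filtered)$coefficients
  A <- sqrt(beta[1]^2 + beta[2]^2)
  if (!is.finite(A) || A < amp_tol) return(NULL)
  phi <- atan2(beta[2], beta[1]) - phase_correction  # y = A sin(w t + phi) + c
  # next t* > t_now with (w t* + phi) = 0 mod 2pi
  k <- ceiling((w * t_now + phi) / (2 * pi) + 1e-12)
  t_star <- (2 * pi * k - phi) / w
  if (t_star <= t_now) t_star <- t_star + 2 * pi / w
  if (isTRUE(config$defer_one_cycle)) t_star <- t_star + 2 * pi / w
  half_period <- 1 / (2 * center_freq)
  data.frame(marker_time_s = t_star, center_freq_hz = center_freq,
             stim_onset_s = t_star, stim_offset_s = t_star + half_period,
             ramp_s = config$ramp, amplitude = A, phase = phi,
             offset = beta[3], power_ratio = power_ratio)
}

#' Run the emulated closed-loop detector over a recording
#'
#' Steps a 5-s buffer through the recording at the configured hop, applying
#' buffer cleaning, the power-ratio gate, center-frequency band filtering
#' (causal, as in the streaming loop), sine fitting and forward projection.
#' A refractory period (default one period of the detected frequency)
#' separates successive markers. Marker placement is identical for Active
#' and Sham; the condition only labels the events.
#'
#' @param recording an [eeg_recording()] containing the channel subset.
#' @param config a [detector_config()].
#' @param condition label attached to the emitted events.
#' @return data.frame of detection events (possibly zero rows), sorted by
#'   marker time; attribute `"n_cycles"` is the number of buffer updates.
#' @export
run_detector <- function(recording, config = detector_config(),
                         condition = "Active") {
  stopifnot(inherits(recording, "eeg_recording"))
  missing_ch <- setdiff(config$channel_subset, recording$labels)
  if (length(missing_ch) > 0)
    stop("recording is missing detector channels: ",
         paste(missing_ch, collapse = ", "))
  srate <- recording$srate
  data <- recording$data[config$channel_subset, , drop = FALSE]
  blen <- as.integer(round(config$buffer_len * srate))
  hop <- max(1L, as.integer(round(config$hop * srate)))
  n <- ncol(data)
  events <- list()
  last_marker <- -Inf
  n_cycles <- 0L
  for (end in seq(blen, n, by = hop)) {
    n_cycles <- n_cycles + 1L
    t_now <- sample_to_time(end, srate)
    buf <- data[, (end - blen + 1L):end, drop = FALSE]
    cb <- clean_buffer(buf, config, srate)
    if (is.null(cb$virtual)) next
    # drop the unsettled first clean_window of the trailing detrend
    settle <- as.integer(round(config$clean_window * srate))
    vbuf <- cb$virtual[-seq_len(min(settle, length(cb$virtual) - 1L))]
    pr <- swo_power_ratio(vbuf, config, srate)
    if (!pr$passed) next
    refractory <- if (is.null(config$refractory)) 1 / pr$center_freq
                  else config$refractory
    ip <- instantaneous_phase(vbuf, pr$center_freq, config, srate,
                              causal = TRUE)
    ev <- fit_and_project(ip$filtered, pr$center_freq, t_now, config, srate,
                          power_ratio = pr$ratio,
                          phase_correction =
                            causal_chain_phase(pr$center_freq, config, srate))
    if (is.null(ev)) next
    if (ev$marker_time_s < last_marker + refractory) next
    if (ev$stim_offset_s > recording_duration(recording)) next
    events[[length(events) + 1L]] <- ev
    last_marker <- ev$marker_time_s
  }
  out <- if (length(events) == 0) {
    data.frame(marker_time_s = numeric(0), center_freq_hz = numeric(0),
               stim_onset_s = numeric(0), stim_offset_s = numeric(0),
               ramp_s = numeric(0), amplitude = numeric(0),
               phase = numeric(0), offset = numeric(0),
               power_ratio = numeric(0))
  } else do.call(rbind, events)
  out$condition <- rep(condition, nrow(out))
  rownames(out) <- NULL
  attr(out, "n_cycles") <- n_cycles
  out
}

#' Offline validation of detector phase locking
#'
#' Extracts epochs around each marker (-5 to +5 s by default) from the raw
#' virtual channel, bandpass filters in the slow-wave range (zero-phase),
#' computes the Hilbert phase at each marker, and submits the marker phases
#' to a v-test against 0 degrees (the up-state start).
#'
#' @param recording an [eeg_recording()].
#' @param markers marker times in seconds (e.g. `events$marker_time_s`).
#' @param config a [detector_config()].
#' @param epoch_half half-width of the validation epoch in seconds.
#' @return list of class `phase_locking_report`: `mean_phase` (rad, wrapped
#'   to (-pi, pi]), `R` (mean resultant length), `v_statistic`, `u`,
#'   `p_value`, `n_markers`, `n_dropped` (markers too close to the edges),
#'   `phases`.
#' @export
validate_phase_locking <- function(recording, markers,
                                   config = detector_config(),
                                   epoch_half = 5) {
  stopifnot(inherits(recording, "eeg_recording"))
  srate <- recording$srate
  dur <- recording_duration(recording)
  ok <- markers >= epoch_half & markers <= dur - epoch_half
  n_dropped <- sum(!ok)
  markers <- markers[ok]
  if (length(markers) < 2L)
    stop("need at least 2 markers with full validation epochs")
  chans <- intersect(config$channel_subset, recording$labels)
  if (length(chans) == 0) chans <- recording$labels
  virtual <- colMeans(recording$data[chans, , drop = FALSE])
  filt <- bandpass_zerophase(virtual, config$swo_band[1], config$swo_band[2],
                             srate, config$filter_order)
  phase <- upcrossing_phase(filt)
  idx <- time_to_sample(markers, srate)
  ph <- phase[idx]
  vt <- v_test(ph, mu = 0)
  structure(
    list(mean_phase = vt$mean_phase, R = vt$R, v_statistic = vt$V, u = vt$u,
         p_value = vt$p_value, n_markers = length(ph), n_dropped = n_dropped,
         phases = ph),
    class = "phase_locking_report"
  )
}

#' @export
print.phase_locking_report <- function(x, ...) {
  cat(sprintf(
    "<phase_locking_report> n = %d markers (%d dropped)\n  mean phase %.1f deg, R = %.3f, V = %.3f, u = %.2f, p = %.3g\n",
    x$n_markers, x$n_dropped, x$mean_phase * 180 / pi, x$R, x$v_statistic,
    x$u, x$p_value))
  invisible(x)
}
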