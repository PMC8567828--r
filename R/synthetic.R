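#' Simulation configuration for the synthetic sleep-EEG cohort
#'
#' Collects and validates every knob of the synthetic-data generator. The
#' defaults define the study conditions emulated throughout the package:
#' slow-wave oscillations (SWOs) drifting inside 0.5-1.2 Hz with up-state-
#' nested 12-15 Hz spindles over 1/f background noise, lagged inter-channel
#' coupling (so the imaginary part of coherency is nonzero), and 100
#' stimulation events per night.
#'
#' @param n_channels number of channels (default the 13 detector channels).
#' @param sampling_rate native rate in Hz (default 500).
#' @param duration recording length in seconds (>= 10).
#' @param swo_freq_range SWO frequency range in Hz, default `c(0.5, 1.2)`.
#' @param swo_amplitude SWO amplitude in microvolts (default 75).
#' @param spindle_band spindle band in Hz, default `c(12, 15)`.
#' @param spindle_amplitude spindle burst amplitude in microvolts (default 10).
#' @param swo_freq_walk random-walk rate of the SWO instantaneous frequency
#'   in Hz per sqrt(second) (default 0.05: the frequency drifts by about
#'   0.1 Hz over a 5-s buffer, keeping the oscillation narrowband on the
#'   detector's timescale while still exercising center-frequency tracking).
#' @param noise_exponent slope of the 1/f background (power ~ 1/f^exponent).
#' @param noise_sd background noise standard deviation in microvolts.
#' @param coupling_spec list of couplings, each
#'   `list(band = c(lo, hi), channels = <indices>, lag = <s>, strength = <0..1>)`.
#'   Channel `j` of a coupling receives the shared band-limited source delayed
#'   by `(j - 1) * lag` seconds; a positive lag guarantees nonzero imaginary
#'   coherency, a zero lag is pure instantaneous mixing.
#' @param stim_effect_spec list of stimulation effects, each
#'   `list(band = c(lo, hi), channels = <indices>, lag = <s>, effect = <SD units>)`,
#'   applied 3-7 s after each Active stimulation offset.
#' @param n_events stimulation events per night (default 100).
#' @param n_participants cohort size (default 18).
#' @param behavior_link `list(feature = <name>, rho = <target correlation>)`
#'   linking a ground-truth feature to the overnight change in type-2 AUC.
#' @param seed integer master seed; fully determines all output.
#' @return validated `sim_config` list.
#' @export
sim_config <- function(n_channels = 13L,
                       sampling_rate = 500,
                       duration = 60,
                       swo_freq_range = c(0.5, 1.2),
                       swo_amplitude = 75,
                       swo_freq_walk = 0.05,
                       spindle_band = c(12, 15),
                       spindle_amplitude = 10,
                       noise_exponent = 1,
                       noise_sd = 15,
                       coupling_spec = default_coupling_spec(n_channels),
                       stim_effect_spec = list(),
                       n_events = 100L,
                       n_participants = 18L,
                       behavior_link = list(feature = "path_length_beta",
                                            rho = -0.66),
                       seed = 1L) {
  cfg <- list(
    n_channels = as.integer(n_channels), sampling_rate = sampling_rate,
    duration = duration, swo_freq_range = swo_freq_range,
    swo_amplitude = swo_amplitude, swo_freq_walk = swo_freq_walk,
    spindle_band = spindle_band,
    spindle_amplitude = spindle_amplitude, noise_exponent = noise_exponent,
    noise_sd = noise_sd, coupling_spec = coupling_spec,
    stim_effect_spec = stim_effect_spec, n_events = as.integer(n_events),
    n_participants = as.integer(n_participants),
    behavior_link = behavior_link, seed = as.integer(seed)
  )
  nyq <- sampling_rate / 2
  if (duration < 10)
    stop("duration must be at least 10 s (buffer plus one epoch)")
  if (swo_freq_range[1] <= 0 || swo_freq_range[2] <= swo_freq_range[1])
    stop("invalid swo_freq_range")
  if (max(spindle_band) >= nyq)
    stop("sampling_rate must exceed twice the highest band edge")
  for (cp in c(coupling_spec, stim_effect_spec)) {
    if (max(cp$band) >= nyq)
      stop("coupling band outside Nyquist range")
    if (!is.null(cp$strength) && (cp$strength < 0 || cp$strength > 1))
      stop("coupling strength must lie in [0, 1]")
    if (any(cp$channels < 1L) || any(cp$channels > n_channels))
      stop("coupling channel index out of range")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' Default inter-channel coupling: lagged theta and beta sources
#' @param n_channels number of channels available.
#' @return list of coupling specifications (see [sim_config()]).
#' @export
default_coupling_spec <- function(n_channels = 13L) {
  k <- min(6L, n_channels)
  list(
    list(band = c(4, 8),   channels = seq_len(k), lag = 0.02, strength = 0.5),
    list(band = c(16, 30), channels = seq_len(k), lag = 0.015, strength = 0.4)
  )
}

# Deterministic per-participant/condition stream seed below 2^31.
# Arithmetic in doubles (exact below 2^53) so derived seeds can be re-derived
# without integer overflow.
derive_seed <- function(seed, participant, condition_offset = 0L) {
  s <- (as.numeric(seed) %% 2147483629) * 7919 +
    as.numeric(participant) * 131 + as.numeric(condition_offset)
  as.integer(s %% 2147483629)
}

#' Generate one synthetic sleep-EEG recording
#'
#' Builds a channels x samples recording as the sum of 1/f background noise,
#' a common SWO whose frequency performs a reflected random walk inside
#' `swo_freq_range`, spindle bursts amplitude-gated to the SWO up-state
#' (positive half-wave), and lagged shared band-limited sources per
#' `coupling_spec`. The true SWO phase (upcrossing convention: 0 at the start
#' of the up-state) is returned per sample.
#'
#' @param config a [sim_config()].
#' @param participant participant index (enters the derived seed).
#' @param condition `"Active"` or `"Sham"` (labels the stream; the raw signal
#'   statistics are identical across conditions).
#' @return list: `recording` ([eeg_recording()]), `swo_phase` (radians per
#'   sample), `swo_freq` (Hz per sample).
#' @export
generate_sleep_eeg <- function(config, participant = 1L, condition = "Sham") {
  stopifnot(inherits(config, "sim_config"))
  srate <- config$sampling_rate
  n <- as.integer(round(config$duration * srate))
  nch <- config$n_channels
  cond_off <- if (identical(condition, "Active")) 1L else 0L
  set.seed(derive_seed(config$seed, participant, cond_off))

  # SWO instantaneous frequency: reflected Gaussian random walk in-range.
  fr <- config$swo_freq_range
  steps <- stats::rnorm(n, sd = config$swo_freq_walk / sqrt(srate))
  f <- stats::runif(1, fr[1], fr[2]) + cumsum(steps)
  f <- reflect_into(f, fr[1], fr[2])
  theta <- cumsum(2 * pi * f / srate)          # total phase, sin convention
  swo <- config$swo_amplitude * sin(theta)
  gate <- pmax(0, sin(theta))^2                # up-state gate for spindles

  spindle_carrier <- bandlimited_noise(n, config$spindle_band[1],
                                       config$spindle_band[2], srate)
  spindle <- config$spindle_amplitude * gate * spindle_carrier

  data <- matrix(0, nrow = nch, ncol = n)
  for (ch in seq_len(nch)) {
    data[ch, ] <- config$noise_sd * pink_noise(n, config$noise_exponent) +
      swo + spindle
  }
  for (cp in config$coupling_spec) {
    src <- bandlimited_noise(n, cp$band[1], cp$band[2], srate)
    for (j in seq_along(cp$channels)) {
      ch <- cp$channels[j]
      data[ch, ] <- data[ch, ] + cp$strength * config$noise_sd *
        shift_signal(src, (j - 1) * cp$lag * srate)
    }
  }
  labels <- if (nch == 13L) detector_channels() else paste0("ch", seq_len(nch))
  list(
    recording = eeg_recording(data, srate, labels, units = "uV",
                              reference = "simulated common"),
    swo_phase = wrap_pi(theta),
    swo_freq = f
  )
}

# Reflect a random walk into [lo, hi].
reflect_into <- function(x, lo, hi) {
  span <- hi - lo
  y <- (x - lo) %% (2 * span)
  lo + ifelse(y > span, 2 * span - y, y)
}

#' Generate a stimulation-event table
#'
#' Events are spaced evenly through the usable part of the recording with
#' uniform jitter, leaving room for the baseline window before onset and the
#' analysis window after offset.
#'
#' @param config a [sim_config()].
#' @param condition condition label stored in the table.
#' @param stim_duration stimulation length in seconds (default 0.5, roughly
#'   one SWO up-state).
#' @param seed optional seed; defaults to the config seed.
#' @return data.frame `(onset_s, offset_s, condition)`, sorted by onset.
#' @export
generate_events <- function(config, condition = "Active", stim_duration = 0.5,
                            seed = config$seed) {
  set.seed(derive_seed(seed, 999L))
  lead <- 7.5                                   # room for -6.4 s baseline
  tail <- stim_duration + 7.5                   # room for +7 s analysis
  usable <- config$duration - lead - tail
  n_ev <- config$n_events
  if (usable <= 0) stop("recording too short for any stimulation event")
  n_ev <- min(n_ev, max(1L, floor(usable / 12)))
  centers <- lead + usable * (seq_len(n_ev) - 0.5) / n_ev
  jitter <- stats::runif(n_ev, -0.3, 0.3) * usable / n_ev
  onset <- sort(centers + jitter)
  data.frame(onset_s = onset, offset_s = onset + stim_duration,
             condition = condition, stringsAsFactors = FALSE)
}

#' Inject a post-stimulation connectivity effect
#'
#' For each Active event, adds lagged shared band-limited sources to the
#' specified channels inside the analysis window 3-7 s after stimulation
#' offset, scaled by `effect` standard deviations of the background noise.
#' Pre-event windows are untouched; Sham events pass through unchanged.
#'
#' @param recording an [eeg_recording()].
#' @param events event table from [generate_events()].
#' @param spec list of effects (see `stim_effect_spec` in [sim_config()]).
#' @param noise_sd the background noise scale in microvolts that defines one
#'   SD unit of effect (default: median per-channel SD of the recording).
#' @param seed seed for the injected sources.
#' @return modified `eeg_recording`; attribute `"n_overlapping"` counts
#'   post-stimulation windows that overlap the next event (flagged with a
#'   warning but still injected).
#' @export
inject_stim_effect <- function(recording, events, spec,
                               noise_sd = stats::median(apply(recording$data, 1, stats::sd)),
                               seed = 1L) {
  stopifnot(inherits(recording, "eeg_recording"))
  srate <- recording$srate
  n <- ncol(recording$data)
  dur <- recording_duration(recording)
  if (any(events$onset_s < 0) || any(events$offset_s > dur))
    stop("events must lie within the recording")
  active <- events[events$condition == "Active", , drop = FALSE]
  n_overlap <- 0L
  if (nrow(active) > 0 && length(spec) > 0) {
    set.seed(derive_seed(seed, 555L))
    win <- cbind(active$offset_s + 3, active$offset_s + 7)
    if (nrow(active) > 1) {
      nxt <- c(active$onset_s[-1], Inf)
      n_overlap <- sum(win[, 2] > nxt)
      if (n_overlap > 0)
        warning(sprintf("%d post-stimulation windows overlap the next event",
                        n_overlap))
    }
    for (sp in spec) {
      if (max(sp$band) >= srate / 2) stop("effect band outside Nyquist range")
      for (ev in seq_len(nrow(win))) {
        i0 <- time_to_sample(win[ev, 1], srate)
        i1 <- min(time_to_sample(win[ev, 2], srate) - 1L, n)
        if (i1 - i0 + 1L < srate) next           # clipped too hard, skip
        len <- i1 - i0 + 1L
        src <- bandlimited_noise(len, sp$band[1], sp$band[2], srate)
        for (j in seq_along(sp$channels)) {
          ch <- sp$channels[j]
          add <- sp$effect * noise_sd *
            shift_signal(src, (j - 1) * sp$lag * srate)
          recording$data[ch, i0:i1] <- recording$data[ch, i0:i1] + add
        }
      }
    }
  }
  attr(recording, "n_overlapping") <- n_overlap
  recording
}

#' Correlation structure of the 48 graph-metric features
#'
#' Graph metrics computed from one connectivity matrix are strongly
#' inter-dependent: characteristic path length, radius and diameter are all
#' functions of the same distance matrix; global efficiency is their inverse
#' counterpart; density and mean coherence both track overall coupling
#' strength. The default feature correlation is therefore a Kronecker
#' product `R_band (x) R_metric` of an exchangeable between-band block and a
#' structured within-band metric block encoding exactly those dependencies -
#' the collinearity the modeling stage's pruning step exists to handle.
#'
#' @param band_cor between-band correlation of the same metric (default 0.3).
#' @return 48 x 48 positive-definite correlation matrix in
#'   [feature_names()] order.
#' @export
feature_correlation_matrix <- function(band_cor = 0.3) {
  metrics <- feature_metrics()
  m <- diag(8)
  dimnames(m) <- list(metrics, metrics)
  set2 <- function(a, b, v) {
    m[a, b] <<- v
    m[b, a] <<- v
  }
  set2("path_length", "radius", 0.75)
  set2("path_length", "diameter", 0.75)
  set2("radius", "diameter", 0.6)
  set2("global_efficiency", "path_length", -0.7)
  set2("global_efficiency", "radius", -0.55)
  set2("global_efficiency", "diameter", -0.55)
  set2("global_efficiency", "density", 0.6)
  set2("global_efficiency", "mean_coherence", 0.5)
  set2("density", "mean_coherence", 0.75)
  set2("clustering", "global_efficiency", 0.45)
  set2("clustering", "density", 0.45)
  set2("clustering", "mean_coherence", 0.4)
  set2("clustering", "path_length", -0.35)
  set2("clustering", "radius", -0.3)
  set2("clustering", "diameter", -0.3)
  set2("modularity", "path_length", 0.3)
  set2("modularity", "radius", 0.25)
  set2("modularity", "diameter", 0.25)
  set2("modularity", "global_efficiency", -0.35)
  set2("modularity", "density", -0.3)
  set2("modularity", "mean_coherence", -0.25)
  set2("modularity", "clustering", -0.2)
  set2("path_length", "density", -0.5)
  set2("radius", "density", -0.4)
  set2("diameter", "density", -0.4)
  set2("path_length", "mean_coherence", -0.4)
  set2("radius", "mean_coherence", -0.35)
  set2("diameter", "mean_coherence", -0.35)
  while (min(eigen(m, symmetric = TRUE, only.values = TRUE)$values) < 1e-6) {
    m <- 0.95 * m + 0.05 * diag(8)   # shrink toward identity until PD
  }
  rb <- matrix(band_cor, 6, 6)
  diag(rb) <- 1
  sigma <- kronecker(rb, m)          # feature_names() order: metric fastest
  dimnames(sigma) <- list(feature_names(), feature_names())
  sigma
}

#' Generate a synthetic feature-table pair (Active, Sham)
#'
#' Fast fixture for the modeling stage: multivariate-normal features with the
#' block correlation structure of [feature_correlation_matrix()] (or a
#' caller-supplied one) and mean shifts for named features in the Active
#' condition, bypassing signal simulation.
#'
#' @param n_participants rows per condition.
#' @param effect_spec named numeric vector: effect size (in SD units) added to
#'   those features in the Active condition. Names must be among
#'   [feature_names()].
#' @param seed integer seed.
#' @param feature_cor correlation structure: either a 48 x 48 positive-
#'   definite matrix or a single exchangeable correlation value; default
#'   [feature_correlation_matrix()].
#' @return data.frame with columns `participant`, `condition`, and the 48
#'   features.
#' @export
generate_feature_table <- function(n_participants = 18L,
                                   effect_spec = numeric(0),
                                   seed = 1L,
                                   feature_cor = feature_correlation_matrix()) {
  fn <- feature_names()
  p <- length(fn)
  if (length(effect_spec) > 0) {
    bad <- setdiff(names(effect_spec), fn)
    if (length(bad) > 0)
      stop("unknown features in effect_spec: ", paste(bad, collapse = ", "))
  }
  sigma <- if (is.matrix(feature_cor)) feature_cor
           else { s <- matrix(feature_cor, p, p); diag(s) <- 1; s }
  ch <- tryCatch(chol(sigma),
                 error = function(e) stop("requested feature correlation matrix is not positive definite"))
  set.seed(derive_seed(seed, 777L))
  draw <- function(n) matrix(stats::rnorm(n * p), n, p) %*% ch
  act <- draw(n_participants)
  shm <- draw(n_participants)
  colnames(act) <- colnames(shm) <- fn
  if (length(effect_spec) > 0)
    act[, names(effect_spec)] <- sweep(act[, names(effect_spec), drop = FALSE],
                                       2, effect_spec, "+")
  rbind(
    data.frame(participant = seq_len(n_participants), condition = "Active",
               act, check.names = FALSE),
    data.frame(participant = seq_len(n_participants), condition = "Sham",
               shm, check.names = FALSE)
  )
}

#' Generate confidence-rating behavior linked to a feature
#'
#' Produces pre- and post-sleep trial tables (binary correctness plus integer
#' confidence 1-10) for each participant such that the overnight change in
#' type-2 ROC AUC correlates with the supplied feature values at the target
#' correlation. The link is a Gaussian copula: the latent overnight
#' sensitivity shift is `rho * z(feature) + sqrt(1 - rho^2) * noise`.
#' Confidence is a 10-bin discretization of a latent evidence variable whose
#' separation between correct and incorrect trials fixes the session's
#' target type-2 AUC via `AUC = pnorm(delta / sqrt(2))`.
#'
#' With `exact = TRUE` (default) the copula noise is residualized against
#' the feature and rescaled so the *sample* correlation between feature and
#' target overnight change equals `rho` exactly - the generated cohort then
#' mirrors an observed correlation rather than drawing one from its sampling
#' distribution (trial-sampling noise still attenuates the measured value
#' slightly). Requires `n >= 3`; an unreachable construction is an error,
#' never silently clipped.
#'
#' @param feature numeric vector, one ground-truth feature value per
#'   participant.
#' @param rho target correlation between feature and overnight AUC change
#'   (must lie in `[-1, 1]`; values outside are an error, never clipped).
#' @param n_trials trials per session (default 200).
#' @param auc_pre target pre-sleep type-2 AUC (default 0.55: with an
#'   overnight-change SD of 0.25 on the bounded AUC scale, a mid-scale
#'   starting point is needed so the post-sleep targets rarely hit the
#'   bounds and the constructed link survives intact).
#' @param dauc_mean,dauc_sd mean and SD of the overnight AUC change across
#'   participants (defaults 0.05 and 0.25; an intercept-only predictor of
#'   the change then has RMSE about 0.25, the regime the modeling stage is
#'   built for).
#' @param p_correct probability of a correct response (default 0.7).
#' @param exact pin the sample correlation of the pre-noise target at `rho`
#'   (default `TRUE`); `FALSE` draws the link distributionally.
#' @param seed integer seed.
#' @return list: `trials` (data.frame `participant, session, trial, correct,
#'   confidence`), `targets` (per-participant target pre/post AUC and change).
#' @export
generate_behavior <- function(feature, rho, n_trials = 200L, auc_pre = 0.55,
                              dauc_mean = 0.05, dauc_sd = 0.25,
                              p_correct = 0.7, exact = TRUE, seed = 1L) {
  if (abs(rho) > 1) stop("target correlation must lie in [-1, 1]")
  n <- length(feature)
  set.seed(derive_seed(seed, 333L))
  z <- as.numeric(scale(feature))
  if (any(!is.finite(z))) stop("feature has zero variance; link correlation unreachable")
  eps <- stats::rnorm(n)
  if (isTRUE(exact)) {
    if (n < 3L) stop("exact link correlation unreachable for n < 3")
    res <- stats::residuals(stats::lm(eps ~ z))
    if (stats::sd(res) == 0) stop("exact link correlation unreachable: degenerate residual")
    eps <- as.numeric(scale(res))
    z <- as.numeric(scale(z))  # idempotent; keeps the construction explicit
  }
  latent <- rho * z + sqrt(1 - rho^2) * eps
  dauc <- dauc_mean + dauc_sd * latent
  auc_post <- pmin(pmax(auc_pre + dauc, 0.02), 0.98)
  targets <- data.frame(participant = seq_len(n), auc_pre_target = auc_pre,
                        auc_post_target = auc_post,
                        dauc_target = auc_post - auc_pre)
  one_session <- function(pid, session, auc_target) {
    delta <- sqrt(2) * stats::qnorm(pmin(pmax(auc_target, 0.001), 0.999))
    correct <- stats::rbinom(n_trials, 1L, p_correct)
    evidence <- stats::rnorm(n_trials, mean = ifelse(correct == 1L, delta, 0))
    # fixed monotone binning of the evidence mixture into confidence 1..10
    cuts <- stats::qnorm(seq(0.1, 0.9, by = 0.1), mean = delta / 2,
                         sd = sqrt(1 + delta^2 / 4))
    conf <- findInterval(evidence, cuts) + 1L
    data.frame(participant = pid, session = session,
               trial = seq_len(n_trials), correct = correct,
               confidence = conf)
  }
  trials <- do.call(rbind, lapply(seq_len(n), function(i) {
    rbind(one_session(i, "presleep", auc_pre),
          one_session(i, "postsleep", auc_post[i]))
  }))
  rownames(trials) <- NULL
  list(trials = trials, targets = targets)
}

#' Generate a full synthetic cohort
#'
#' Assembles recordings, event tables, stimulation effects and linked
#' behavior for `n_participants` under Active and Sham conditions. Active and
#' Sham recordings share their generative statistics and differ only through
#' `stim_effect_spec`; the per-participant effect ground truth and the
#' feature-behavior link are returned for recovery scoring.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort`: `recordings` (nested by
#'   participant then condition), `events` (same nesting), `behavior`
#'   (from [generate_behavior()]), `ground_truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  parts <- seq_len(config$n_participants)
  latent_seed <- derive_seed(config$seed, 111L)
  set.seed(latent_seed)
  latent_feature <- stats::rnorm(config$n_participants)
  recordings <- events <- vector("list", config$n_participants)
  for (i in parts) {
    rec <- list()
    evs <- list()
    for (cond in c("Active", "Sham")) {
      g <- generate_sleep_eeg(config, i, cond)
      ev <- generate_events(config, cond,
                            seed = derive_seed(config$seed, i,
                                               if (cond == "Active") 21L else 22L))
      r <- g$recording
      if (cond == "Active" && length(config$stim_effect_spec) > 0) {
        r <- inject_stim_effect(r, ev, config$stim_effect_spec,
                                noise_sd = config$noise_sd,
                                seed = derive_seed(config$seed, i, 31L))
      }
      rec[[cond]] <- list(recording = r, swo_phase = g$swo_phase)
      evs[[cond]] <- ev
    }
    recordings[[i]] <- rec
    events[[i]] <- evs
  }
  behavior <- generate_behavior(latent_feature, config$behavior_link$rho,
                                seed = derive_seed(config$seed, 444L))
  structure(
    list(recordings = recordings, events = events, behavior = behavior,
         ground_truth = list(latent_feature = latent_feature,
                             behavior_link = config$behavior_link,
                             stim_effect_spec = config$stim_effect_spec)),
    class = "synthetic_cohort"
  )
}
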