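test_that("config validation enforces the generator invariants", {
  expect_error(sim_config(duration = 5), "10 s")
  expect_error(sim_config(sampling_rate = 20), "Nyquist|twice")
  expect_error(sim_config(coupling_spec = list(
    list(band = c(300, 400), channels = 1:2, lag = 0.02, strength = 0.5))),
    "Nyquist")
  expect_error(sim_config(coupling_spec = list(
    list(band = c(4, 8), channels = 1:2, lag = 0.02, strength = 1.5))),
    "strength")
  expect_silent(sim_config())
})

test_that("same seed and config give bit-identical recordings", {
  sc <- sim_config(duration = 12, seed = 77)
  g1 <- generate_sleep_eeg(sc, participant = 2, condition = "Active")
  g2 <- generate_sleep_eeg(sc, participant = 2, condition = "Active")
  expect_identical(g1$recording$data, g2$recording$data)
  expect_identical(g1$swo_phase, g2$swo_phase)
  # different participant: different stream
  g3 <- generate_sleep_eeg(sc, participant = 3, condition = "Active")
  expect_false(identical(g1$recording$data, g3$recording$data))
})

test_that("strong SWO passes the power-ratio gate on most windows", {
  sc <- sim_config(duration = 40, swo_amplitude = 150, noise_sd = 10,
                   seed = 4)
  g <- generate_sleep_eeg(sc, 1, "Sham")
  cfg <- detector_config()
  srate <- sc$sampling_rate
  passes <- vapply(seq(5, 40, by = 5), function(end) {
    i1 <- end * srate
    buf <- g$recording$data[cfg$channel_subset, (i1 - 5 * srate + 1):i1]
    cb <- clean_buffer(buf, cfg, srate)
    swo_power_ratio(cb$virtual, cfg, srate)$ratio > 0.3
  }, logical(1))
  expect_gt(mean(passes), 0.7)
  # ground-truth SWO frequency stays in range
  expect_true(all(g$swo_freq >= 0.5 & g$swo_freq <= 1.2))
})

test_that("zero-lag coupling yields no imaginary coherency, lagged does", {
  mk <- function(lag, seed) {
    sc <- sim_config(duration = 40, n_channels = 4, swo_amplitude = 0,
                     spindle_amplitude = 0,
                     coupling_spec = list(list(band = c(4, 8), channels = 1:4,
                                               lag = lag, strength = 0.9)),
                     seed = seed)
    g <- generate_sleep_eeg(sc, 1, "Sham")
    arr <- array(0, dim = c(4, 4, 2000))
    for (tr in 1:4) {
      arr[tr, , ] <- g$recording$data[, ((tr - 1) * 2000 + 1):(tr * 2000)]
    }
    bc <- band_icoh(make_epoch_set(arr, sc$sampling_rate))
    abs(bc$icoh[1, 2, "theta"])
  }
  lagged <- vapply(1:6, function(s) mk(0.02, s), 0)
  zero <- vapply(1:6, function(s) mk(0, s), 0)
  expect_gt(mean(lagged), 3 * mean(zero))
  expect_lt(mean(zero), 0.1)
})

test_that("stimulation effects are injected only after Active events", {
  sc <- sim_config(duration = 60, seed = 6)
  g <- generate_sleep_eeg(sc, 1, "Active")
  ev <- generate_events(sc, "Active", seed = 6)
  spec <- list(list(band = c(4, 8), channels = 1:6, lag = 0.02, effect = 2))
  out <- inject_stim_effect(g$recording, ev, spec, seed = 6)
  # effect size 0: output identical to input
  spec0 <- list(list(band = c(4, 8), channels = 1:6, lag = 0.02, effect = 0))
  out0 <- inject_stim_effect(g$recording, ev, spec0, seed = 6)
  expect_equal(out0$data, g$recording$data)
  # Sham events: pass through unchanged
  ev_sham <- ev; ev_sham$condition <- "Sham"
  out_sham <- inject_stim_effect(g$recording, ev_sham, spec, seed = 6)
  expect_identical(out_sham$data, g$recording$data)
  # pre-event windows untouched; post windows changed
  srate <- sc$sampling_rate
  pre_idx <- upstate:::time_to_sample(ev$onset_s[1] - 6.4, srate):
    upstate:::time_to_sample(ev$onset_s[1] - 2.4, srate)
  post_idx <- upstate:::time_to_sample(ev$offset_s[1] + 3, srate):
    upstate:::time_to_sample(ev$offset_s[1] + 6, srate)
  expect_identical(out$data[1, pre_idx], g$recording$data[1, pre_idx])
  expect_false(identical(out$data[1, post_idx], g$recording$data[1, post_idx]))
  # events outside the recording are rejected
  bad <- data.frame(onset_s = 100, offset_s = 100.5, condition = "Active")
  expect_error(inject_stim_effect(g$recording, bad, spec), "within")
})

test_that("injected theta effect raises post-minus-pre theta iCoh for Active only", {
  post_pre_theta <- function(seed, active) {
    sc <- sim_config(duration = 60, n_channels = 6, swo_amplitude = 30,
                     coupling_spec = list(list(band = c(4, 8), channels = 1:6,
                                               lag = 0.02, strength = 0.3)),
                     seed = seed)
    g <- generate_sleep_eeg(sc, 1, if (active) "Active" else "Sham")
    ev <- generate_events(sc, if (active) "Active" else "Sham", seed = seed)
    rec <- if (active) {
      inject_stim_effect(g$recording, ev,
                         list(list(band = c(4, 8), channels = 1:6,
                                   lag = 0.02, effect = 2)),
                         noise_sd = sc$noise_sd, seed = seed)
    } else g$recording
    pp <- preprocess(rec)
    eps <- extract_epochs(pp, ev)
    d <- baseline_correct(band_icoh(eps$analysis), band_icoh(eps$baseline))
    m <- abs(d$icoh[, , "theta"])
    mean(m[upper.tri(m)] * sign(d$icoh[, , "theta"][upper.tri(m)]))
  }
  act <- vapply(1:8, function(s) post_pre_theta(s, TRUE), 0)
  shm <- vapply(1:8, function(s) post_pre_theta(s, FALSE), 0)
  # sign test: Active shifts are positive (more theta coupling after stim)
  expect_gte(mean(act > 0), 0.875)
  expect_gt(mean(act), mean(shm) + 2 * sd(shm) / sqrt(8))
})

test_that("feature tables have 48 columns with requested shifts", {
  eff <- c(mean_coherence_theta = 1, path_length_beta = -0.5)
  ft <- generate_feature_table(18, eff, seed = 3)
  expect_equal(ncol(ft), 50L)    # participant, condition + 48
  expect_equal(nrow(ft), 36L)
  expect_setequal(unique(ft$condition), c("Active", "Sham"))
  expect_identical(setdiff(names(ft), c("participant", "condition")),
                   feature_names())
  # determinism
  expect_identical(ft, generate_feature_table(18, eff, seed = 3))
  # average injected shift recovered over seeds
  set.seed(1)
  shifts <- vapply(1:30, function(s) {
    f <- generate_feature_table(18, eff, seed = s)
    mean(f$mean_coherence_theta[f$condition == "Active"]) -
      mean(f$mean_coherence_theta[f$condition == "Sham"])
  }, 0)
  expect_equal(mean(shifts), 1, tolerance = 0.15)
  expect_error(generate_feature_table(10, c(not_a_feature = 1)), "unknown")
  expect_error(generate_feature_table(10, feature_cor = 1.2), "positive definite")
})

test_that("behavior generator controls type-2 AUC and the feature link", {
  # perfect and chance metacognition
  expect_equal(type2_auc(c(1, 1, 0, 0), c(10, 10, 1, 1))$auc, 1.0)
  set.seed(2)
  chance <- type2_auc(rbinom(2000, 1, 0.7), sample(1:10, 2000, TRUE))$auc
  expect_equal(chance, 0.5, tolerance = 0.05)
  # requested AUC hit within 0.05 at n_trials >= 200
  beh <- generate_behavior(rnorm(30), rho = 0, n_trials = 400,
                           auc_pre = 0.75, dauc_sd = 0, dauc_mean = 0,
                           seed = 9)
  st <- sensitivity_table(beh$trials)
  expect_equal(mean(st$auc), 0.75, tolerance = 0.05)
  expect_true(all(beh$trials$confidence %in% 1:10))
  expect_error(generate_behavior(rnorm(10), rho = -1.2), "\\[-1, 1\\]")
})

test_that("the built-in link reproduces the target feature-behavior correlation", {
  rs <- vapply(1:25, function(s) {
    feature <- rnorm(18)
    beh <- generate_behavior(feature, rho = -0.66, seed = s)
    dd <- overnight_dauc(beh$trials)
    cor(feature, dd$dauc)
  }, 0)
  expect_equal(mean(rs), -0.66, tolerance = 0.15)
})

test_that("cohort generation is deterministic with consistent structure", {
  sc <- sim_config(duration = 30, n_participants = 3, n_events = 2, seed = 21)
  coh <- generate_cohort(sc)
  expect_length(coh$recordings, 3L)
  expect_named(coh$recordings[[1]], c("Active", "Sham"))
  ev <- coh$events[[1]]$Active
  dur <- recording_duration(coh$recordings[[1]]$Active$recording)
  expect_true(all(ev$onset_s > 0 & ev$offset_s < dur))
  expect_equal(nrow(coh$behavior$targets), 3L)
  coh2 <- generate_cohort(sc)
  expect_identical(coh$recordings[[2]]$Sham$recording$data,
                   coh2$recordings[[2]]$Sham$recording$data)
  expect_identical(coh$behavior$trials, coh2$behavior$trials)
})
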