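test_that("preprocessing re-references, filters and decimates correctly", {
  srate <- 500
  t <- seq(0, 20 - 1 / srate, by = 1 / srate)
  x10 <- sin(2 * pi * 10 * t)
  x100 <- sin(2 * pi * 100 * t)
  data <- rbind(x10, x100, 0.5 * x10, -x10)
  rec <- eeg_recording(data, srate, paste0("ch", 1:4))
  pp <- preprocess(rec)
  expect_equal(pp$srate, 250)
  expect_equal(ncol(pp$data), length(t) / 2)
  # average reference: instantaneous sum across channels ~ 0
  expect_lt(max(abs(colSums(pp$data))), 1e-8)
  # 10 Hz survives decimation within 1% (compare interior amplitude)
  rec10 <- eeg_recording(rbind(x10, -x10), srate, c("a", "b"))
  pp10 <- preprocess(rec10)
  mid <- 500:2000
  amp <- sqrt(2 * mean(pp10$data[1, mid]^2))
  expect_equal(amp, 1, tolerance = 0.01)
  # 100 Hz attenuated by > 12 dB relative to 10 Hz by the 0.1-70 Hz filter
  rec_both <- eeg_recording(rbind(x10 + x100, -(x10 + x100)), srate, c("a", "b"))
  ppb <- preprocess(rec_both)
  spec_at <- function(x, f, sr) {
    n <- length(x)
    abs(sum(x * exp(-2i * pi * f * (0:(n - 1)) / sr))) / n
  }
  a10 <- spec_at(ppb$data[1, mid], 10, 250)
  a100 <- spec_at(ppb$data[1, mid], 100, 250)
  expect_gt(20 * log10(a10 / a100), 12)
  expect_error(preprocess(eeg_recording(matrix(x10, 1), srate, "a")),
               "2 channels")
})

test_that("epoch windows follow the baseline/analysis definitions", {
  srate <- 250
  n <- 120 * srate
  rec <- eeg_recording(rbind(seq_len(n), seq_len(n)), srate, c("a", "b"))
  events <- data.frame(onset_s = c(100), offset_s = c(100.5))
  eps <- extract_epochs(rec, events)
  # baseline covers [onset - 6.4, onset - 2.4) = [93.6, 97.6) s
  first_sample <- eps$baseline$epochs[1, 1, 1]
  expect_equal(unname((first_sample - 1) / srate), 93.6)
  expect_equal(dim(eps$baseline$epochs)[3], 4 * srate)
  first_a <- eps$analysis$epochs[1, 1, 1]
  expect_equal(unname((first_a - 1) / srate), 103.5)
  # event too close to the start is dropped
  ev2 <- data.frame(onset_s = c(3, 100), offset_s = c(3.5, 100.5))
  eps2 <- extract_epochs(rec, ev2)
  expect_equal(eps2$baseline$n_dropped, 1L)
  expect_equal(eps2$baseline$event_index, 2L)
  # analysis window overlapping the next stimulation is dropped
  ev3 <- data.frame(onset_s = c(50, 55), offset_s = c(50.5, 55.5))
  eps3 <- extract_epochs(rec, ev3)
  expect_equal(eps3$analysis$event_index, 2L)
  expect_error(extract_epochs(rec, data.frame(onset_s = 3, offset_s = 3.5)),
               "no surviving")
})

test_that("Welch cross-spectra are Hermitian with correct peak and resolution", {
  srate <- 250
  set.seed(5)
  n <- 1000
  arr <- array(rnorm(2 * n), dim = c(1, 2, n))
  t <- (0:(n - 1)) / srate
  arr[1, 1, ] <- sin(2 * pi * 10 * t)
  eps <- make_epoch_set(arr, srate)
  cs <- welch_cross_spectra(eps)
  expect_equal(cs$freqs[2] - cs$freqs[1], 250 / 512)
  # Hermitian symmetry, real nonnegative diagonal
  for (f in c(5L, 21L, 100L)) {
    expect_equal(cs$S[1, 2, f], Conj(cs$S[2, 1, f]))
    expect_true(all(Re(diag(cs$S[, , f])) >= 0))
    expect_lt(max(abs(Im(diag(cs$S[, , f])))), 1e-14)
  }
  psd1 <- Re(cs$S[1, 1, ])
  expect_equal(cs$freqs[which.max(psd1)], 10, tolerance = 250 / 512)
})

test_that("white-noise coherency magnitude shrinks as segments accumulate", {
  set.seed(8)
  srate <- 250
  few <- welch_cross_spectra(white_noise_epochs(4, 2, 1024, srate))
  many <- welch_cross_spectra(white_noise_epochs(32, 2, 1024, srate))
  coh_mag <- function(cs) {
    mean(abs(cs$S[1, 2, ] / sqrt(Re(cs$S[1, 1, ]) * Re(cs$S[2, 2, ]))))
  }
  expect_equal(few$n_segments, 12L)   # 3 segments per 1024-sample epoch
  expect_gt(coh_mag(few), coh_mag(many))
  # expected |coherency| of independent noise ~ sqrt(pi / (4 n_seg))
  expect_equal(coh_mag(many), sqrt(pi / (4 * many$n_segments)),
               tolerance = 0.35)
  # flat diagonal spectrum within sampling error
  psd <- Re(few$S[1, 1, 5:250])
  expect_lt(sd(psd) / mean(psd), 0.6)
})

test_that("imaginary coherency obeys its analytic identities", {
  set.seed(9)
  srate <- 250
  # quarter-period delay at 10 Hz: iCoh approaches +-1 as noise vanishes
  eps_clean <- delayed_copy_epochs(16, 1024, srate, c(8, 12), 0.025, 0.01)
  cs <- welch_cross_spectra(eps_clean)
  ic <- imaginary_coherence(cs)
  freqs <- attr(ic, "freqs")
  k10 <- which.min(abs(freqs - 10))
  expect_gt(abs(ic[1, 2, k10]), 0.95)
  # self-coherency exactly zero; antisymmetry
  expect_true(all(ic[1, 1, ] == 0))
  expect_equal(ic[1, 2, ], -ic[2, 1, ])
  # |iCoh| <= |coherency| <= 1
  coh <- abs(cs$S[1, 2, ] / sqrt(Re(cs$S[1, 1, ]) * Re(cs$S[2, 2, ])))
  expect_true(all(abs(ic[1, 2, ]) <= coh + 1e-12))
  expect_true(all(coh <= 1 + 1e-12))
  # noisier copy: weaker iCoh
  eps_noisy <- delayed_copy_epochs(16, 1024, srate, c(8, 12), 0.025, 1)
  icn <- imaginary_coherence(welch_cross_spectra(eps_noisy))
  expect_lt(abs(icn[1, 2, k10]), abs(ic[1, 2, k10]))
  # zero-lag scaling: iCoh identically ~0
  arr <- array(0, dim = c(8, 2, 1024))
  for (tr in 1:8) {
    x <- rnorm(1024)
    arr[tr, 1, ] <- x
    arr[tr, 2, ] <- 3 * x
  }
  icz <- imaginary_coherence(welch_cross_spectra(make_epoch_set(arr, srate)))
  expect_lt(max(abs(icz[1, 2, ])), 1e-10)
})

test_that("zero-lag mixtures stay below the matched white-noise floor", {
  set.seed(10)
  srate <- 250
  mix <- band_icoh(zero_lag_mixture_epochs(12, 4, 1024, srate))
  noise <- band_icoh(white_noise_epochs(12, 4, 1024, srate))
  floor_level <- max(mean_abs_band_icoh(noise))
  expect_lt(mean(mean_abs_band_icoh(mix)), floor_level * 1.5)
  expect_lt(mean(mean_abs_band_icoh(mix)), 0.2)
})

test_that("band averaging uses half-open bins and all six bands", {
  freqs <- (0:256) * 250 / 512
  nch <- 3
  ic <- array(rep(freqs, each = nch * nch), dim = c(nch, nch, length(freqs)))
  attr(ic, "freqs") <- freqs
  bc <- band_average(ic)
  expect_equal(dim(bc$icoh)[3], 6L)
  expect_identical(dimnames(bc$icoh)[[3]], names(eeg_bands()))
  # spindle band 12-15 at 0.488 Hz resolution: bins 12.21 .. 14.65
  sel <- freqs[freqs >= 12 & freqs < 15]
  expect_equal(unname(bc$icoh[1, 2, "spindle"]), mean(sel))
  expect_equal(min(sel), 12.20703125)
  expect_equal(max(sel), 14.6484375)
  # constant input averages to itself
  ic2 <- array(0.3, dim = c(2, 2, length(freqs)))
  attr(ic2, "freqs") <- freqs
  expect_true(all(band_average(ic2)$icoh == 0.3))
  expect_error(band_average(ic2, bands = list(empty = c(126, 130)),
                            freqs = freqs), "no frequency bins")
})

test_that("baseline correction subtracts pre from post", {
  arr <- array(0.2, dim = c(3, 3, 6),
               dimnames = list(NULL, NULL, names(eeg_bands())))
  mk <- function(a) structure(list(icoh = a, bands = eeg_bands(),
                                   window_role = "x"),
                              class = "band_coherence")
  pre <- mk(arr)
  post_a <- arr; post_a[, , "theta"] <- post_a[, , "theta"] + 0.1
  d <- baseline_correct(mk(post_a), pre)
  expect_equal(unname(d$icoh[, , "theta"]), matrix(0.1, 3, 3))
  expect_true(all(abs(d$icoh[, , "delta"]) < 1e-15))
  expect_true(all(baseline_correct(pre, pre)$icoh == 0))
  # metric vectors
  m1 <- c(a = 1, b = 2); m2 <- c(a = 1.5, b = 2)
  expect_equal(baseline_correct(m2, m1), c(a = 0.5, b = 0))
  expect_error(baseline_correct(mk(arr[, , 1:5]), pre))
})
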