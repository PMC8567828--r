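# Shared signal fixtures built in code.

make_epoch_set <- function(arr, srate, role = "analysis") {
  structure(list(epochs = arr, window_role = role, window_def = c(0, 0),
                 srate = srate, n_dropped = 0L, event_index = seq_len(dim(arr)[1])),
            class = "epoch_set")
}

# Epochs where channel 2 is channel 1 delayed by `tau` seconds, plus
# independent noise; channel 3 is independent noise.
delayed_copy_epochs <- function(n_trials, n_samples, srate, band, tau,
                                noise_sd) {
  arr <- array(0, dim = c(n_trials, 3L, n_samples))
  for (tr in seq_len(n_trials)) {
    src <- upstate:::bandlimited_noise(n_samples, band[1], band[2], srate)
    arr[tr, 1, ] <- src + noise_sd * stats::rnorm(n_samples)
    arr[tr, 2, ] <- upstate:::shift_signal(src, tau * srate) +
      noise_sd * stats::rnorm(n_samples)
    arr[tr, 3, ] <- stats::rnorm(n_samples)
  }
  make_epoch_set(arr, srate)
}

# Zero-lag mixtures of independent sources (volume-conduction surrogate).
zero_lag_mixture_epochs <- function(n_trials, n_channels, n_samples, srate,
                                    n_sources = 4L) {
  arr <- array(0, dim = c(n_trials, n_channels, n_samples))
  mix <- matrix(stats::runif(n_channels * n_sources, -1, 1),
                n_channels, n_sources)
  for (tr in seq_len(n_trials)) {
    src <- matrix(stats::rnorm(n_sources * n_samples), n_sources)
    arr[tr, , ] <- mix %*% src
  }
  make_epoch_set(arr, srate)
}

white_noise_epochs <- function(n_trials, n_channels, n_samples, srate) {
  arr <- array(stats::rnorm(n_trials * n_channels * n_samples),
               dim = c(n_trials, n_channels, n_samples))
  make_epoch_set(arr, srate)
}

# Mean |band iCoh| over off-diagonal pairs, per band.
mean_abs_band_icoh <- function(bc) {
  vapply(seq_len(dim(bc$icoh)[3]), function(b) {
    m <- bc$icoh[, , b]
    mean(abs(m[upper.tri(m)]))
  }, 0)
}
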