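#' Canonical EEG frequency bands
#'
#' The six analysis bands: delta (1-4), theta (4-8), alpha (8-12),
#' spindle (12-15), beta (16-30) and low gamma (40-50) Hz. Bands are treated
#' as half-open intervals `[low, high)` when assigning frequency bins, so
#' abutting edges (e.g. 4 Hz) are never double-counted.
#'
#' @return named list of `c(low, high)` pairs in Hz.
#' @export
eeg_bands <- function() {
  list(
    delta   = c(1, 4),
    theta   = c(4, 8),
    alpha   = c(8, 12),
    spindle = c(12, 15),
    beta    = c(16, 30),
    gamma   = c(40, 50)
  )
}

#' Graph metrics forming the connectivity feature set
#'
#' The eight network measures computed per band: average clustering
#' coefficient, global efficiency, characteristic path length, radius,
#' diameter, modularity, density and mean coherence. (Degree assortativity is
#' also available via [graph_metrics()] but is not part of the default
#' feature set because it is undefined on degree-regular graphs.)
#'
#' @return character vector of metric names.
#' @export
feature_metrics <- function() {
  c("clustering", "global_efficiency", "path_length", "radius",
    "diameter", "modularity", "density", "mean_coherence")
}

#' Names of the 48 connectivity features (metric x band)
#' @return character vector of length 48, `<metric>_<band>`.
#' @export
feature_names <- function() {
  as.vector(outer(feature_metrics(), names(eeg_bands()),
                  function(m, b) paste(m, b, sep = "_")))
}

#' Default fronto-parieto-central detector channels
#' @return character vector of 13 10-20-system labels.
#' @export
detector_channels <- function() {
  c("Cz", "FC1", "FC2", "CP1", "CP2", "Fz", "C4",
    "Pz", "C3", "F3", "F4", "P3", "P4")
}
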