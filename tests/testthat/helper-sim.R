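# Shared fixtures built in code.

# Small, fast cohort for unit tests (full species set, fewer samples/noise).
small_sim_config <- function(seed = 1L, n_per_group = 4L, ...) {
  simulation_config(n_per_group = n_per_group, n_noise_peaks = 100L,
                    seed = seed, ...)
}

# Construct a feature_matrix directly from an intensity matrix and group
# labels (for statistics tests that do not need alignment).
make_fm <- function(intensity, groups, mz = NULL, drift_time = NULL) {
  n <- nrow(intensity)
  if (is.null(mz)) mz <- seq(500, 500 + n - 1)
  if (is.null(drift_time)) drift_time <- rep(8, n)
  ids <- sprintf("F%05d", seq_len(n))
  rownames(intensity) <- ids
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- sprintf("S%02d", seq_len(ncol(intensity)))
  }
  structure(list(
    features = data.frame(feature_id = ids, mz = mz, drift_time = drift_time,
                          charge = 1L, n_samples = rowSums(intensity > 0)),
    intensity = intensity,
    samples = data.frame(sample_id = colnames(intensity), group = groups,
                         site = NA_character_),
    mz_tol_ppm = 8, dt_tol = 0.3, normalization = "none", scalars = NULL),
    class = "feature_matrix")
}

# Map ground-truth species to the best-matching row of a feature matrix.
map_truth_rows <- function(fm, truth, mz_tol_ppm = 8, dt_tol = 0.3) {
  vapply(seq_len(nrow(truth)), function(j) {
    d <- abs(fm$features$mz - truth$mz[j]) / truth$mz[j] * 1e6
    i <- which(d < mz_tol_ppm &
                 abs(fm$features$drift_time - truth$drift_time[j]) < dt_tol)
    if (length(i) == 0) NA_integer_ else i[which.min(d[i])]
  }, integer(1))
}
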