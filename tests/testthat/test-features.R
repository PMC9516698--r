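test_that("charge assignment reads isotopic spacing", {
  # triply charged envelope: spacing 1.00336/3
  pk <- data.frame(mz = c(800.000, 800.33445, 800.66890),
                   drift_time = rep(3.0, 3), intensity = c(100, 95, 50))
  out <- assign_charge(pk)
  expect_equal(out$charge, 3L)
  expect_equal(nrow(out), 1)               # isotopologues collapsed
  expect_equal(out$intensity, 245)         # intensities summed
  # singly charged pair
  pk1 <- data.frame(mz = c(907.772, 908.776), drift_time = c(8.3, 8.3),
                    intensity = c(100, 60))
  expect_equal(assign_charge(pk1)$charge, 1L)
  # isolated peak: no evidence, unassigned
  lone <- data.frame(mz = 500, drift_time = 5, intensity = 10)
  expect_true(is.na(assign_charge(lone)$charge))
  expect_error(assign_charge(data.frame(mz = c(2, 1), drift_time = c(1, 1),
                                        intensity = c(1, 1))), "sorted")
})

test_that("charge assignment respects co-elution and intensity plausibility", {
  # same spacing but different drift time: not an isotopologue
  pk <- data.frame(mz = c(800.000, 801.00336), drift_time = c(3.0, 7.0),
                   intensity = c(100, 60))
  expect_true(all(is.na(assign_charge(pk)$charge)))
  # a 100x more intense "companion" is not a plausible isotopologue
  pk2 <- data.frame(mz = c(800.000, 801.00336), drift_time = c(3.0, 3.0),
                    intensity = c(5, 500))
  out <- assign_charge(pk2)
  expect_equal(nrow(out), 2)
  expect_true(all(is.na(out$charge)))
})

test_that("doubly charged envelopes beat the singly charged reading", {
  # z=2 spacing 0.50168: the z=1 hypothesis only sees every other peak
  mz0 <- 760.123
  pk <- data.frame(mz = mz0 + (0:3) * 1.0033548378 / 2,
                   drift_time = rep(6.2, 4), intensity = c(100, 90, 45, 15))
  out <- assign_charge(pk)
  expect_equal(out$charge, 2L)
})

test_that("alignment merges jittered samples and is order-invariant", {
  set.seed(21)
  base <- data.frame(mz = c(500.1, 650.2, 800.3, 950.4),
                     drift_time = c(4, 5, 8, 9.5),
                     intensity = c(1e4, 2e4, 3e4, 4e4))
  jitter_sample <- function(s) {
    s$mz <- s$mz * (1 + rnorm(nrow(s), 0, 1e-6))
    s$drift_time <- s$drift_time + rnorm(nrow(s), 0, 0.03)
    s$intensity <- s$intensity * runif(nrow(s), 0.5, 2)
    s
  }
  samples <- list(a = jitter_sample(base), b = jitter_sample(base),
                  c = jitter_sample(base))
  fm <- align_features(samples)
  expect_equal(nrow(fm$features), 4)
  expect_true(all(fm$features$n_samples == 3))
  # permuting sample order yields the same consensus rows
  fm2 <- align_features(rev(samples))
  expect_equal(fm2$features$mz, fm$features$mz, tolerance = 1e-12)
  expect_equal(fm2$intensity[, names(samples)], fm$intensity,
               ignore_attr = TRUE)
})

test_that("self-alignment of a duplicated sample is exact", {
  s <- data.frame(mz = c(500, 700, 900), drift_time = c(4, 6, 8),
                  intensity = c(10, 20, 30))
  fm <- align_features(list(x = s, y = s))
  expect_equal(nrow(fm$features), 3)
  expect_true(all(fm$features$n_samples == 2))
  expect_equal(fm$features$mz, s$mz)
  expect_equal(fm$features$drift_time, s$drift_time)
})

test_that("jitter far beyond tolerance fragments rows", {
  s1 <- data.frame(mz = c(500, 700), drift_time = c(4, 6), intensity = c(10, 20))
  s2 <- s1; s2$mz <- s2$mz + 0.5   # ~1000 ppm apart
  fm <- align_features(list(a = s1, b = s2), mz_tol_ppm = 5)
  expect_gte(nrow(fm$features), 4)
  expect_error(align_features(list(a = s1, b = s2), mz_tol_ppm = 0),
               "positive")
  expect_error(align_features(list(a = s1)), "at least 2")
})

test_that("normalization is scale-invariant and idempotent", {
  set.seed(31)
  m <- matrix(rlnorm(60, log(1e4), 0.4), nrow = 10)
  fm <- make_fm(m, groups = rep(c("PD", "control"), each = 3))
  for (method in c("TIC", "reference_scalar")) {
    n1 <- normalize_features(fm, method)
    # doubling one column changes nothing after normalization
    fm2 <- fm; fm2$intensity[, 2] <- fm2$intensity[, 2] * 2
    n2 <- normalize_features(fm2, method)
    expect_equal(n2$intensity, n1$intensity, tolerance = 1e-12)
    # idempotent
    n11 <- normalize_features(n1, method)
    expect_equal(n11$intensity, n1$intensity, tolerance = 1e-9)
  }
  # all-equal columns: scalars are 1
  fme <- make_fm(matrix(rep(c(5, 10, 20), 4), nrow = 3),
                 groups = rep(c("PD", "control"), 2))
  ns <- normalize_features(fme, "reference_scalar")
  expect_equal(unname(ns$scalars), rep(1, 4))
  # zero-intensity column is an error
  fm0 <- fm; fm0$intensity[, 1] <- 0
  expect_error(normalize_features(fm0, "TIC"), "zero total intensity")
})

test_that("a planted fold change survives alignment and normalization", {
  cfg <- small_sim_config(seed = 12, n_per_group = 8L)
  sim <- simulate_cohort(cfg)
  samples <- lapply(sim$samples, function(s) {
    assign_charge(s[, c("mz", "drift_time", "intensity")])
  })
  fm <- normalize_features(align_features(samples, sim$metadata), "TIC")
  rows <- map_truth_rows(fm, sim$truth)
  pd <- fm$samples$group == "PD"
  eff <- which(sim$truth$cluster %in% c(3, 5))
  fc <- rowMeans(fm$intensity[rows[eff], pd]) /
    rowMeans(fm$intensity[rows[eff], !pd])
  # 2x planted effect preserved up to the ~7% TIC share bias and noise
  expect_equal(mean(fc), 2, tolerance = 0.2)
})

test_that("feature matrix accessors and writers work", {
  m <- matrix(c(1, 2, 3, 4), nrow = 2)
  fm <- make_fm(m, groups = c("PD", "control"))
  expect_equal(dim(fm), c(2, 2))
  expect_output(print(fm), "2 features x 2 samples")
  path <- withr::local_tempfile(fileext = ".csv")
  write_feature_matrix(fm, path)
  expect_true(file.exists(path))
  expect_true(file.exists(paste0(path, ".json")))
  back <- utils::read.csv(path)
  expect_equal(nrow(back), 2)
})
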