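# Synthetic PS-IM-MS cohort generator with ground truth.
#
# Emulates the structure of a sebum paper-spray ion-mobility dataset: five
# drift-time clusters of singly/doubly/triply charged lipid envelopes
# (m/z 700-1800), CH2- and saturation-spaced homologous series, 256-Da-spaced
# high-mass envelopes (intact C16H32O2 estolide units), carbon isotope
# envelopes, cohort-specific up-regulation of chosen clusters, ppm-scale m/z
# noise, ms-scale drift noise, uniform baseline noise peaks, and three
# constant-intensity pseudo-internal-standard matrix ions.

#' Class-specific CCS trend
#'
#' Linear CCS vs m/z trend anchored at reference standards: TG at
#' (907.7725 Th, 335.8 Angstrom^2; sodiated TG 54:3) and DG at
#' (509.4200 Th, 243.3 Angstrom^2; protonated DG 28:2). Each double bond
#' relative to the anchor's count subtracts a small CCS decrement.
#'
#' @param lipid_class `"TG"` or `"DG"`.
#' @param mz m/z in Th.
#' @param double_bonds Optional double-bond count; `NULL` applies no
#'   saturation adjustment.
#' @param slope CCS slope in Angstrom^2 per Th (default 0.0587).
#' @param db_decrement CCS decrease per double bond (Angstrom^2, default 0.2).
#' @return CCS in Angstrom^2.
#' @export
ccs_trend <- function(lipid_class, mz, double_bonds = NULL,
                      slope = 0.0587, db_decrement = 0.2) {
  anchor <- switch(lipid_class,
    TG = list(mz = 907.7725, ccs = 335.8, db = 3),
    DG = list(mz = 509.4200, ccs = 243.3, db = 2),
    stop("unknown lipid class for CCS trend: ", lipid_class)
  )
  ccs <- anchor$ccs + slope * (mz - anchor$mz)
  if (!is.null(double_bonds)) {
    ccs <- ccs - db_decrement * (double_bonds - anchor$db)
  }
  ccs
}

#' Default simulated lipid species table
#'
#' One row per species. Clusters follow the five drift-time windows with
#' nominal charges 3, 2, 2, 1, 1. Cluster 4 carries the main TG series
#' (CH2-spaced carbons 49-57, saturation ladder 1-4 double bonds, sodiated);
#' Cluster 5 carries high-mass estolide envelopes (base TG 64:2-68:2 plus 0-2
#' intact C16H32O2 units, 256.24-Da spaced); Cluster 3 large doubly charged
#' monomers (7.01-Th CH2/2 spacing); Clusters 1-2 triply/doubly charged
#' species; a DG series (m/z 500-650) and one unknown ion at 822.61 Th
#' (the PI negative-control species) complete the set.
#'
#' Species with `dt_lo`/`dt_hi` set are placed in that drift band (m/z-ordered
#' linear spacing); others take drift times from [ccs_trend()].
#'
#' @return data.frame of species definitions used by [simulation_config()].
#' @export
default_lipid_series <- function() {
  rows <- list()
  # Cluster 4: sodiated TG series, CH2 and H2 (saturation) spacings
  g <- expand.grid(carbons = 49:57, db = 1:4)
  rows$c4 <- data.frame(
    lipid = sprintf("TG %d:%d", g$carbons, g$db), extra_units = 0L,
    adduct = "+Na", charge = 1L, cluster = 4L, meanlog = log(1e5),
    dt_lo = NA_real_, dt_hi = NA_real_, mz_override = NA_real_)
  # Cluster 5: high-mass singly charged estolide envelopes, 256-Da spaced;
  # middle-heavy intensity profile so each envelope is a unimodal hump
  g <- expand.grid(carbons = 64:68, k = 0:2)
  rows$c5 <- data.frame(
    lipid = sprintf("TG %d:2", g$carbons), extra_units = g$k,
    adduct = "+Na", charge = 1L, cluster = 5L,
    meanlog = log(1e4) - 0.5 * ((g$carbons - 66) / 1.5)^2,
    dt_lo = 9.2, dt_hi = 9.8, mz_override = NA_real_)
  # Cluster 3: large doubly charged monomeric acyl glycerides (7.01 spacing)
  rows$c3 <- data.frame(
    lipid = sprintf("TG %d:4", 90:104), extra_units = 0L,
    adduct = "+H+Na", charge = 2L, cluster = 3L, meanlog = log(1e4),
    dt_lo = 6.05, dt_hi = 6.45, mz_override = NA_real_)
  # Cluster 2: compact doubly charged species
  rows$c2 <- data.frame(
    lipid = sprintf("TG %d:8", seq(92, 100, by = 2)), extra_units = 0L,
    adduct = "+2H", charge = 2L, cluster = 2L, meanlog = log(3e4),
    dt_lo = 3.8, dt_hi = 4.4, mz_override = NA_real_)
  # Cluster 1: triply charged species
  rows$c1 <- data.frame(
    lipid = sprintf("TG %d:6", seq(141, 149, by = 2)), extra_units = 0L,
    adduct = "+3H", charge = 3L, cluster = 1L, meanlog = log(3e4),
    dt_lo = 2.7, dt_hi = 3.3, mz_override = NA_real_)
  # DG series in the m/z 500-650 region (protonated)
  rows$dg <- data.frame(
    lipid = sprintf("DG %d:0", 27:33), extra_units = 0L,
    adduct = "+H", charge = 1L, cluster = NA_integer_, meanlog = log(3e4),
    dt_lo = NA_real_, dt_hi = NA_real_, mz_override = NA_real_)
  # Unknown sebum species at 822.61 Th (near-PI m/z; negative control)
  rows$unk <- data.frame(
    lipid = NA_character_, extra_units = 0L,
    adduct = "+Na", charge = 1L, cluster = 4L, meanlog = log(3e4),
    dt_lo = NA_real_, dt_hi = NA_real_, mz_override = 822.61)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulation configuration
#'
#' Defaults define the package's reference study conditions: 20 samples per
#' cohort, the [default_lipid_series()] species set, 1 ppm m/z noise
#' (lock-mass-corrected instrument scale), 0.05 ms drift noise, log-normal
#' intensities (sdlog 0.5), 500 uniform noise peaks per sample, and +1 log2
#' fold change in the PD cohort for Clusters 3 and 5.
#'
#' @param n_per_group Samples per cohort (>= 2).
#' @param lipid_series Species table as in [default_lipid_series()].
#' @param effect_log2 Named numeric: log2 fold change (PD vs control) per
#'   cluster id.
#' @param mz_noise_ppm m/z jitter standard deviation in ppm (>= 0).
#' @param dt_noise_ms Drift-time jitter standard deviation in ms.
#' @param intensity_sdlog Within-feature log-normal scale (natural-log units).
#' @param n_noise_peaks Uniform baseline noise peaks per sample.
#' @param noise_mean_intensity Mean of the exponential noise intensities.
#' @param n_isotope_peaks Isotopologue peaks emitted per species (>= 2).
#' @param calibration The "true" instrument `ccs_calibration` used to place
#'   species in drift time (and to test calibration recovery end-to-end).
#' @param pseudo_standards data.frame of matrix ions held at effect-free
#'   intensity in both cohorts: defaults to 103.05 Th/1.0 ms, 105.07 Th/1.0 ms
#'   and 109.10 Th/1.2 ms.
#' @param seed Integer seed; the generator is deterministic given the seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 20L,
                              lipid_series = default_lipid_series(),
                              effect_log2 = c("3" = 1, "5" = 1),
                              mz_noise_ppm = 1,
                              dt_noise_ms = 0.05,
                              intensity_sdlog = 0.5,
                              n_noise_peaks = 500L,
                              noise_mean_intensity = 200,
                              n_isotope_peaks = 3L,
                              calibration = default_instrument_calibration(),
                              pseudo_standards = NULL,
                              seed = 1L) {
  if (n_per_group < 2) stop("n_per_group must be >= 2")
  if (mz_noise_ppm < 0 || dt_noise_ms < 0) stop("noise s.d. must be >= 0")
  if (!all(is.finite(effect_log2))) stop("all fold changes must be finite")
  if (nrow(lipid_series) == 0) stop("lipid_series must be non-empty")
  if (is.null(pseudo_standards)) {
    pseudo_standards <- data.frame(
      mz = c(103.05, 105.07, 109.10), drift_time = c(1.0, 1.0, 1.2),
      meanlog = log(5e4), sdlog = 0.3)
  }
  structure(list(n_per_group = as.integer(n_per_group),
                 lipid_series = lipid_series, effect_log2 = effect_log2,
                 mz_noise_ppm = mz_noise_ppm, dt_noise_ms = dt_noise_ms,
                 intensity_sdlog = intensity_sdlog,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mean_intensity = noise_mean_intensity,
                 n_isotope_peaks = as.integer(n_isotope_peaks),
                 calibration = calibration,
                 pseudo_standards = pseudo_standards,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# Resolve the species table into theoretical m/z, carbon counts, CCS and
# drift times under the configured instrument calibration.
resolve_species <- function(cfg) {
  ser <- cfg$lipid_series
  cal <- cfg$calibration
  palmitic <- monoisotopic_mass("C16H32O2")
  n <- nrow(ser)
  mz <- numeric(n); carbons <- integer(n); dbs <- integer(n)
  cls <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(ser$mz_override[i])) {
      mz[i] <- ser$mz_override[i]
      carbons[i] <- 55L   # assumed C count for the isotope model
      dbs[i] <- 3L; cls[i] <- "TG"
      next
    }
    lip <- parse_lipid(ser$lipid[i])
    f <- lipid_formula(lip)
    mass <- monoisotopic_mass(f) + ser$extra_units[i] * palmitic
    mz[i] <- adduct_mz(mass, ser$adduct[i], ser$charge[i])
    carbons[i] <- unclass(f)[["C"]] + 16L * ser$extra_units[i]
    dbs[i] <- lip$double_bonds; cls[i] <- lip$class
  }
  ccs <- numeric(n); dt <- numeric(n)
  banded <- !is.na(ser$dt_lo)
  for (grp in unique(ser$cluster[banded])) {
    idx <- which(banded & (ser$cluster %in% grp))
    lo <- ser$dt_lo[idx[1]]; hi <- ser$dt_hi[idx[1]]
    rng <- range(mz[idx])
    frac <- if (diff(rng) > 0) (mz[idx] - rng[1]) / diff(rng) else 0.5
    dt[idx] <- lo + frac * (hi - lo)
    ccs[idx] <- dt_to_ccs(cal, mz[idx], ser$charge[idx], dt[idx])
  }
  for (i in which(!banded)) {
    ccs[i] <- ccs_trend(cls[i], mz[i], dbs[i])
    dt[i] <- ccs_to_dt(cal, mz[i], ser$charge[i], ccs[i])
  }
  data.frame(species_id = sprintf("sp%03d", seq_len(n)),
             lipid = ifelse(is.na(ser$lipid), "unknown", ser$lipid),
             lipid_class = cls, extra_units = ser$extra_units,
             adduct = ser$adduct, charge = ser$charge, cluster = ser$cluster,
             mz = mz, drift_time = dt, ccs = ccs, carbons = carbons,
             double_bonds = dbs, meanlog = ser$meanlog,
             log2_effect = unname(ifelse(
               is.na(ser$cluster), 0,
               cfg$effect_log2[as.character(ser$cluster)])),
             stringsAsFactors = FALSE)
}

#' Generate a synthetic two-cohort PS-IM-MS dataset
#'
#' Draws per-sample centroided peak lists for a PD and a control cohort from
#' the configured species table, together with a ground-truth manifest. Every
#' non-noise peak is tagged with its species id, so downstream accuracy can be
#' scored exactly. Deterministic under a fixed `cfg$seed`.
#'
#' @param cfg A [simulation_config()].
#' @return A `sim_cohort` object: `samples` (named list of data.frames with
#'   columns `mz`, `drift_time`, `intensity`, `species_id`, `isotope`),
#'   `metadata` (sample_id, group, site), `truth` (species-level manifest with
#'   theoretical m/z, drift time, CCS, charge, cluster, effect), `signal`
#'   (species x sample matrix of emitted signal totals) and `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  stopifnot(inherits(cfg, "simulation_config"))
  set.seed(cfg$seed)
  truth <- resolve_species(cfg)
  truth$log2_effect[is.na(truth$log2_effect)] <- 0
  n_sp <- nrow(truth)
  n <- cfg$n_per_group
  metadata <- data.frame(
    sample_id = c(sprintf("PD_%02d", seq_len(n)),
                  sprintf("CTRL_%02d", seq_len(n))),
    group = rep(c("PD", "control"), each = n),
    site = rep(c("siteA", "siteB"), length.out = 2L * n))
  # isotope envelope shapes per species (relative intensities)
  k <- 0:(cfg$n_isotope_peaks - 1L)
  rel <- lapply(truth$carbons, function(nc) {
    r <- stats::dbinom(k, size = nc, prob = .c13_abundance)
    r / max(r)
  })
  std <- cfg$pseudo_standards
  signal <- matrix(0, n_sp, nrow(metadata),
                   dimnames = list(truth$species_id, metadata$sample_id))
  samples <- vector("list", nrow(metadata))
  names(samples) <- metadata$sample_id
  for (j in seq_len(nrow(metadata))) {
    is_pd <- metadata$group[j] == "PD"
    shift <- if (is_pd) log(2) * truth$log2_effect else rep(0, n_sp)
    base_int <- exp(stats::rnorm(n_sp, truth$meanlog + shift,
                                 cfg$intensity_sdlog))
    dt_j <- truth$drift_time + stats::rnorm(n_sp, 0, cfg$dt_noise_ms)
    sp_mz <- rep(truth$mz, each = length(k)) +
      rep(k, n_sp) * .c13_spacing / rep(truth$charge, each = length(k))
    sp_mz <- sp_mz * (1 + stats::rnorm(length(sp_mz), 0,
                                       cfg$mz_noise_ppm * 1e-6))
    sp_int <- rep(base_int, each = length(k)) * unlist(rel)
    peaks <- data.frame(
      mz = sp_mz,
      drift_time = rep(dt_j, each = length(k)),
      intensity = sp_int,
      species_id = rep(truth$species_id, each = length(k)),
      isotope = rep(k, n_sp))
    signal[, j] <- base_int * vapply(rel, sum, numeric(1))
    # pseudo internal standards: effect-free in both cohorts
    std_peaks <- data.frame(
      mz = std$mz * (1 + stats::rnorm(nrow(std), 0, cfg$mz_noise_ppm * 1e-6)),
      drift_time = std$drift_time + stats::rnorm(nrow(std), 0, cfg$dt_noise_ms),
      intensity = exp(stats::rnorm(nrow(std), std$meanlog, std$sdlog)),
      species_id = sprintf("std%d", seq_len(nrow(std))),
      isotope = 0L)
    noise <- data.frame(
      mz = stats::runif(cfg$n_noise_peaks, 50, 2000),
      drift_time = stats::runif(cfg$n_noise_peaks, 0.5, 12),
      intensity = stats::rexp(cfg$n_noise_peaks,
                              rate = 1 / cfg$noise_mean_intensity),
      species_id = NA_character_, isotope = NA_integer_)
    out <- rbind(peaks, std_peaks, noise)
    out <- out[order(out$mz), ]
    rownames(out) <- NULL
    samples[[j]] <- out
  }
  structure(list(samples = samples, metadata = metadata, truth = truth,
                 signal = signal, config = cfg),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat("Synthetic PS-IM-MS cohort\n")
  cat(sprintf("  %d samples (%d PD / %d control), %d species + %d standards, %d noise peaks/sample\n",
              nrow(x$metadata), sum(x$metadata$group == "PD"),
              sum(x$metadata$group == "control"), nrow(x$truth),
              nrow(x$config$pseudo_standards), x$config$n_noise_peaks))
  eff <- x$truth$log2_effect != 0
  cat(sprintf("  %d species carry a cohort effect (clusters %s)\n", sum(eff),
              paste(sort(unique(x$truth$cluster[eff])), collapse = ", ")))
  invisible(x)
}

#' Simulate a tandem-MS (MSMS) fragment spectrum
#'
#' Produces an observed fragment peak list around the supplied fragment m/z
#' values (small mass jitter) plus uniform low-intensity noise fragments.
#'
#' @param fragment_mz Fragment m/z values to emit.
#' @param precursor_mz Precursor m/z; noise fragments are drawn below it.
#' @param mz_sd Fragment m/z jitter s.d. in Th (default 0.001).
#' @param n_noise Number of noise fragments.
#' @param seed Optional seed.
#' @return data.frame with columns `mz` and `intensity`.
#' @export
simulate_msms <- function(fragment_mz, precursor_mz, mz_sd = 0.001,
                          n_noise = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  frags <- data.frame(
    mz = fragment_mz + stats::rnorm(length(fragment_mz), 0, mz_sd),
    intensity = stats::runif(length(fragment_mz), 5e3, 5e4))
  noise <- data.frame(
    mz = stats::runif(n_noise, 100, precursor_mz - 30),
    intensity = stats::runif(n_noise, 10, 100))
  out <- rbind(frags, noise)
  out[order(out$mz), , drop = FALSE]
}

#' Write a simulated cohort to disk
#'
#' Per-sample peak lists as CSV (`mz`, `drift_time_ms`, `intensity`), sample
#' metadata as CSV, the ground-truth manifest as JSON and the configuration
#' summary as YAML.
#'
#' @param sim A `sim_cohort`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the directory path.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (sid in names(sim$samples)) {
    s <- sim$samples[[sid]]
    utils::write.csv(
      data.frame(mz = s$mz, drift_time_ms = s$drift_time,
                 intensity = s$intensity),
      file.path(dir, paste0(sid, ".csv")), row.names = FALSE)
  }
  utils::write.csv(sim$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  jsonlite::write_json(sim$truth, file.path(dir, "ground_truth.json"),
                       digits = NA, dataframe = "rows")
  cfg <- sim$config
  yaml::write_yaml(list(
    n_per_group = cfg$n_per_group, seed = cfg$seed,
    mz_noise_ppm = cfg$mz_noise_ppm, dt_noise_ms = cfg$dt_noise_ms,
    intensity_sdlog = cfg$intensity_sdlog,
    n_noise_peaks = cfg$n_noise_peaks,
    effect_log2 = as.list(cfg$effect_log2),
    calibration = list(A = cfg$calibration$A, B = cfg$calibration$B,
                       c = cfg$calibration$c, a = cfg$calibration$a)),
    file.path(dir, "config.yaml"))
  invisible(dir)
}
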