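# End-to-end orchestration: simulate (or load) -> charge assignment ->
# alignment -> normalization -> CCS calibration -> clusters/series ->
# differential abundance + QC -> annotation, with a run manifest.

#' Pipeline configuration
#'
#' @param simulation A [simulation_config()], or `NULL` to read peak lists
#'   from `input_dir`.
#' @param input_dir Directory of per-sample CSV peak lists plus
#'   `metadata.csv` (used when `simulation` is `NULL`).
#' @param charge_tol_ppm Isotope-companion tolerance for charge assignment.
#' @param mz_tol_ppm,dt_tol Alignment tolerances (ppm, ms).
#' @param normalization `"TIC"` (default; scale-invariant and robust here
#'   because the differential features carry a small share of total signal)
#'   or `"reference_scalar"` (Progenesis-style median ratio to the
#'   feature-richest run).
#' @param series_tol_ppm Homologous-series spacing tolerance.
#' @param annotation_tol_ppm,annotation_ccs_tol Annotation thresholds
#'   (ppm, percent CCS).
#' @param min_detect_fraction Features must be detected in at least this
#'   fraction of one group's samples to enter the differential stage.
#' @param calibrants Calibrant table for CCS calibration (default: packaged
#'   synthetic set).
#' @param bayes A [bayes_config()].
#' @param seed Master seed; propagated to simulation and sampler seeds.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(simulation = simulation_config(),
                            input_dir = NULL,
                            charge_tol_ppm = 5,
                            mz_tol_ppm = 8, dt_tol = 0.3,
                            normalization = "TIC",
                            series_tol_ppm = 15,
                            annotation_tol_ppm = 10,
                            annotation_ccs_tol = 2,
                            min_detect_fraction = 0.5,
                            calibrants = NULL,
                            bayes = bayes_config(),
                            seed = 1L) {
  if (any(c(charge_tol_ppm, mz_tol_ppm, dt_tol, series_tol_ppm,
            annotation_tol_ppm, annotation_ccs_tol) <= 0)) {
    stop("all tolerances must be positive")
  }
  seed <- as.integer(seed)
  if (!is.null(simulation)) simulation$seed <- seed
  bayes$seed <- seed + 1L
  structure(list(simulation = simulation, input_dir = input_dir,
                 charge_tol_ppm = charge_tol_ppm, mz_tol_ppm = mz_tol_ppm,
                 dt_tol = dt_tol, normalization = normalization,
                 series_tol_ppm = series_tol_ppm,
                 annotation_tol_ppm = annotation_tol_ppm,
                 annotation_ccs_tol = annotation_ccs_tol,
                 min_detect_fraction = min_detect_fraction,
                 calibrants = calibrants, bayes = bayes, seed = seed),
            class = "pipeline_config")
}

read_input_dir <- function(dir) {
  meta_path <- file.path(dir, "metadata.csv")
  if (!file.exists(meta_path)) {
    stop("missing group labels: metadata file not found at ", meta_path)
  }
  metadata <- utils::read.csv(meta_path)
  if (!all(c("sample_id", "group") %in% names(metadata))) {
    stop("metadata.csv must have sample_id and group columns: ", meta_path)
  }
  samples <- lapply(metadata$sample_id, function(sid) {
    read_peaklist(file.path(dir, paste0(sid, ".csv")))
  })
  names(samples) <- metadata$sample_id
  list(samples = samples, metadata = metadata)
}

stage <- function(name, expr) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), name))
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full analysis pipeline
#'
#' Executes simulate/load, per-sample charge assignment, cross-sample
#' alignment, normalization, CCS calibration and conversion, drift-cluster
#' and homologous-series analysis, dimer adduct-hypothesis testing,
#' frequentist and Bayesian differential abundance with pseudo-standard QC,
#' and lipid annotation. When `outdir` is given, all artifacts are written
#' there (feature matrix CSV + sidecar, calibration JSON, cluster/series
#' JSON, differential CSV, QC JSON, annotation CSV, run manifest).
#' Deterministic under a fixed configuration seed.
#'
#' @param cfg A [pipeline_config()].
#' @param outdir Optional output directory.
#' @return Invisible list with all stage results: `sim`, `matrix`,
#'   `calibration`, `clusters`, `series`, `envelopes`, `adduct_hypotheses`,
#'   `differential`, `qc`, `annotations`.
#' @export
run_pipeline <- function(cfg = pipeline_config(), outdir = NULL) {
  stopifnot(inherits(cfg, "pipeline_config"))
  sim <- NULL
  if (!is.null(cfg$simulation)) {
    sim <- stage("simulate", simulate_cohort(cfg$simulation))
    samples <- lapply(sim$samples, function(s) {
      s[, c("mz", "drift_time", "intensity")]
    })
    metadata <- sim$metadata
  } else {
    if (is.null(cfg$input_dir)) stop("either simulation or input_dir is required")
    inp <- stage("load", read_input_dir(cfg$input_dir))
    samples <- inp$samples
    metadata <- inp$metadata
  }
  samples <- stage("assign_charge", lapply(samples, assign_charge,
                                           tol_ppm = cfg$charge_tol_ppm))
  fm_raw <- stage("align", align_features(samples, metadata,
                                          mz_tol_ppm = cfg$mz_tol_ppm,
                                          dt_tol = cfg$dt_tol))
  # QC runs on the raw matrix: pseudo-standards gauge measurement noise and
  # must not be confounded with the cohort-driven TIC shift
  qc <- stage("qc", qc_pseudo_standards(fm_raw))
  fm <- stage("normalize", normalize_features(fm_raw, cfg$normalization))
  calib <- stage("calibrate", {
    calibrants <- if (is.null(cfg$calibrants)) read_calibrants()
                  else cfg$calibrants
    fit_ccs_calibration(calibrants)
  })
  feats <- fm$features
  z_eff <- ifelse(is.na(feats$charge), 1L, feats$charge)
  feats$ccs <- dt_to_ccs(calib, feats$mz, z_eff, feats$drift_time)
  cl <- stage("clusters", assign_clusters(feats$drift_time, feats$charge))
  feats$cluster <- cl$cluster
  fm$features <- feats
  tot <- rowSums(fm$intensity)
  series_report <- stage("series", {
    wins <- drift_clusters()
    out <- list()
    for (i in seq_len(nrow(wins))) {
      sel <- which(feats$cluster == wins$cluster_id[i])
      if (length(sel) < 3) next
      s <- detect_series(feats$mz[sel], unit = "CH2",
                         z = wins$nominal_charge[i],
                         tol_ppm = cfg$series_tol_ppm)
      out[[paste0("cluster", wins$cluster_id[i])]] <- lapply(s, function(x) {
        x$members <- feats$feature_id[sel][x$members]
        x
      })
    }
    out
  })
  env_report <- stage("envelopes", {
    sel <- which(!is.na(feats$charge) & feats$charge == 1L)
    detect_envelopes(feats$mz[sel], tot[sel])
  })
  adduct_report <- stage("adduct_hypotheses", {
    c3 <- which(feats$cluster == 3L & !is.na(feats$charge) &
                  feats$charge == 2L)
    singly <- feats$mz[!is.na(feats$charge) & feats$charge == 1L]
    if (length(c3) == 0 || length(singly) == 0) NULL
    else enumerate_adduct_hypotheses(feats$mz[c3], singly)
  })
  diff_res <- stage("differential", {
    n_test <- sum(metadata$group == "PD")
    n_ref <- sum(metadata$group == "control")
    min_n <- ceiling(cfg$min_detect_fraction * min(n_test, n_ref))
    tested <- filter_features(fm, min_samples = max(3L, min_n))
    tt <- t_test_features(tested)
    bayes <- bayes_upregulation(tested, cfg$bayes)
    names(bayes)[names(bayes) == "log_fold_change"] <- "bayes_log_fc"
    merge(cbind(tested$features, tt[, -1]), bayes, by = "feature_id",
          sort = FALSE)
  })
  annotations <- stage("annotate", {
    sel <- which(feats$n_samples >= 3 & z_eff == 1L)
    annotate_features(feats[sel, ], tol_ppm = cfg$annotation_tol_ppm,
                      ccs_tol = cfg$annotation_ccs_tol)
  })
  result <- list(sim = sim, matrix = fm, calibration = calib,
                 clusters = cl, series = series_report,
                 envelopes = env_report, adduct_hypotheses = adduct_report,
                 differential = diff_res, qc = qc, annotations = annotations,
                 config = cfg)
  if (!is.null(outdir)) {
    stage("write", write_run(result, outdir))
  }
  invisible(result)
}

# serialize all pipeline artifacts plus a manifest with config hash
write_run <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(result$sim)) write_cohort(result$sim, file.path(outdir, "input"))
  write_feature_matrix(result$matrix, file.path(outdir, "feature_matrix.csv"))
  cal <- result$calibration
  jsonlite::write_json(
    list(A = cal$A, B = cal$B, c = cal$c, a = cal$a,
         gas_mass = cal$gas_mass, residual_sd_log = cal$residual_sd_log,
         n_calibrants = cal$n_calibrants, flagged = cal$flagged),
    file.path(outdir, "calibration.json"), digits = NA, auto_unbox = TRUE)
  jsonlite::write_json(
    list(series = result$series,
         envelopes = list(centers = result$envelopes$centers,
                          spacings = result$envelopes$spacings),
         adduct_matched_fraction =
           if (is.null(result$adduct_hypotheses)) NULL
           else result$adduct_hypotheses$matched_fraction),
    file.path(outdir, "clusters_series.json"), digits = NA,
    auto_unbox = TRUE, null = "null")
  utils::write.csv(result$differential,
                   file.path(outdir, "differential.csv"), row.names = FALSE)
  jsonlite::write_json(result$qc, file.path(outdir, "qc.json"),
                       digits = NA, auto_unbox = TRUE, dataframe = "rows")
  utils::write.csv(result$annotations,
                   file.path(outdir, "annotations.csv"), row.names = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(serialize_config(result$config), cfg_path)
  manifest <- list(
    package = "sebumIMS",
    version = as.character(utils::packageVersion("sebumIMS")),
    r_version = as.character(getRversion()),
    seed = result$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_features = nrow(result$matrix$features),
    n_samples = nrow(result$matrix$samples),
    qc_status = result$qc$status)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}

serialize_config <- function(cfg) {
  sim <- cfg$simulation
  list(seed = cfg$seed,
       charge_tol_ppm = cfg$charge_tol_ppm, mz_tol_ppm = cfg$mz_tol_ppm,
       dt_tol = cfg$dt_tol, normalization = cfg$normalization,
       series_tol_ppm = cfg$series_tol_ppm,
       annotation_tol_ppm = cfg$annotation_tol_ppm,
       annotation_ccs_tol = cfg$annotation_ccs_tol,
       min_detect_fraction = cfg$min_detect_fraction,
       bayes = unclass(cfg$bayes),
       simulation = if (is.null(sim)) NULL else list(
         n_per_group = sim$n_per_group, seed = sim$seed,
         mz_noise_ppm = sim$mz_noise_ppm, dt_noise_ms = sim$dt_noise_ms,
         intensity_sdlog = sim$intensity_sdlog,
         n_noise_peaks = sim$n_noise_peaks,
         effect_log2 = as.list(sim$effect_log2)),
       input_dir = cfg$input_dir)
}
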