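# Peak-list conditioning: isotope-based charge assignment, cross-sample
# alignment into a feature matrix, and normalization. These stages stand in
# for the vendor Apex3D/Progenesis steps on centroided (m/z, drift time,
# intensity) peak lists.

#' Read a per-sample peak list
#'
#' @param path CSV with columns `mz`, `drift_time_ms` (or `drift_time`) and
#'   `intensity`.
#' @return data.frame with columns `mz`, `drift_time`, `intensity`, sorted by
#'   m/z.
#' @export
read_peaklist <- function(path) {
  d <- utils::read.csv(path)
  if ("drift_time_ms" %in% names(d)) d$drift_time <- d$drift_time_ms
  req <- c("mz", "drift_time", "intensity")
  if (!all(req %in% names(d))) {
    stop("peak list must have columns mz, drift_time_ms (or drift_time), intensity: ",
         path)
  }
  d <- d[order(d$mz), req]
  rownames(d) <- NULL
  d
}

#' Assign charge states from isotopic spacing
#'
#' For each peak (ascending m/z), looks for isotopologue companions at
#' `+k * 1.00336 / z` Th (z in `charges`) within a ppm tolerance and a
#' drift-time co-elution window. A companion must also be intensity-plausible
#' (at most `max_ratio` times its predecessor: the 13C binomial never exceeds
#' ~1.6x below 150 carbons). The charge whose envelope has the most
#' consistent members wins; peaks with no companions stay unassigned.
#' Non-monoisotopic envelope members are flagged and collapsed into their
#' monoisotopic feature (intensities summed).
#'
#' @param peaks data.frame with `mz`, `drift_time`, `intensity`, sorted by
#'   ascending m/z.
#' @param tol_ppm Position tolerance for companion matching (ppm of the
#'   monoisotopic m/z); default 5.
#' @param dt_window Drift co-elution window in ms (default 0.2).
#' @param charges Candidate charge states (default 1:3).
#' @param max_isotopes Maximum envelope length searched (default 4).
#' @param max_ratio Maximum allowed companion/predecessor intensity ratio
#'   (default 2).
#' @param collapse If `TRUE` (default), drop isotopologue rows and add their
#'   intensity to the monoisotopic peak.
#' @return The peak data.frame with added `charge` (NA when unassigned) and,
#'   when `collapse = FALSE`, logical `isotopologue`.
#' @export
assign_charge <- function(peaks, tol_ppm = 5, dt_window = 0.2,
                          charges = 1:3, max_isotopes = 4L,
                          max_ratio = 2, collapse = TRUE) {
  if (is.unsorted(peaks$mz)) stop("peaks must be sorted by ascending m/z")
  n <- nrow(peaks)
  mz <- peaks$mz; dt <- peaks$drift_time; int <- peaks$intensity
  charge <- rep(NA_integer_, n)
  member_of <- rep(NA_integer_, n)  # index of the envelope's monoisotopic peak
  claimed <- logical(n)
  # nearest unclaimed peak to 'target' within tol, dt window and intensity bound
  find_companion <- function(target, dt0, tol_th, int_prev) {
    lo <- findInterval(target - tol_th, mz) + 1L
    hi <- findInterval(target + tol_th, mz)
    if (hi < lo) return(NA_integer_)
    cand <- lo:hi
    cand <- cand[!claimed[cand] & abs(dt[cand] - dt0) <= dt_window &
                   int[cand] <= max_ratio * int_prev]
    if (length(cand) == 0) return(NA_integer_)
    cand[which.min(abs(mz[cand] - target))]
  }
  for (i in seq_len(n)) {
    if (claimed[i]) next
    best_z <- NA_integer_; best_members <- integer(0)
    for (z in sort(charges, decreasing = TRUE)) {
      tol_th <- tol_ppm * 1e-6 * mz[i]
      members <- integer(0)
      prev_int <- int[i]
      for (k in seq_len(max_isotopes - 1L)) {
        target <- mz[i] + k * .c13_spacing / z
        j <- find_companion(target, dt[i], tol_th, prev_int)
        if (is.na(j)) break
        members <- c(members, j)
        prev_int <- int[j]
      }
      if (length(members) > length(best_members)) {
        best_z <- z; best_members <- members
      }
    }
    if (length(best_members) > 0) {
      charge[i] <- best_z
      claimed[best_members] <- TRUE
      member_of[best_members] <- i
    }
  }
  peaks$charge <- charge
  iso <- !is.na(member_of)
  if (collapse) {
    add <- tapply(peaks$intensity[iso], member_of[iso], sum)
    if (length(add) > 0) {
      idx <- as.integer(names(add))
      peaks$intensity[idx] <- peaks$intensity[idx] + as.numeric(add)
    }
    out <- peaks[!iso, , drop = FALSE]
    rownames(out) <- NULL
    out
  } else {
    peaks$isotopologue <- iso
    peaks
  }
}

#' Align peak lists across samples into a feature matrix
#'
#' Greedy intensity-ordered centroid clustering: pooled peaks are visited in
#' decreasing intensity; each unclaimed peak seeds a consensus row that
#' absorbs at most one peak per sample within the m/z and drift-time
#' tolerances. Row consensus m/z and drift time are intensity-weighted means.
#' Deterministic and invariant to sample order.
#'
#' @param samples Named list of peak data.frames (`mz`, `drift_time`,
#'   `intensity`, optional `charge`).
#' @param metadata data.frame with `sample_id`, `group` and optionally `site`;
#'   row order defines column order.
#' @param mz_tol_ppm m/z tolerance (ppm), > 0.
#' @param dt_tol Drift-time tolerance (ms), > 0.
#' @return A `feature_matrix`: list with `features` (consensus mz, drift time,
#'   modal charge, n_samples), `intensity` (features x samples, 0 = absent),
#'   `samples` metadata, and the tolerances used.
#' @export
align_features <- function(samples, metadata = NULL, mz_tol_ppm = 8,
                           dt_tol = 0.3) {
  if (length(samples) < 2) stop("alignment needs at least 2 samples")
  if (mz_tol_ppm <= 0 || dt_tol <= 0) stop("tolerances must be positive")
  if (is.null(names(samples)) || anyDuplicated(names(samples))) {
    stop("samples must be a uniquely named list")
  }
  if (is.null(metadata)) {
    metadata <- data.frame(sample_id = names(samples),
                           group = NA_character_, site = NA_character_)
  }
  if (!all(names(samples) %in% metadata$sample_id)) {
    stop("metadata is missing sample ids: ",
         paste(setdiff(names(samples), metadata$sample_id), collapse = ", "))
  }
  metadata <- metadata[match(names(samples), metadata$sample_id), ,
                       drop = FALSE]
  pool <- do.call(rbind, lapply(seq_along(samples), function(j) {
    s <- samples[[j]]
    data.frame(mz = s$mz, drift_time = s$drift_time,
               intensity = s$intensity,
               charge = if ("charge" %in% names(s)) s$charge else NA_integer_,
               sample = j)
  }))
  o_mz <- order(pool$mz)
  pool <- pool[o_mz, ]
  n <- nrow(pool)
  mz <- pool$mz; dt <- pool$drift_time; int <- pool$intensity
  # visiting order: intensity desc, ties broken by mz/dt for determinism
  visit <- order(-int, mz, dt)
  claimed <- logical(n)
  row_id <- rep(NA_integer_, n)
  n_rows <- 0L
  for (i in visit) {
    if (claimed[i]) next
    n_rows <- n_rows + 1L
    w <- mz_tol_ppm * 1e-6 * mz[i]
    lo <- findInterval(mz[i] - w, mz) + 1L
    hi <- findInterval(mz[i] + w, mz)
    cand <- lo:hi
    cand <- cand[!claimed[cand] & abs(dt[cand] - dt[i]) <= dt_tol]
    # at most one member per sample: nearest in m/z
    if (length(cand) > 1) {
      dmz <- abs(mz[cand] - mz[i])
      keep <- unlist(lapply(split(seq_along(cand), pool$sample[cand]),
                            function(ii) ii[which.min(dmz[ii])]))
      cand <- cand[keep]
    }
    claimed[cand] <- TRUE
    row_id[cand] <- n_rows
  }
  n_samp <- length(samples)
  intensity <- matrix(0, n_rows, n_samp,
                      dimnames = list(NULL, names(samples)))
  intensity[cbind(row_id, pool$sample)] <- int
  # tapply orders numeric groups lexicographically; map back by id explicitly
  wsum <- tapply(int, row_id, sum)
  ids <- as.integer(names(wsum))
  cons_mz <- cons_dt <- numeric(n_rows)
  n_members <- integer(n_rows)
  modal_charge <- rep(NA_integer_, n_rows)
  cons_mz[ids] <- tapply(mz * int, row_id, sum) / wsum
  cons_dt[ids] <- tapply(dt * int, row_id, sum) / wsum
  n_members[ids] <- as.integer(tapply(row_id, row_id, length))
  modal_charge[ids] <- as.integer(tapply(pool$charge, row_id, function(z) {
    z <- z[!is.na(z)]
    if (length(z) == 0) return(NA_integer_)
    as.integer(names(which.max(table(z))))
  }))
  feats <- data.frame(feature_id = sprintf("F%05d", seq_len(n_rows)),
                      mz = cons_mz,
                      drift_time = cons_dt,
                      charge = modal_charge,
                      n_samples = n_members)
  o <- order(feats$mz, feats$drift_time)
  feats <- feats[o, ]
  feats$feature_id <- sprintf("F%05d", seq_len(n_rows))
  rownames(feats) <- NULL
  intensity <- intensity[o, , drop = FALSE]
  rownames(intensity) <- feats$feature_id
  structure(list(features = feats, intensity = intensity, samples = metadata,
                 mz_tol_ppm = mz_tol_ppm, dt_tol = dt_tol,
                 normalization = "none", scalars = NULL),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat("PS-IM-MS feature matrix\n")
  cat(sprintf("  %d features x %d samples (normalization: %s)\n",
              nrow(x$features), nrow(x$samples), x$normalization))
  grp <- table(x$samples$group)
  if (length(grp) > 0 && !all(is.na(x$samples$group))) {
    cat("  groups:", paste(names(grp), grp, sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.feature_matrix <- function(x) dim(x$intensity)

#' Drift time vs m/z map of a feature matrix
#'
#' @param x A `feature_matrix`.
#' @param y Unused.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.feature_matrix <- function(x, y, ...) {
  tot <- rowSums(x$intensity)
  cex <- 0.2 + 1.3 * sqrt(tot / max(tot))
  graphics::plot(x$features$mz, x$features$drift_time, cex = cex,
                 pch = 16, col = grDevices::adjustcolor("steelblue", 0.5),
                 xlab = "m/z (Th)", ylab = "drift time (ms)", ...)
}

#' Filter features by detection frequency
#'
#' @param fm A `feature_matrix`.
#' @param min_samples Keep rows detected (> 0) in at least this many samples.
#' @return A `feature_matrix` with the retained rows.
#' @export
filter_features <- function(fm, min_samples = 3L) {
  keep <- rowSums(fm$intensity > 0) >= min_samples
  fm$features <- fm$features[keep, , drop = FALSE]
  fm$intensity <- fm$intensity[keep, , drop = FALSE]
  fm
}

#' Normalize a feature matrix
#'
#' `TIC`: total-sum scaling; each sample column is scaled so its summed
#' intensity equals 1e6, which is exactly invariant to any per-column scale
#' factor. `reference_scalar`: the sample with the most detected
#' features is the reference and every other column is multiplied by the
#' median reference/sample ratio over shared features (Progenesis-style
#' run-specific scalar factors). Both methods are scale-invariant per column
#' and idempotent.
#'
#' @param fm A `feature_matrix`.
#' @param method `"TIC"` or `"reference_scalar"`.
#' @return The normalized `feature_matrix` (with `scalars` recorded).
#' @export
normalize_features <- function(fm, method = c("TIC", "reference_scalar")) {
  method <- match.arg(method)
  x <- fm$intensity
  tic <- colSums(x)
  if (any(tic == 0)) {
    stop("sample(s) with zero total intensity: ",
         paste(colnames(x)[tic == 0], collapse = ", "))
  }
  if (method == "TIC") {
    scal <- 1e6 / tic
  } else {
    ref <- which.max(colSums(x > 0))
    scal <- vapply(seq_len(ncol(x)), function(j) {
      shared <- x[, ref] > 0 & x[, j] > 0
      if (!any(shared)) stop("no shared features with the reference sample")
      stats::median(x[shared, ref] / x[shared, j])
    }, numeric(1))
    names(scal) <- colnames(x)
  }
  fm$intensity <- sweep(x, 2, scal, "*")
  fm$normalization <- method
  fm$scalars <- scal
  if (method == "reference_scalar") {
    fm$reference_sample <- colnames(x)[which.max(colSums(x > 0))]
  }
  fm
}

#' Write a feature matrix as wide CSV plus JSON sidecar
#'
#' @param fm A `feature_matrix`.
#' @param path Output CSV path; the sidecar is written next to it as
#'   `<path>.json` (tolerances, normalization, scalars).
#' @return Invisibly, `path`.
#' @export
write_feature_matrix <- function(fm, path) {
  wide <- cbind(fm$features, as.data.frame(fm$intensity))
  utils::write.csv(wide, path, row.names = FALSE)
  jsonlite::write_json(
    list(mz_tol_ppm = fm$mz_tol_ppm, dt_tol = fm$dt_tol,
         normalization = fm$normalization,
         reference_sample = fm$reference_sample,
         scalars = as.list(fm$scalars),
         samples = fm$samples),
    paste0(path, ".json"), digits = NA, auto_unbox = TRUE, null = "null")
  invisible(path)
}
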