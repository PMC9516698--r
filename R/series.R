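# Drift-cluster segmentation, homologous-series detection, high-mass envelope
# analysis and [M + A + B]2+ dimer adduct-hypothesis testing: the structural
# reasoning layer over the aligned feature space.

#' Drift-time cluster windows
#'
#' The five drift-time windows with their nominal charge states:
#' Cluster 1 2.5-3.5 ms (3+), Cluster 2 3.5-5 ms (2+), Cluster 3 6-7 ms (2+),
#' Cluster 4 7.5-9 ms (1+), Cluster 5 9-10 ms (1+). Windows are half-open
#' `[low, high)`.
#'
#' @return data.frame with `cluster_id`, `dt_low`, `dt_high`,
#'   `nominal_charge`.
#' @export
drift_clusters <- function() {
  data.frame(cluster_id = 1:5,
             dt_low = c(2.5, 3.5, 6, 7.5, 9),
             dt_high = c(3.5, 5, 7, 9, 10),
             nominal_charge = c(3L, 2L, 2L, 1L, 1L))
}

#' Assign features to drift-time clusters
#'
#' Labels each feature by half-open window membership; drift times outside
#' all windows give `NA` (unclustered). When a `charge` vector is supplied,
#' disagreements with the cluster's nominal charge are reported in the
#' `charge_consistent` column.
#'
#' @param drift_time Numeric drift times (ms), or a `feature_matrix`.
#' @param charge Optional assigned charges (recycled from the feature matrix
#'   when one is given).
#' @param windows Cluster window table as from [drift_clusters()].
#' @return data.frame with `cluster` (integer or NA) and, when charges are
#'   available, `charge_consistent`.
#' @export
assign_clusters <- function(drift_time, charge = NULL,
                            windows = drift_clusters()) {
  if (inherits(drift_time, "feature_matrix")) {
    fm <- drift_time
    charge <- fm$features$charge
    drift_time <- fm$features$drift_time
  }
  cluster <- rep(NA_integer_, length(drift_time))
  for (i in seq_len(nrow(windows))) {
    hit <- drift_time >= windows$dt_low[i] & drift_time < windows$dt_high[i]
    cluster[hit] <- windows$cluster_id[i]
  }
  out <- data.frame(cluster = cluster)
  if (!is.null(charge)) {
    nominal <- windows$nominal_charge[match(cluster, windows$cluster_id)]
    out$charge_consistent <- ifelse(is.na(cluster) | is.na(charge), NA,
                                    charge == nominal)
  }
  out
}

# repeat-unit masses for series detection
series_unit_mass <- function(unit) {
  switch(unit,
    CH2 = monoisotopic_mass("CH2"),
    H2 = monoisotopic_mass("H2"),
    C16H32O2 = monoisotopic_mass("C16H32O2"),
    stop("unknown series unit: ", unit)
  )
}

#' Detect homologous series
#'
#' Greedy maximal-chain search for features spaced by `mass(unit) / z` within
#' a ppm tolerance. Chains are grown from the lowest-m/z unclaimed member by
#' repeatedly taking the nearest match at the expected next position; each
#' feature belongs to at most one chain per unit. Only series with at least
#' `min_length` members are reported.
#'
#' @param mz Feature m/z values (need not be pre-sorted).
#' @param unit Repeat unit: `"CH2"` (14.0157 Da), `"H2"` (2.0157, saturation
#'   ladder) or `"C16H32O2"` (256.2402, palmitic ester unit).
#' @param z Charge state of the series (spacing is `mass(unit)/z`).
#' @param tol_ppm Spacing tolerance in ppm of the member m/z (default 15).
#' @param min_length Minimum reported chain length (default 3).
#' @return List of series; each has `members` (indices into `mz`), `mz`,
#'   `length`, `unit`, `charge`, `observed_spacing` (mean Th) and
#'   `expected_spacing`.
#' @export
detect_series <- function(mz, unit = "CH2", z = 1L, tol_ppm = 15,
                          min_length = 3L) {
  spacing <- series_unit_mass(unit) / z
  o <- order(mz)
  m <- mz[o]
  n <- length(m)
  claimed <- logical(n)
  series <- list()
  for (i in seq_len(n)) {
    if (claimed[i]) next
    chain <- i
    repeat {
      cur <- chain[length(chain)]
      target <- m[cur] + spacing
      tol <- tol_ppm * 1e-6 * m[cur]
      lo <- findInterval(target - tol, m) + 1L
      hi <- findInterval(target + tol, m)
      if (hi < lo) break
      cand <- (lo:hi)[!claimed[lo:hi]]
      cand <- setdiff(cand, chain)
      if (length(cand) == 0) break
      nxt <- cand[which.min(abs(m[cand] - target))]
      chain <- c(chain, nxt)
    }
    if (length(chain) >= min_length) {
      claimed[chain] <- TRUE
      series[[length(series) + 1L]] <- list(
        members = o[chain], mz = m[chain], length = length(chain),
        unit = unit, charge = z,
        observed_spacing = mean(diff(m[chain])),
        expected_spacing = spacing)
    }
  }
  series
}

#' Detect high-mass intensity envelopes and 256-Da linkage
#'
#' Groups singly charged high-mass features into intensity envelopes by
#' kernel-smoothing summed intensity along m/z and taking local maxima of the
#' smoothed trace. Pairwise envelope-center spacings within +/- `unit_window`
#' Da of the palmitic ester unit C16H32O2 (256.2402 Da) are flagged as
#' ester-unit linked.
#'
#' @param mz Feature m/z values (the analysis restricts itself to
#'   `mz >= min_mz`).
#' @param intensity Summed feature intensities (same length).
#' @param bw Gaussian smoothing bandwidth in Th (default 10).
#' @param min_mz Lower m/z bound of the high-mass region (default 950).
#' @param unit_window Flagging half-window around 256.2402 Da (default 4).
#' @return List with `centers` (envelope center m/z), `spacings` (data.frame
#'   of pairwise center spacings with `ester_unit_linked` flag) and
#'   `n_features`.
#' @export
detect_envelopes <- function(mz, intensity, bw = 10, min_mz = 950,
                             unit_window = 4) {
  keep <- mz >= min_mz
  mz <- mz[keep]; intensity <- intensity[keep]
  if (length(mz) == 0) {
    return(list(centers = numeric(0),
                spacings = data.frame(from = numeric(0), to = numeric(0),
                                      spacing = numeric(0),
                                      ester_unit_linked = logical(0)),
                n_features = 0L))
  }
  d <- stats::density(mz, weights = intensity / sum(intensity), bw = bw,
                      n = 2048, from = min(mz) - 3 * bw, to = max(mz) + 3 * bw)
  y <- d$y
  is_max <- which(diff(sign(diff(y))) == -2) + 1L
  # keep maxima carrying non-trivial mass (> 1% of the modal density)
  is_max <- is_max[y[is_max] > 0.01 * max(y)]
  centers <- d$x[is_max]
  if (length(centers) >= 2) {
    pairs <- utils::combn(seq_along(centers), 2)
    spacing <- centers[pairs[2, ]] - centers[pairs[1, ]]
    spacings <- data.frame(from = centers[pairs[1, ]],
                           to = centers[pairs[2, ]], spacing = spacing)
  } else {
    spacings <- data.frame(from = numeric(0), to = numeric(0),
                           spacing = numeric(0))
  }
  palmitic <- monoisotopic_mass("C16H32O2")
  spacings$ester_unit_linked <- abs(spacings$spacing - palmitic) <= unit_window
  list(centers = centers, spacings = spacings, n_features = length(mz))
}

#' Enumerate dimer adduct hypotheses for doubly charged features
#'
#' Tests whether doubly charged features could be adducted dimers of observed
#' singly charged species: each m/z is treated as a solution of
#' `[M + A + B]2+` over all unordered adduct pairs (A, B), giving
#' `M = 2 mz - delta(A) - delta(B)`; candidate singly charged ions `[M + X]+`
#' for every adduct X are then searched in the observed singly charged peak
#' list within a ppm tolerance. A low matched fraction argues that the doubly
#' charged features are genuine high-mass monomers rather than dimers.
#'
#' @param doubly_charged_mz m/z values of the doubly charged features (Th).
#' @param singly_charged_mz Observed singly charged peak m/z values.
#' @param adducts Character vector of singly charged adduct names
#'   (default `c("+H", "+Na", "+K")`).
#' @param tol_ppm Match tolerance in ppm (default 10).
#' @return List with `hypotheses` (one row per (mz, A, B, X) combination:
#'   neutral `M`, `candidate_mz`, `matched`, `matched_mz`) and
#'   `matched_fraction`.
#' @export
enumerate_adduct_hypotheses <- function(doubly_charged_mz, singly_charged_mz,
                                        adducts = c("+H", "+Na", "+K"),
                                        tol_ppm = 10) {
  if (length(adducts) == 0) stop("adducts must be non-empty")
  deltas <- vapply(adducts, function(a) adduct_spec(a)$mass_delta, numeric(1))
  pair_idx <- which(upper.tri(matrix(0, length(adducts), length(adducts)),
                              diag = TRUE), arr.ind = TRUE)
  singly <- sort(singly_charged_mz)
  grid <- expand.grid(mz2 = doubly_charged_mz, pair = seq_len(nrow(pair_idx)),
                      ix = seq_along(adducts))
  ia <- pair_idx[grid$pair, 1]; ib <- pair_idx[grid$pair, 2]
  M <- 2 * grid$mz2 - deltas[ia] - deltas[ib]
  cand <- M + deltas[grid$ix]
  tol <- tol_ppm * 1e-6 * cand
  lo <- findInterval(cand - tol, singly) + 1L
  hi <- findInterval(cand + tol, singly)
  hit <- hi >= lo
  matched_mz <- rep(NA_real_, length(cand))
  for (i in which(hit)) {
    w <- singly[lo[i]:hi[i]]
    matched_mz[i] <- w[which.min(abs(w - cand[i]))]
  }
  hypotheses <- data.frame(
    mz2 = grid$mz2, adduct_a = adducts[ia], adduct_b = adducts[ib],
    neutral_mass = M, candidate_adduct = adducts[grid$ix],
    candidate_mz = cand, matched = hit, matched_mz = matched_mz)
  list(hypotheses = hypotheses,
       matched_fraction = mean(hypotheses$matched))
}
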