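# Traveling-wave ion-mobility CCS calibration.
#
# Classic log-log power-law calibration with reduced CCS and an m/z-dependent
# drift-time correction:
#   t' = dt - c * sqrt(mz) / 1000
#   reduced CCS: omega' = CCS * sqrt(mu) / z,  mu = m_ion * m_gas / (m_ion + m_gas)
#   ln(omega') = ln(A) + B * ln(t')
# The velocity relaxation parameter "a" is carried as configuration surface and
# is a documented no-op at its default 1.0.

.n2_mass <- 28.0134

reduced_mass <- function(mz, z, gas_mass = .n2_mass) {
  m_ion <- mz * z
  m_ion * gas_mass / (m_ion + gas_mass)
}

corrected_dt <- function(dt, mz, c = 0.2) dt - c * sqrt(mz) / 1000

#' Fit a traveling-wave CCS calibration
#'
#' Least-squares fit of `ln(reduced CCS) = ln(A) + B * ln(t')` on calibrant
#' reference peaks, where `t'` is the drift time corrected by
#' `c * sqrt(mz) / 1000` and reduced CCS is `CCS * sqrt(mu) / z` against the
#' drift gas (N2 by default).
#'
#' @param calibrants data.frame with columns `mz`, `charge`, `reference_ccs`
#'   (Angstrom^2) and `measured_dt` (ms); at least 3 rows.
#' @param c Drift-time correction coefficient (ms Th^-1/2 / 1000); default 0.2.
#' @param a Velocity relaxation parameter; stored pass-through, default 1.0.
#' @param gas_mass Drift gas mass in Da (default N2, 28.0134).
#' @return A `ccs_calibration` object with coefficients `A`, `B`, parameters
#'   `c`, `a`, and fit diagnostics (`residual_sd_log`, per-calibrant percent
#'   CCS residuals, `n_calibrants`).
#' @export
fit_ccs_calibration <- function(calibrants, c = 0.2, a = 1.0,
                                gas_mass = .n2_mass) {
  req <- c("mz", "charge", "reference_ccs", "measured_dt")
  if (!all(req %in% names(calibrants))) {
    stop("calibrants must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(calibrants) < 3) stop("at least 3 calibrants are required")
  tprime <- corrected_dt(calibrants$measured_dt, calibrants$mz, c)
  if (any(tprime <= 0)) stop("non-positive corrected drift time in calibrants")
  mu <- reduced_mass(calibrants$mz, calibrants$charge, gas_mass)
  omega_red <- calibrants$reference_ccs * sqrt(mu) / calibrants$charge
  fit <- stats::lm(log(omega_red) ~ log(tprime))
  A <- exp(unname(stats::coef(fit)[1]))
  B <- unname(stats::coef(fit)[2])
  cal <- structure(list(A = A, B = B, c = c, a = a, gas_mass = gas_mass,
                        residual_sd_log = stats::sd(stats::residuals(fit)),
                        n_calibrants = nrow(calibrants)),
                   class = "ccs_calibration")
  fitted_ccs <- dt_to_ccs(cal, calibrants$mz, calibrants$charge,
                          calibrants$measured_dt)
  cal$ccs_residual_pct <- (fitted_ccs - calibrants$reference_ccs) /
    calibrants$reference_ccs * 100
  cal$flagged <- any(abs(cal$ccs_residual_pct) > 2)
  cal
}

#' Construct a CCS calibration from known coefficients
#'
#' Used by the simulator and for round-trip testing; [fit_ccs_calibration()]
#' is the data-driven constructor.
#'
#' @param A,B Power-law scale and exponent (`B > 0`).
#' @inheritParams fit_ccs_calibration
#' @return A `ccs_calibration` object.
#' @export
ccs_calibration <- function(A, B, c = 0.2, a = 1.0, gas_mass = .n2_mass) {
  stopifnot(A > 0, B > 0)
  structure(list(A = A, B = B, c = c, a = a, gas_mass = gas_mass,
                 residual_sd_log = NA_real_, n_calibrants = NA_integer_,
                 ccs_residual_pct = NULL, flagged = FALSE),
            class = "ccs_calibration")
}

#' @export
print.ccs_calibration <- function(x, ...) {
  cat("Traveling-wave CCS calibration\n")
  cat(sprintf("  CCS' = A * t'^B : A = %.4f, B = %.5f\n", x$A, x$B))
  cat(sprintf("  drift correction c = %.3f, velocity relaxation a = %.2f (inert)\n",
              x$c, x$a))
  cat(sprintf("  drift gas mass = %.4f Da\n", x$gas_mass))
  if (!is.na(x$n_calibrants)) {
    cat(sprintf("  fitted on %d calibrants, residual sd (ln) = %.2e%s\n",
                x$n_calibrants, x$residual_sd_log,
                if (isTRUE(x$flagged)) " [FLAGGED: >2% CCS residual]" else ""))
  }
  invisible(x)
}

#' @export
coef.ccs_calibration <- function(object, ...) {
  c(A = object$A, B = object$B, c = object$c, a = object$a)
}

#' Convert drift time to CCS
#'
#' @param cal A `ccs_calibration`.
#' @param mz m/z of the ion (Th).
#' @param z Charge state.
#' @param dt Measured drift time (ms); must exceed the correction offset
#'   `c * sqrt(mz) / 1000`.
#' @return CCS in Angstrom^2: `A * t'^B * z / sqrt(mu)`.
#' @export
dt_to_ccs <- function(cal, mz, z, dt) {
  stopifnot(inherits(cal, "ccs_calibration"))
  tprime <- corrected_dt(dt, mz, cal$c)
  if (any(tprime <= 0)) stop("drift time at or below the correction offset")
  mu <- reduced_mass(mz, z, cal$gas_mass)
  cal$A * tprime^cal$B * z / sqrt(mu)
}

#' Convert CCS to drift time (exact inverse of [dt_to_ccs()])
#'
#' @inheritParams dt_to_ccs
#' @param ccs CCS in Angstrom^2 (> 0).
#' @return Drift time in ms.
#' @export
ccs_to_dt <- function(cal, mz, z, ccs) {
  stopifnot(inherits(cal, "ccs_calibration"))
  if (any(ccs <= 0)) stop("CCS must be positive")
  mu <- reduced_mass(mz, z, cal$gas_mass)
  omega_red <- ccs * sqrt(mu) / z
  (omega_red / cal$A)^(1 / cal$B) + cal$c * sqrt(mz) / 1000
}

#' Default instrument calibration model
#'
#' The fixed "true" calibration used by the synthetic-data generator, anchored
#' so that a singly charged ion at 907.7725 Th with CCS 335.8 Angstrom^2 (the
#' sodiated TG 54:3 reference) arrives at 8.3 ms. `B = 0.55`, `c = 0.2`,
#' `a = 1.0`.
#'
#' @return A `ccs_calibration`.
#' @export
default_instrument_calibration <- function() {
  B <- 0.55; c <- 0.2
  anchor_mz <- 907.7725; anchor_ccs <- 335.8; anchor_dt <- 8.3
  tprime <- corrected_dt(anchor_dt, anchor_mz, c)
  omega_red <- anchor_ccs * sqrt(reduced_mass(anchor_mz, 1L)) / 1
  ccs_calibration(A = omega_red / tprime^B, B = B, c = c, a = 1.0)
}

#' Read a calibrant reference table
#'
#' @param path TSV with columns `mz`, `charge`, `reference_ccs`, `measured_dt`.
#'   Defaults to the packaged synthetic calibrant set (generated from the
#'   default instrument model).
#' @return data.frame of calibrant peaks.
#' @export
read_calibrants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "synthetic_calibrants.tsv",
                        package = "sebumIMS", mustWork = TRUE)
  }
  utils::read.delim(path, comment.char = "#")
}
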