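# Elemental-formula arithmetic, lipid shorthand, adducts and isotope envelopes.
# All mass arithmetic in the package goes through this file.

# IUPAC 2021 monoisotopic masses (lightest isotope), Da. One table; the packaged
# TSV in inst/extdata mirrors it and a test asserts they agree.
.element_masses <- c(
  C  = 12.0,
  H  = 1.00782503207,
  N  = 14.0030740048,
  O  = 15.9949146196,
  Na = 22.9897692809,
  K  = 38.96370668,
  P  = 30.97376163,
  S  = 31.97207100,
  F  = 18.99840322,
  Cl = 34.96885268
)

.electron_mass <- 0.000548579909
.c13_spacing <- 1.0033548378   # 13C - 12C
.c13_abundance <- 0.0107

#' Monoisotopic element mass table
#'
#' @return Named numeric vector of monoisotopic masses (Da) for the elements
#'   supported by [parse_formula()].
#' @export
element_masses <- function() .element_masses

#' Parse an elemental formula string
#'
#' Parses Hill-notation formula strings such as `"C57H104O6"` into an
#' `elemental_formula`: a named integer vector of element counts.
#'
#' @param text Formula string, e.g. `"C57H104O6"`.
#' @return An `elemental_formula` object (named integer vector, Hill order).
#' @examples
#' parse_formula("C57H104O6")
#' @export
parse_formula <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(as_formula(integer(0)))
  }
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", text)[[1]]
  tokens <- regmatches(text, list(m))[[1]]
  if (paste(tokens, collapse = "") != text) {
    stop("malformed formula string: '", text, "'")
  }
  sym <- sub("[0-9]*$", "", tokens)
  cnt <- sub("^[A-Za-z]+", "", tokens)
  cnt <- ifelse(cnt == "", 1L, as.integer(cnt))
  unknown <- setdiff(sym, names(.element_masses))
  if (length(unknown) > 0) {
    stop("unknown element symbol(s): ", paste(unknown, collapse = ", "))
  }
  counts <- tapply(cnt, sym, sum)
  as_formula(stats::setNames(as.integer(counts), names(counts)))
}

# internal constructor: sorts to Hill order (C, H, then alphabetical), drops zeros
as_formula <- function(counts) {
  counts <- counts[counts != 0]
  if (any(counts < 0)) stop("negative element count in formula")
  nm <- names(counts)
  hill <- c(intersect(c("C", "H"), nm), sort(setdiff(nm, c("C", "H"))))
  out <- as.integer(counts[hill])
  names(out) <- hill
  class(out) <- "elemental_formula"
  out
}

#' Format an elemental formula in Hill notation
#'
#' @param f An `elemental_formula`.
#' @return Canonical Hill-order formula string.
#' @export
format_formula <- function(f) {
  if (length(f) == 0) return("")
  paste0(names(f), ifelse(unclass(f) == 1L, "", unclass(f)), collapse = "")
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<formula>", format_formula(x), " (", format(monoisotopic_mass(x), nsmall = 4),
      " Da)\n", sep = "")
  invisible(x)
}

#' Add two elemental formulas element-wise
#' @param f1,f2 `elemental_formula` objects (or formula strings).
#' @return An `elemental_formula`.
#' @export
formula_add <- function(f1, f2) {
  f1 <- as_formula_arg(f1); f2 <- as_formula_arg(f2)
  all_el <- union(names(f1), names(f2))
  v1 <- stats::setNames(integer(length(all_el)), all_el)
  v1[names(f1)] <- unclass(f1)
  v1[names(f2)] <- v1[names(f2)] + unclass(f2)
  as_formula(v1)
}

#' Subtract an elemental formula element-wise
#'
#' Errors if any element count would become negative.
#' @inheritParams formula_add
#' @return An `elemental_formula`.
#' @export
formula_subtract <- function(f1, f2) {
  f1 <- as_formula_arg(f1); f2 <- as_formula_arg(f2)
  all_el <- union(names(f1), names(f2))
  v1 <- stats::setNames(integer(length(all_el)), all_el)
  v1[names(f1)] <- unclass(f1)
  v1[names(f2)] <- v1[names(f2)] - unclass(f2)
  if (any(v1 < 0)) {
    stop("formula subtraction would give a negative count for: ",
         paste(names(v1)[v1 < 0], collapse = ", "))
  }
  as_formula(v1)
}

as_formula_arg <- function(f) {
  if (inherits(f, "elemental_formula")) f else parse_formula(f)
}

#' Monoisotopic mass of a formula
#'
#' @param f An `elemental_formula` or formula string.
#' @return Mass in Da (sum of count x lightest-isotope mass). The empty
#'   formula has mass 0.
#' @examples
#' monoisotopic_mass("CH2")      # 14.01565
#' monoisotopic_mass("C57H104O6")
#' @export
monoisotopic_mass <- function(f) {
  f <- as_formula_arg(f)
  if (length(f) == 0) return(0)
  sum(.element_masses[names(f)] * unclass(f))
}

#' Signed mass error in parts per million
#'
#' @param observed,theoretical m/z values (Th); `theoretical` must be > 0.
#' @return `(observed - theoretical) / theoretical * 1e6`, signed.
#' @export
ppm_error <- function(observed, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be positive")
  (observed - theoretical) / theoretical * 1e6
}

## ---- lipid shorthand -------------------------------------------------------

#' Parse lipid shorthand
#'
#' Accepts both summed notation (`"TG 54:3"`) and per-chain notation
#' (`"DG (12:0/17:0/0:0)"`, `"TG 18:1/18:1/18:1"`). Per-chain forms are
#' summed to class totals; sn-position is not mass-distinguishing.
#'
#' @param s Shorthand string. Classes: TG, DG, PI.
#' @return A `lipid_shorthand` list: `class`, `carbons`, `double_bonds`,
#'   `chains` (data.frame of per-chain carbons/double bonds, or NULL when only
#'   totals were given).
#' @export
parse_lipid <- function(s) {
  stopifnot(is.character(s), length(s) == 1L)
  s <- trimws(s)
  cls <- sub("^([A-Za-z]+).*$", "\\1", s)
  if (!cls %in% c("TG", "DG", "PI")) stop("unsupported lipid class: ", cls)
  body <- trimws(sub("^[A-Za-z]+", "", s))
  body <- gsub("[()]", "", body)
  parts <- strsplit(body, "/", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (!all(grepl("^[0-9]+:[0-9]+$", parts))) {
    stop("malformed lipid shorthand: '", s, "'")
  }
  cd <- do.call(rbind, lapply(strsplit(parts, ":", fixed = TRUE), as.integer))
  chains <- NULL
  if (length(parts) > 1L) {
    chains <- data.frame(carbons = cd[, 1], double_bonds = cd[, 2])
    carbons <- sum(chains$carbons)
    db <- sum(chains$double_bonds)
    n_expected <- switch(cls, TG = 3L, DG = 3L, PI = 1L)
    if (cls %in% c("TG", "DG") && nrow(chains) > n_expected) {
      stop("too many acyl chains for ", cls)
    }
  } else {
    carbons <- cd[1, 1]
    db <- cd[1, 2]
  }
  n_chains <- switch(cls, TG = 3L, DG = 2L, PI = NA_integer_)
  if (!is.na(n_chains) && carbons < 2L * n_chains) {
    stop("implausible total acyl carbon count for ", cls, ": ", carbons)
  }
  structure(list(class = cls, carbons = carbons, double_bonds = db,
                 chains = chains),
            class = "lipid_shorthand")
}

#' @export
format.lipid_shorthand <- function(x, ...) {
  paste0(x$class, " ", x$carbons, ":", x$double_bonds)
}

#' @export
print.lipid_shorthand <- function(x, ...) {
  cat("<lipid>", format(x), "\n")
  invisible(x)
}

#' Expand lipid shorthand to an elemental formula
#'
#' Glycerolipid condensation arithmetic: a TG with `c` total acyl carbons and
#' `d` double bonds is glycerol + three fatty acids - 3 H2O, i.e.
#' `C(c+3) H(2c-2d+2) O6`; a DG is glycerol + two fatty acids - 2 H2O, i.e.
#' `C(c+3) H(2c-2d+4) O5`. PI expansion is not implemented (PI standards carry
#' literal values in the standards table).
#'
#' @param s A `lipid_shorthand` or shorthand string.
#' @return An `elemental_formula`.
#' @examples
#' lipid_formula("TG 54:3")  # C57H104O6 (triolein)
#' lipid_formula("DG 29:0")  # C32H62O5
#' @export
lipid_formula <- function(s) {
  if (is.character(s)) s <- parse_lipid(s)
  c_ <- s$carbons; d <- s$double_bonds
  counts <- switch(s$class,
    TG = c(C = c_ + 3L, H = 2L * c_ - 2L * d + 2L, O = 6L),
    DG = c(C = c_ + 3L, H = 2L * c_ - 2L * d + 4L, O = 5L),
    stop("formula expansion not implemented for class ", s$class)
  )
  if (any(counts <= 0)) stop("implausible shorthand: ", format(s))
  as_formula(counts)
}

#' Elemental formula of a free fatty acid
#'
#' `c:d` fatty acid = `Cc H(2c-2d) O2` (e.g. 16:0 palmitic = C16H32O2).
#' @param carbons,double_bonds Chain carbons and double-bond count.
#' @return An `elemental_formula`.
#' @export
fatty_acid_formula <- function(carbons, double_bonds = 0L) {
  h <- 2L * carbons - 2L * double_bonds
  if (carbons < 1L || h < 2L) stop("implausible fatty acid ", carbons, ":", double_bonds)
  as_formula(c(C = as.integer(carbons), H = as.integer(h), O = 2L))
}

## ---- adducts ---------------------------------------------------------------

# Registry of supported ionization adducts. add/remove are neutral formula
# strings; charge is the ion charge. mass_delta = mass(add) - mass(remove)
# - charge * electron mass, so m/z = (M + mass_delta) / z is exact.
.adduct_registry <- list(
  "none"     = list(add = "",     remove = "",    charge = 1L),
  "+H"       = list(add = "H",    remove = "",    charge = 1L),
  "+Na"      = list(add = "Na",   remove = "",    charge = 1L),
  "+K"       = list(add = "K",    remove = "",    charge = 1L),
  "+NH4"     = list(add = "NH4",  remove = "",    charge = 1L),
  "+H-H2O"   = list(add = "H",    remove = "H2O", charge = 1L),
  "+Na-H2O"  = list(add = "Na",   remove = "H2O", charge = 1L),
  "+K-H2O"   = list(add = "K",    remove = "H2O", charge = 1L),
  "+NH4-H2O" = list(add = "NH4",  remove = "H2O", charge = 1L),
  "+2H"      = list(add = "H2",   remove = "",    charge = 2L),
  "+2Na"     = list(add = "Na2",  remove = "",    charge = 2L),
  "+H+Na"    = list(add = "HNa",  remove = "",    charge = 2L),
  "+H+K"     = list(add = "HK",   remove = "",    charge = 2L),
  "+2K"      = list(add = "K2",   remove = "",    charge = 2L),
  "+3H"      = list(add = "H3",   remove = "",    charge = 3L),
  "+2H+Na"   = list(add = "H2Na", remove = "",    charge = 3L)
)

#' Supported adduct names
#' @return Character vector of adduct names usable with [adduct_mz()].
#' @export
adduct_names <- function() names(.adduct_registry)

#' Adduct specification
#'
#' @param name Adduct name, e.g. `"+Na"`, `"+H-H2O"`, `"+H+Na"`. `"none"` is
#'   the identity adduct (mass delta 0, charge 1).
#' @return List with `name`, `charge` and `mass_delta` (Da; monoisotopic mass
#'   of the attached species minus `charge` electron masses).
#' @export
adduct_spec <- function(name) {
  a <- .adduct_registry[[name]]
  if (is.null(a)) stop("unknown adduct: '", name, "'")
  delta <- if (name == "none") 0 else
    monoisotopic_mass(a$add) - monoisotopic_mass(a$remove) -
      a$charge * .electron_mass
  list(name = name, charge = a$charge, mass_delta = delta)
}

#' m/z of an adducted ion
#'
#' `(M + mass_delta) / z` with the electron mass accounted for in the adduct
#' delta; e.g. a sodiated ion appears at `M + 22.98922`.
#'
#' @param neutral_mass Neutral monoisotopic mass M (Da).
#' @param adduct Adduct name (see [adduct_names()]) or an [adduct_spec()].
#' @param z Ion charge; defaults to the adduct's own charge.
#' @return m/z in Th.
#' @examples
#' adduct_mz(884.7833, "+Na")  # 907.7725
#' @export
adduct_mz <- function(neutral_mass, adduct = "+H", z = NULL) {
  spec <- if (is.list(adduct)) adduct else adduct_spec(adduct)
  if (is.null(z)) z <- spec$charge
  if (z < 1) stop("charge z must be >= 1")
  if (z != spec$charge && spec$name != "none") {
    stop("charge z = ", z, " inconsistent with adduct ", spec$name,
         " (charge ", spec$charge, ")")
  }
  (neutral_mass + spec$mass_delta) / z
}

#' Neutral mass from an adducted m/z (inverse of [adduct_mz()])
#' @inheritParams adduct_mz
#' @param mz Observed m/z (Th).
#' @return Neutral monoisotopic mass in Da.
#' @export
neutral_mass <- function(mz, adduct = "+H", z = NULL) {
  spec <- if (is.list(adduct)) adduct else adduct_spec(adduct)
  if (is.null(z)) z <- spec$charge
  mz * z - spec$mass_delta
}

## ---- isotope envelope ------------------------------------------------------

#' Carbon isotope envelope of an ion
#'
#' Peaks spaced by `1.00336 / z` Th starting at the monoisotopic m/z, with
#' relative intensities from a binomial model on 13C abundance (0.0107) over
#' the carbon count. Heavy isotopes of H and O are below 0.04% and ignored.
#'
#' @param f Ion elemental formula (adduct included) or formula string.
#' @param z Charge state (>= 1).
#' @param n_peaks Number of isotopologue peaks to return (>= 2).
#' @return data.frame with columns `mz` and `relative_intensity` (base peak
#'   normalized to 1).
#' @export
isotope_envelope <- function(f, z = 1L, n_peaks = 3L) {
  f <- as_formula_arg(f)
  if (length(f) == 0) stop("empty formula has no isotope envelope")
  if (n_peaks < 2) stop("n_peaks must be >= 2")
  if (z < 1) stop("charge z must be >= 1")
  n_c <- if ("C" %in% names(f)) unclass(f)[["C"]] else 0L
  mz0 <- (monoisotopic_mass(f) - z * .electron_mass) / z
  k <- 0:(n_peaks - 1L)
  rel <- stats::dbinom(k, size = n_c, prob = .c13_abundance)
  rel <- rel / max(rel)
  data.frame(mz = mz0 + k * .c13_spacing / z, relative_intensity = rel)
}
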