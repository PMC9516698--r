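# Candidate lipid identification from accurate mass, CCS and MSMS fragment
# evidence, with MSI confidence levels. The candidate database is generated
# combinatorially from TG/DG composition ranges; reference standards (with
# printed m/z, CCS and fragment values) are packaged as TSV.

#' Build the combinatorial lipid candidate database
#'
#' Exhaustive TG and DG compositions over total-carbon and double-bond
#' ranges, expanded to elemental formulas and deduplicated by formula. The
#' default TG range (45-57 carbons, 0-8 double bonds) spans the sebum TG
#' window: singly protonated/sodiated species fall in m/z 700-950.
#'
#' @param tg_carbons,tg_double_bonds TG total acyl carbon / double-bond
#'   ranges.
#' @param dg_carbons,dg_double_bonds DG ranges.
#' @return data.frame: `shorthand`, `class`, `carbons`, `double_bonds`,
#'   `formula`, `neutral_mass`, sorted by mass.
#' @export
build_lipid_db <- function(tg_carbons = 45:57, tg_double_bonds = 0:8,
                           dg_carbons = 24:40, dg_double_bonds = 0:6) {
  if (length(tg_carbons) == 0 && length(dg_carbons) == 0) {
    stop("empty composition ranges")
  }
  rows <- rbind(
    if (length(tg_carbons) > 0)
      expand.grid(class = "TG", carbons = tg_carbons, db = tg_double_bonds,
                  stringsAsFactors = FALSE),
    if (length(dg_carbons) > 0)
      expand.grid(class = "DG", carbons = dg_carbons, db = dg_double_bonds,
                  stringsAsFactors = FALSE))
  sh <- sprintf("%s %d:%d", rows$class, rows$carbons, rows$db)
  formulas <- vapply(sh, function(s) format_formula(lipid_formula(s)),
                     character(1), USE.NAMES = FALSE)
  db <- data.frame(shorthand = sh, class = rows$class,
                   carbons = rows$carbons, double_bonds = rows$db,
                   formula = formulas,
                   neutral_mass = vapply(formulas, monoisotopic_mass,
                                         numeric(1), USE.NAMES = FALSE))
  db <- db[!duplicated(db$formula), ]
  db <- db[order(db$neutral_mass), ]
  rownames(db) <- NULL
  db
}

#' Packaged lipid standards table
#'
#' Reference standards with their printed adducted m/z, charge, CCS and MSMS
#' fragment values: sodiated TG 54:3 (907.79 Th, 335.8 Angstrom^2, fragments
#' 603.55 / 339.29 / 265.26), PI 33:1 as the water-loss protonated ion
#' (822.62 Th, 318.2 Angstrom^2; values stored verbatim as printed) and
#' protonated DG 28:2 (14:1/14:1; 509.42 Th, 243.3 Angstrom^2).
#'
#' @param path Optional TSV path overriding the packaged table.
#' @return data.frame with `name`, `shorthand`, `adduct`, `mz`, `charge`,
#'   `reference_ccs`, `fragments` (list column of fragment m/z vectors).
#' @export
lipid_standards <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "lipid_standards.tsv",
                        package = "sebumIMS", mustWork = TRUE)
  }
  d <- utils::read.delim(path, comment.char = "#")
  d$fragments <- lapply(strsplit(ifelse(is.na(d$fragments), "",
                                        d$fragments), ";"),
                        function(x) as.numeric(x[nzchar(x)]))
  d
}

#' Accurate-mass search against the candidate database
#'
#' @param mz Observed m/z (Th).
#' @param z Charge state of the observed feature.
#' @param adducts Adduct names to consider (restricted to those matching the
#'   charge).
#' @param db Candidate database from [build_lipid_db()].
#' @param tol_ppm Match tolerance in ppm (> 0).
#' @return data.frame of (candidate, adduct) pairs within tolerance, with
#'   `theoretical_mz` and signed `ppm`, sorted by absolute ppm error.
#' @export
match_mass <- function(mz, z = 1L, adducts = c("+H", "+Na", "+K", "+NH4"),
                       db = build_lipid_db(), tol_ppm = 10) {
  if (tol_ppm <= 0) stop("tol_ppm must be positive")
  specs <- lapply(adducts, adduct_spec)
  specs <- specs[vapply(specs, function(s) s$charge == z, logical(1))]
  hits <- list()
  for (spec in specs) {
    theo <- (db$neutral_mass + spec$mass_delta) / z
    ppm <- ppm_error(mz, theo)
    sel <- abs(ppm) <= tol_ppm
    if (any(sel)) {
      h <- db[sel, c("shorthand", "class", "formula", "neutral_mass")]
      h$adduct <- spec$name
      h$theoretical_mz <- theo[sel]
      h$ppm <- ppm[sel]
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) {
    return(data.frame(shorthand = character(0), class = character(0),
                      formula = character(0), neutral_mass = numeric(0),
                      adduct = character(0), theoretical_mz = numeric(0),
                      ppm = numeric(0)))
  }
  out <- do.call(rbind, hits)
  out <- out[order(abs(out$ppm)), ]
  rownames(out) <- NULL
  out
}

#' CCS percent difference against a reference value
#'
#' @param measured,reference CCS values in Angstrom^2 (`reference > 0`).
#' @return List with `percent` (signed) and `abs_percent`.
#' @examples
#' match_ccs(336.5, 335.8)  # +0.21% (prints as 0.2%)
#' match_ccs(249.2, 243.3)  # +2.4%
#' @export
match_ccs <- function(measured, reference) {
  if (any(reference <= 0)) stop("reference CCS must be positive")
  pct <- (measured - reference) / reference * 100
  list(percent = pct, abs_percent = abs(pct))
}

#' Predict MSMS fragments of a sodiated triacylglyceride
#'
#' Encodes the collision-induced dissociation of `[TG + Na]+`: for each
#' distinct acyl chain, (i) a DG-like ion from neutral loss of the sodium
#' carboxylate (fatty acid - H + Na), (ii) an MG-like ion from further loss
#' of one acyl ketene (fatty acid - H2O), and (iii) the acylium cation
#' RCO+ (fatty acid - OH, as a cation). For triolein (tri-18:1, sodiated at
#' 907.77 Th) this yields 603.53, 339.29 and 265.25 Th.
#'
#' @param shorthand TG shorthand; per-chain form (`"TG 18:1/18:1/18:1"`) or
#'   summed totals divisible into identical chains (`"TG 54:3"` = tri-18:1).
#' @param adduct Must be `"+Na"` (protonated-TG rules are not encoded).
#' @return data.frame: `fragment` type, `chain`, `mz`.
#' @export
predict_fragments <- function(shorthand, adduct = "+Na") {
  lip <- if (is.character(shorthand)) parse_lipid(shorthand) else shorthand
  if (lip$class != "TG") stop("fragment rules are encoded for TG only")
  if (adduct != "+Na") stop("fragment rules are encoded for sodiated TG only")
  chains <- lip$chains
  if (is.null(chains)) {
    if (lip$carbons %% 3L != 0L || lip$double_bonds %% 3L != 0L) {
      stop("per-chain composition required for asymmetric TG ", format(lip))
    }
    chains <- data.frame(carbons = rep(lip$carbons / 3L, 3),
                         double_bonds = rep(lip$double_bonds / 3L, 3))
  }
  chains <- unique(chains)
  chains <- chains[chains$carbons > 0, , drop = FALSE]   # skip 0:0 stubs
  precursor <- adduct_mz(monoisotopic_mass(lipid_formula(lip)), "+Na")
  m_h <- monoisotopic_mass("H"); m_na <- monoisotopic_mass("Na")
  m_h2o <- monoisotopic_mass("H2O"); m_oh <- monoisotopic_mass("HO")
  out <- lapply(seq_len(nrow(chains)), function(i) {
    fa <- monoisotopic_mass(fatty_acid_formula(chains$carbons[i],
                                               chains$double_bonds[i]))
    dg_like <- precursor - (fa - m_h + m_na)   # sodium carboxylate loss
    mg_like <- dg_like - (fa - m_h2o)          # acyl ketene loss
    acylium <- fa - m_oh - .electron_mass      # RCO+
    data.frame(fragment = c("DG_like", "MG_like", "acylium"),
               chain = sprintf("%d:%d", chains$carbons[i],
                               chains$double_bonds[i]),
               mz = c(dg_like, mg_like, acylium))
  })
  out <- do.call(rbind, out)
  attr(out, "precursor_mz") <- precursor
  out
}

#' Score MSMS fragment evidence for a candidate
#'
#' `confirmed` when at least two expected fragment ions are matched in the
#' observed spectrum. For PI candidates the characteristic 259-Da head-group
#' neutral loss is required: its absence (no peak at precursor - 259.02 Th)
#' `contradicts` the PI identification. With no spectrum the evidence is
#' `untested`.
#'
#' @param observed_mz Observed fragment m/z values (NULL when no MSMS was
#'   acquired).
#' @param expected_mz Predicted fragment m/z values.
#' @param tol Absolute match tolerance in Th (> 0; default 0.02).
#' @param candidate_class Lipid class of the candidate (`"PI"` triggers the
#'   neutral-loss rule).
#' @param precursor_mz Precursor m/z, required for the PI rule.
#' @param min_matches Matches needed for confirmation (default 2).
#' @return `"confirmed"`, `"contradicted"` or `"untested"`.
#' @export
check_fragments <- function(observed_mz, expected_mz = NULL, tol = 0.02,
                            candidate_class = "TG", precursor_mz = NULL,
                            min_matches = 2L) {
  if (tol <= 0) stop("tol must be positive")
  if (is.null(observed_mz) || length(observed_mz) == 0) return("untested")
  if (candidate_class == "PI") {
    if (is.null(precursor_mz)) stop("precursor_mz required for the PI rule")
    nl <- precursor_mz - 259.02
    if (!any(abs(observed_mz - nl) <= tol)) return("contradicted")
    return("confirmed")
  }
  if (is.null(expected_mz) || length(expected_mz) == 0) return("untested")
  n_hit <- sum(vapply(expected_mz,
                      function(f) any(abs(observed_mz - f) <= tol),
                      logical(1)))
  if (n_hit >= min_matches) "confirmed" else "untested"
}

#' Assign an MSI identification confidence level
#'
#' Level 1 requires accurate mass, CCS and fragment evidence all passing;
#' level 2 mass + CCS; level 3 mass only; contradicted fragment evidence
#' voids the annotation regardless of mass/CCS.
#'
#' @param mass_ppm Signed mass error in ppm (NA when no candidate).
#' @param ccs_pct CCS percent difference (NA when no CCS reference).
#' @param fragment_evidence `"confirmed"`, `"contradicted"` or `"untested"`.
#' @param ppm_tol Mass threshold (default 10 ppm).
#' @param ccs_tol CCS threshold (default 2%).
#' @return `"1"`, `"2"`, `"3"` or `"unannotated"`.
#' @export
assign_msi_level <- function(mass_ppm, ccs_pct = NA_real_,
                             fragment_evidence = "untested",
                             ppm_tol = 10, ccs_tol = 2) {
  if (fragment_evidence == "contradicted") return("unannotated")
  mass_ok <- !is.na(mass_ppm) && abs(mass_ppm) <= ppm_tol
  ccs_ok <- !is.na(ccs_pct) && abs(ccs_pct) <= ccs_tol
  frag_ok <- fragment_evidence == "confirmed"
  if (mass_ok && ccs_ok && frag_ok) "1"
  else if (mass_ok && ccs_ok) "2"
  else if (mass_ok) "3"
  else "unannotated"
}

#' Annotate features with lipid candidates and MSI levels
#'
#' For each feature: accurate-mass search against the combinatorial database
#' and the standards table, CCS comparison against a matching standard when a
#' measured CCS is available, fragment scoring when an MSMS spectrum is
#' supplied, and MSI level assignment.
#'
#' @param features data.frame with `mz`, `charge` and optionally `ccs`; NA
#'   charge is treated as 1.
#' @param db Candidate database ([build_lipid_db()]).
#' @param standards Standards table ([lipid_standards()]).
#' @param msms Optional named list of MSMS spectra (data.frames with `mz`),
#'   keyed by row index or `feature_id`.
#' @param tol_ppm Accurate-mass tolerance (default 10).
#' @param standards_tol_ppm Tolerance for direct printed-m/z standard matches
#'   (default 15; the PI standard case prints an 11 ppm error).
#' @param ccs_tol CCS threshold in percent (default 2).
#' @param fragment_tol MSMS match tolerance in Th (default 0.02).
#' @return data.frame: feature columns plus `candidate`, `candidate_class`,
#'   `adduct`, `mass_ppm`, `ccs_pct`, `fragment_evidence`, `msi_level`.
#' @export
annotate_features <- function(features, db = build_lipid_db(),
                              standards = lipid_standards(), msms = NULL,
                              tol_ppm = 10, standards_tol_ppm = 15,
                              ccs_tol = 2, fragment_tol = 0.02) {
  n <- nrow(features)
  out <- data.frame(candidate = rep(NA_character_, n),
                    candidate_class = NA_character_, adduct = NA_character_,
                    mass_ppm = NA_real_, ccs_pct = NA_real_,
                    fragment_evidence = "untested",
                    msi_level = "unannotated", stringsAsFactors = FALSE)
  key <- if ("feature_id" %in% names(features)) features$feature_id
         else as.character(seq_len(n))
  for (i in seq_len(n)) {
    z <- features$charge[i]
    if (is.na(z)) z <- 1L
    hits <- match_mass(features$mz[i], z, db = db, tol_ppm = tol_ppm)
    # standards matched directly on their printed adducted m/z
    std_ppm <- ppm_error(features$mz[i], standards$mz)
    std_sel <- which(abs(std_ppm) <= standards_tol_ppm &
                       standards$charge == z)
    best <- NULL
    if (nrow(hits) > 0) {
      best <- list(name = hits$shorthand[1], class = hits$class[1],
                   adduct = hits$adduct[1], ppm = hits$ppm[1])
    } else if (length(std_sel) > 0) {
      j <- std_sel[which.min(abs(std_ppm[std_sel]))]
      best <- list(name = standards$name[j],
                   class = sub(" .*$", "", standards$shorthand[j]),
                   adduct = standards$adduct[j], ppm = std_ppm[j])
    }
    if (is.null(best)) next
    out$candidate[i] <- best$name
    out$candidate_class[i] <- best$class
    out$adduct[i] <- best$adduct
    out$mass_ppm[i] <- best$ppm
    # CCS evidence against a standard of the same shorthand/name
    if ("ccs" %in% names(features) && !is.na(features$ccs[i])) {
      std_row <- which(standards$shorthand == best$name |
                         standards$name == best$name)
      if (length(std_row) > 0) {
        out$ccs_pct[i] <- match_ccs(features$ccs[i],
                                    standards$reference_ccs[std_row[1]])$percent
      }
    }
    # fragment evidence
    spec <- NULL
    if (!is.null(msms)) {
      spec <- msms[[key[i]]]
      if (is.null(spec) && !is.null(msms[[as.character(i)]])) {
        spec <- msms[[as.character(i)]]
      }
    }
    if (!is.null(spec)) {
      expected <- if (best$class == "TG" && best$adduct == "+Na") {
        tryCatch(predict_fragments(best$name)$mz, error = function(e) NULL)
      } else NULL
      out$fragment_evidence[i] <- check_fragments(
        spec$mz, expected, tol = fragment_tol,
        candidate_class = best$class, precursor_mz = features$mz[i])
    }
    out$msi_level[i] <- assign_msi_level(out$mass_ppm[i], out$ccs_pct[i],
                                         out$fragment_evidence[i],
                                         ppm_tol = tol_ppm,
                                         ccs_tol = ccs_tol)
  }
  cbind(features, out)
}
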