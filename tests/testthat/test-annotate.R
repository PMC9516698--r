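test_that("the combinatorial database enumerates TG/DG compositions", {
  db <- build_lipid_db()
  tg <- db[db$class == "TG", ]
  expect_equal(nrow(tg), 13 * 9)     # 45-57 carbons x 0-8 double bonds
  expect_true("C57H104O6" %in% tg$formula)          # TG 54:3
  expect_true("C32H62O5" %in% db$formula[db$class == "DG"])  # DG 29:0
  expect_false(is.unsorted(db$neutral_mass))
  expect_false(any(duplicated(db$formula)))
  # masses agree with an independent recomputation through the formulas
  idx <- c(5, 50, 100, nrow(db))
  expect_equal(db$neutral_mass[idx],
               vapply(db$formula[idx], monoisotopic_mass, numeric(1),
                      USE.NAMES = FALSE), tolerance = 1e-12)
  # sodiated TGs with plausible saturation stay in the 700-950 Th window
  sel <- tg$double_bonds <= 6
  mzs <- (tg$neutral_mass[sel] + adduct_spec("+Na")$mass_delta)
  expect_true(all(mzs > 700 & mzs < 960))
  expect_error(build_lipid_db(tg_carbons = integer(0),
                              dg_carbons = integer(0)), "empty")
})

test_that("accurate-mass search ranks the printed identifications first", {
  db <- build_lipid_db()
  hits <- match_mass(907.77, z = 1, db = db, tol_ppm = 10)
  expect_equal(hits$shorthand[1], "TG 54:3")
  expect_equal(hits$adduct[1], "+Na")
  # the DG 29:0 case: printed m/z 527.47 at ~5.7 ppm (either 12:0/17:0 or
  # 13:0/16:0 -- identical formula, one record)
  hits2 <- match_mass(527.47, z = 1, db = db, tol_ppm = 10)
  expect_equal(hits2$shorthand[1], "DG 29:0")
  expect_equal(hits2$ppm[1], 5.7, tolerance = 0.1)
  # over-tight tolerance returns nothing
  expect_equal(nrow(match_mass(527.47, z = 1, db = db, tol_ppm = 0.1)), 0)
})

test_that("every reported mass hit satisfies the tolerance on recomputation", {
  set.seed(61)
  db <- build_lipid_db()
  # query at jittered true positions (hits guaranteed) and at random ones
  probes <- c((db$neutral_mass[sample(nrow(db), 15)] +
                 adduct_spec("+Na")$mass_delta) * (1 + runif(15, -8e-6, 8e-6)),
              runif(10, 500, 960))
  n_checked <- 0L
  for (mz in probes) {
    hits <- match_mass(mz, z = 1, db = db, tol_ppm = 10)
    if (nrow(hits) == 0) next
    theo <- vapply(seq_len(nrow(hits)), function(i) {
      adduct_mz(monoisotopic_mass(hits$formula[i]), hits$adduct[i])
    }, numeric(1))
    expect_true(all(abs(ppm_error(mz, theo)) <= 10))
    n_checked <- n_checked + 1L
  }
  expect_gte(n_checked, 15)
})

test_that("CCS percent differences reproduce the worked examples", {
  expect_equal(round(match_ccs(336.5, 335.8)$percent, 1), 0.2)
  expect_equal(round(match_ccs(249.2, 243.3)$percent, 1), 2.4)
  expect_equal(match_ccs(300, 300)$percent, 0)
  expect_equal(match_ccs(294, 300)$abs_percent, 2)
  expect_error(match_ccs(300, 0), "positive")
})

test_that("sodiated-TG fragment prediction matches triolein", {
  fr <- predict_fragments("TG 54:3")
  expect_equal(nrow(fr), 3)   # symmetric TG: one distinct chain
  expect_equal(fr$mz[fr$fragment == "DG_like"], 603.53, tolerance = 5e-3)
  expect_equal(fr$mz[fr$fragment == "MG_like"], 339.29, tolerance = 5e-3)
  expect_equal(fr$mz[fr$fragment == "acylium"], 265.25, tolerance = 5e-3)
  # internal consistency: DG-like - MG-like = one acyl ketene
  ketene <- monoisotopic_mass(fatty_acid_formula(18, 1)) -
    monoisotopic_mass("H2O")
  expect_equal(fr$mz[fr$fragment == "DG_like"] -
                 fr$mz[fr$fragment == "MG_like"], ketene, tolerance = 1e-9)
  # mixed chains: one ion triple per distinct chain (the 14-Da variations)
  fr2 <- predict_fragments("TG (16:0/18:1/18:2)")
  expect_equal(nrow(fr2), 9)
  expect_equal(length(unique(fr2$chain)), 3)
  expect_error(predict_fragments("DG 28:2"), "TG only")
  expect_error(predict_fragments("TG 54:3", adduct = "+H"), "sodiated")
  expect_error(predict_fragments("TG 55:3"), "per-chain")
})

test_that("fragment evidence scoring follows the confirmation and PI rules", {
  expected <- predict_fragments("TG 54:3")$mz
  expect_equal(check_fragments(c(603.53, 339.29, 100.1), expected), "confirmed")
  expect_equal(check_fragments(c(603.53, 100.1), expected), "untested")
  expect_equal(check_fragments(NULL, expected), "untested")
  # PI: absence of the 259-Da head-group loss contradicts the candidate
  expect_equal(check_fragments(c(500.1, 600.2), candidate_class = "PI",
                               precursor_mz = 822.62), "contradicted")
  expect_equal(check_fragments(c(822.62 - 259.02, 600.2),
                               candidate_class = "PI",
                               precursor_mz = 822.62), "confirmed")
  expect_error(check_fragments(c(1, 2), expected, tol = 0), "positive")
})

test_that("MSI levels follow the three-evidence rule table", {
  expect_equal(assign_msi_level(2, 0.2, "confirmed"), "1")
  expect_equal(assign_msi_level(2, 0.2, "untested"), "2")
  expect_equal(assign_msi_level(2, NA, "untested"), "3")
  expect_equal(assign_msi_level(2, 5, "untested"), "3")
  expect_equal(assign_msi_level(NA, 0.2, "confirmed"), "unannotated")
  expect_equal(assign_msi_level(50, 0.2, "confirmed"), "unannotated")
  expect_equal(assign_msi_level(2, 0.2, "contradicted"), "unannotated")
})

test_that("the packaged standards table stores the printed values", {
  std <- lipid_standards()
  tg <- std[std$name == "TG 54:3", ]
  expect_equal(tg$mz, 907.79)
  expect_equal(tg$reference_ccs, 335.8)
  expect_equal(tg$fragments[[1]], c(603.55, 339.29, 265.26))
  pi <- std[std$name == "PI 33:1", ]
  expect_equal(pi$mz, 822.62)
  expect_equal(pi$reference_ccs, 318.2)
  expect_equal(std$reference_ccs[std$name == "DG 14:1/14:1"], 243.3)
})
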