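test_that("formula parsing is exact and round-trips in Hill order", {
  f <- parse_formula("C57H104O6")
  expect_equal(unclass(f)[c("C", "H", "O")], c(C = 57L, H = 104L, O = 6L))
  expect_equal(format_formula(f), "C57H104O6")
  expect_equal(format_formula(parse_formula("O6H104C57")), "C57H104O6")
  expect_equal(unclass(parse_formula("C16H32O2")),
               c(C = 16L, H = 32L, O = 2L), ignore_attr = TRUE)
  expect_equal(format_formula(parse_formula("CH4")), "CH4")
  expect_error(parse_formula("C57H104O6X"), "unknown element")
  expect_error(parse_formula("C57#H104"), "malformed")
})

test_that("monoisotopic masses match reference values", {
  expect_equal(monoisotopic_mass("CH2"), 14.01565, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C16H32O2"), 256.2402, tolerance = 1e-6)
  expect_equal(monoisotopic_mass("C57H104O6"), 884.7833, tolerance = 1e-6)
  expect_equal(monoisotopic_mass(parse_formula("")), 0)
})

test_that("mass is additive and subtraction guards negative counts", {
  set.seed(11)
  els <- names(element_masses())
  for (i in 1:20) {
    f1 <- stats::setNames(sample(0:30, 4), sample(els, 4))
    f2 <- stats::setNames(sample(0:30, 3), sample(els, 3))
    s1 <- paste0(names(f1)[f1 > 0], f1[f1 > 0], collapse = "")
    s2 <- paste0(names(f2)[f2 > 0], f2[f2 > 0], collapse = "")
    if (!nzchar(s1) || !nzchar(s2)) next
    expect_equal(monoisotopic_mass(formula_add(s1, s2)),
                 monoisotopic_mass(s1) + monoisotopic_mass(s2),
                 tolerance = 1e-12)
  }
  expect_error(formula_subtract("CH4", "C2H2"), "negative")
  expect_equal(format_formula(formula_subtract("C57H104O6", "C16H32O2")),
               "C41H72O4")
})

test_that("lipid shorthand expands via condensation arithmetic", {
  expect_equal(format_formula(lipid_formula("TG 54:3")), "C57H104O6")
  expect_equal(format_formula(lipid_formula("DG 29:0")), "C32H62O5")
  # per-chain forms sum to the same totals (sn-position not mass-relevant)
  expect_equal(format_formula(lipid_formula("DG (12:0/17:0/0:0)")),
               format_formula(lipid_formula("DG 29:0")))
  expect_equal(format_formula(lipid_formula("TG 18:1/18:1/18:1")),
               "C57H104O6")
  # one H2 per double bond
  expect_equal(monoisotopic_mass(lipid_formula("TG 54:0")) -
                 monoisotopic_mass(lipid_formula("TG 54:3")),
               3 * 2.01565, tolerance = 1e-4)
  expect_error(lipid_formula("PI 33:1"), "not implemented")
  expect_error(parse_lipid("XX 10:0"), "unsupported lipid class")
})

test_that("TG/DG mass relations: ester condensation and estolide units", {
  palmitic <- monoisotopic_mass("C16H32O2")
  # esterifying one more 16:0 chain onto a DG loses one water
  for (cd in list(c(48, 2), c(54, 3), c(50, 0))) {
    d_mass <- monoisotopic_mass(lipid_formula(sprintf("TG %d:%d", cd[1], cd[2]))) -
      monoisotopic_mass(lipid_formula(sprintf("DG %d:%d", cd[1] - 16, cd[2])))
    expect_equal(d_mass, palmitic - monoisotopic_mass("H2O"),
                 tolerance = 1e-9)
  }
  # intact-C16H32O2 (estolide) addition gives the exact 256.24 Da spacing
  base <- lipid_formula("TG 66:2")
  expect_equal(monoisotopic_mass(formula_add(base, "C16H32O2")) -
                 monoisotopic_mass(base), 256.2402, tolerance = 1e-4)
})

test_that("adduct m/z accounts for the electron and inverts exactly", {
  expect_equal(adduct_mz(884.7833, "+Na"), 907.7725, tolerance = 1e-4)
  expect_equal(adduct_mz(526.4597, "+H"), 527.4670, tolerance = 1e-4)
  expect_equal(adduct_mz(500, "none"), 500)
  for (a in c("+H", "+Na", "+K", "+NH4", "+H-H2O", "+2H", "+H+Na", "+3H")) {
    spec <- adduct_spec(a)
    mz <- adduct_mz(884.7833, spec)
    expect_equal(neutral_mass(mz, spec), 884.7833, tolerance = 1e-9)
  }
  expect_error(adduct_mz(500, "+H", z = 0), "z must be")
  expect_error(adduct_spec("+Xx"), "unknown adduct")
})

test_that("isotope envelopes follow the carbon binomial model", {
  env1 <- isotope_envelope("C57H104O6", z = 1, n_peaks = 3)
  expect_equal(diff(env1$mz)[1], 1.00336, tolerance = 1e-5)
  env2 <- isotope_envelope("C57H104O6", z = 2, n_peaks = 3)
  expect_equal(diff(env2$mz)[1], 0.50168, tolerance = 1e-5)
  # A+1 / A ratio for 57 carbons
  expect_equal(env1$relative_intensity[2] / env1$relative_intensity[1],
               57 * 0.0107 / 0.9893, tolerance = 1e-3)
  # normalized to base peak; monotone decay after the mode below 90 carbons
  for (f in c("C30H50O2", "C57H104O6", "C80H140O6")) {
    env <- isotope_envelope(f, n_peaks = 5)
    expect_equal(max(env$relative_intensity), 1)
    mode_k <- which.max(env$relative_intensity)
    if (mode_k < 5) {
      expect_true(all(diff(env$relative_intensity[mode_k:5]) < 0))
    }
  }
  expect_error(isotope_envelope(parse_formula(""), 1), "empty formula")
  expect_error(isotope_envelope("C10H20", n_peaks = 1), "n_peaks")
})

test_that("ppm error is signed and exact", {
  expect_equal(ppm_error(527.47, 527.4670), 5.69, tolerance = 0.01)
  expect_equal(ppm_error(907.78, 907.7725), 8.3, tolerance = 0.1)
  expect_equal(ppm_error(1000, 1000), 0)
  expect_equal(ppm_error(999.99, 1000), -10, tolerance = 1e-6)
  expect_error(ppm_error(500, 0), "positive")
})
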