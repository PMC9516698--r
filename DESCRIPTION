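Package: sebumIMS
Title: Paper-Spray Ion-Mobility Mass-Spectrometry Lipidomics Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for paper-spray ion-mobility mass-spectrometry
    (PS-IM-MS) profiling of sebum lipids. Provides elemental-formula and lipid
    shorthand arithmetic, a synthetic cohort generator with ground truth,
    isotope-based charge assignment, cross-sample feature alignment and
    normalization, traveling-wave CCS calibration (power-law model), drift-time
    cluster segmentation, homologous CH2/H2/palmitic-unit series and high-mass
    envelope detection, dimer adduct-hypothesis testing, frequentist and
    Bayesian (Gibbs-sampled mixture model) differential abundance with
    pseudo-internal-standard QC, and accurate-mass/CCS/MSMS lipid annotation
    with MSI confidence levels.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
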