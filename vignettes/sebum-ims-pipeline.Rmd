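---
title: "Methods: the sebumIMS PS-IM-MS analysis pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the sebumIMS PS-IM-MS analysis pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sebumIMS)
```

This vignette documents the models, algorithms and defaults behind
`sebumIMS`, and the design choices made where several reasonable options
existed. The package analyses paper-spray ion-mobility mass-spectrometry
(PS-IM-MS) peak lists of sebum: each detected ion is an (m/z, drift time,
intensity) triple, and a molecular feature is an m/z–drift-time pair tracked
across samples.

## The data model

Sebum is dominated by acyl glycerides. In drift time the high-mass signal
separates into five clusters — 2.5–3.5 ms, 3.5–5 ms, 6–7 ms, 7.5–9 ms and
9–10 ms — carrying nominal charges 3+, 2+, 2+, 1+ and 1+ respectively.
Within clusters, features form homologous series: CH2 ladders (14.0157 Da,
or 7.008 Th at z = 2), saturation ladders (2.0157 Da per double bond), and
high-mass envelopes spaced by the palmitic ester unit C16H32O2 (256.2402 Da).
Window boundaries are half-open `[low, high)`; prose window definitions leave
boundary membership undefined, so the convention is fixed here and tested.

## Mass arithmetic (chem)

All m/z arithmetic goes through one table of monoisotopic masses (IUPAC
values, hard-coded and mirrored in `inst/extdata/element_masses.tsv`). Ion
m/z always accounts for the electron mass; at sub-ppm work this matters
(the electron is 0.6 ppm of a 900 Th ion). Lipid shorthand expands by
condensation arithmetic — TG c:d is `C(c+3) H(2c−2d+2) O6`, DG c:d is
`C(c+3) H(2c−2d+4) O5` — so sodiated TG 54:3 (triolein) sits at 907.7725 Th.

Two mass relations are worth distinguishing. Esterifying one more 16:0
chain onto a DG adds palmitic acid *minus water* (238.23 Da), because
condensation releases H2O. The observed 256-Da spacing between high-mass
envelopes corresponds to an *intact* C16H32O2 unit, which is how
estolide-type (ester-linked fatty-acid) extensions accumulate mass; the
simulator builds its high-mass species this way, giving exact 256.2402-Da
spacings.

The isotope model is a carbon-only binomial on the 1.07% 13C abundance;
heavy isotopes of H and O contribute < 0.04% and are irrelevant at the
two-decimal precision used throughout. Note that above ~93 carbons the A+1
peak overtakes the monoisotopic peak — the charge-assignment and collapse
logic does not assume the first peak is the largest.

## Synthetic cohorts (simulate)

The generator emulates a two-cohort study at desk scale. Defaults, chosen
once as the package's reference conditions:

| parameter | default | rationale |
|---|---|---|
| samples per group | 20 | large enough for p < 0.05 discoveries, seconds-scale tests |
| species | 84 lipids + 3 standards | five clusters, CH2/H2 series, 3 estolide envelopes |
| effect | +1 log2 on clusters 3 and 5 (PD) | the clusters that differ between cohorts |
| m/z noise | 1 ppm s.d. | lock-mass-corrected instrument scale |
| drift noise | 0.05 ms s.d. | small relative to the 0.5–1 ms windows |
| intensity | log-normal, sdlog 0.5 | standard metabolomics intensity model |
| noise peaks | 500/sample, uniform m/z 50–2000, DT 0.5–12 ms | exponential intensities well below lipid signal |
| pseudo-standards | 103.05/1.0, 105.07/1.0, 109.10/1.2 (Th/ms) | effect-free matrix ions |

Intensities are in arbitrary units (no absolute scale is defined), so every
downstream statistic is scale-invariant. Each species emits a three-peak
isotope envelope; every non-noise peak is tagged with its species id in the
in-memory object (dropped when writing the documented CSV schema), so
accuracy can be scored exactly.

Drift times are generated *through the same calibration model the analysis
fits* (in the inverse direction), making the calibration round-trip testable
end-to-end. The default instrument model is a power law with B = 0.55,
c = 0.2, anchored so the sodiated TG 54:3 reference (335.8 Å²) arrives at
8.3 ms. The singly charged TG cluster takes its CCS from a linear trend
anchored at the printed standards (TG: 335.8 Å² at 907.77 Th; DG: 243.3 Å²
at 509.42 Th; slope 0.0587 Å²/Th, −0.2 Å² per double bond); the other
clusters are placed by mapping each series' m/z range onto a band inside
its drift window. The cluster-3 band is set low in its window
(6.05–6.45 ms) so that the charge-sanity argument — misreading the doubly
charged cluster as singly charged yields CCS values more than 10% below the
TG trend — holds for every member, not just on average.

What the generator does **not** emulate: chimeric/overlapping peak shapes,
profile-mode spectra, instrument drift over time, retention time, missing
lipids, or batch effects. Passing tests therefore demonstrate correctness of
the algorithms under clean ionization and alignment assumptions, not
robustness to every pathology of real instrument data.

## Charge assignment and alignment (features)

Charge is read from isotopic spacing: for each peak in ascending m/z, the
algorithm searches for companions at `+k·1.00336/z` (z in 1–3, up to 4
peaks) within 5 ppm, inside a 0.2 ms drift co-elution window, and with a
companion/predecessor intensity ratio of at most 2 (the 13C binomial never
exceeds ~1.6 below 150 carbons; the bound stops noise peaks from
"adopting" large true peaks as isotopologues). The charge with the most
consistent envelope wins; isotopologues are collapsed into the monoisotopic
feature. The 5 ppm companion tolerance deliberately excludes the saturation
neighbour: an A+2 isotope expectation and a one-double-bond-less neighbour
differ by 8.9 mTh (~10 ppm at 900 Th).

Alignment is greedy centroid clustering ordered by decreasing intensity
(deterministic; ties broken by m/z and drift time, so it is invariant to
sample order): each unclaimed peak seeds a row that absorbs at most one
peak per sample within 8 ppm and 0.3 ms. The drift tolerance is 4 standard
deviations of the pairwise drift jitter (0.05·√2 ms); at 0.2 ms (2.8 s.d.)
roughly half a percent of true members were dropped, and a single zero cell
badly inflates a feature's t-test variance — this is why the alignment
tolerance is looser than the isotope co-elution window.

Missing values are stored as 0. The frequentist tests use zeros as
measured; the Bayesian model treats them as left-censored at half the
sample's smallest positive intensity.

Normalization offers total-sum scaling ("TIC"; columns scaled to a 10^6
total, exactly invariant to per-column scale factors) and a
reference-scalar method (each column multiplied by the median ratio of
shared features to the feature-richest run). TIC is the pipeline default:
with ~35% of shared features shifted one-sidedly between cohorts and wide
per-feature spread, the median ratio sits in the null distribution's upper
tail and visibly biases the reference-scalar method, whereas TIC's bias is
only the differential features' share of total signal (~7% under the
default conditions). Both methods are idempotent and tested.

## CCS calibration (ccscal)

Traveling-wave instruments need empirical calibration. The model is the
classic log-log power law on reduced CCS:

- corrected drift `t' = dt − c·√(m/z)/1000` with c = 0.2 by default;
- reduced CCS `Ω' = CCS·√μ/z`, with μ the reduced mass against N2
  (28.0134 Da; configurable);
- least squares on `ln Ω' = ln A + B·ln t'`, requiring ≥ 3 calibrants.

The velocity relaxation parameter `a` is carried in the object and the
serialized JSON but is inert at its default 1.0: its functional role in the
vendor calibration tool is not recoverable, so it is surfaced as
configuration without effect (documented no-op). Fit diagnostics include
the ln-space residual s.d. and per-calibrant CCS residuals; calibrations
with any residual above 2% are flagged. A synthetic calibrant ladder
generated from the default instrument model ships in `inst/extdata` and is
user-replaceable by any TSV with columns `mz`, `charge`, `reference_ccs`,
`measured_dt`.

## Series, envelopes and dimer hypotheses (series)

Homologous-series detection grows maximal chains greedily from the
lowest-m/z unclaimed member, taking the nearest feature at the expected
next position within 15 ppm (the printed spacings have two decimals; 15 ppm
is comfortably wider than the simulator's jitter and narrower than any
competing spacing). Chains shorter than 3 are not reported, and a feature
belongs to at most one chain per unit.

Envelope detection smooths summed intensity along m/z with a Gaussian
kernel (bandwidth 10 Th — wide enough to merge 14-Da series members into
one hump, narrow versus the 256-Da envelope spacing), takes local maxima
with at least 1% of the modal density as centers, and flags pairwise center
spacings within ±4 Da of 256.2402 as ester-unit linked.

The dimer test treats each doubly charged m/z as `[M + A + B]²⁺` over all
unordered adduct pairs from {+H, +Na, +K}, derives the implied neutral M,
and searches the observed singly charged peaks for `[M + X]⁺` for every
adduct X. The generalized candidate form in the source literature mixes
addition and subtraction ambiguously; the implemented convention —
candidates are `[M + X]⁺` for each single adduct — is the chemically
coherent reading and is configurable through the adduct set. Only features
with isotope-confirmed charge 1 enter the query list; including unassigned
noise peaks (~10 peaks/Th) would produce spurious matches at any tolerance.
A matched fraction near 0 supports the monomer interpretation of the
doubly charged cluster; a planted dimer is the positive control.

## Differential abundance (diffabund)

Per feature, the frequentist layer reports a two-tailed Welch t-test,
one-way ANOVA (identical to the t-test for two groups, and asserted so),
the raw fold change, and the raw p < 0.05 selection flag the workflow uses;
Benjamini–Hochberg q-values are reported additionally as an extension.
Under the default conditions (n = 20 + 20, sdlog 0.5, 2× effect) the
t-test's per-feature power exceeds 0.9 and its type-I error is calibrated
(asserted within [3%, 7%] over 2000 null features).

The Bayesian layer is a per-feature hierarchical mixture on natural-log
intensities: observations are Normal around their group mean with a shared
variance (Normal/inverse-gamma conjugate priors; the group-mean prior s.d.
is `lambda_scale` × the feature's spread, default 10 — weakly informative);
each observation carries a latent correct-assignment indicator with prior
`p_reliability` (default 0.95), mis-assigned points coming from a broad
background; zeros are imputed from the truncated model below the detection
floor. A Gibbs sampler alternates imputation, indicators, means and
variance. Outputs are the posterior mean log fold change (natural log), a
central 95% credible interval, and the probability of up-regulation
`P(μ_PD > μ_control)`.

The sampler default is 100 iterations with a burn-in of 10. At 90 retained
(autocorrelated) draws the Monte-Carlo error of `probability_up` is wide —
around ±0.05 near 0.9 — which is visible as occasional dropouts at strict
probability thresholds; the iteration count is configurable and larger
values are recommended when the probability itself is the decision
quantity. With `p_reliability = 1` and no outliers the posterior log-ratio
collapses onto the frequentist log fold change (asserted).

Pseudo-internal-standard QC locates the three matrix ions by (m/z, DT),
t-tests them between cohorts at α = 0.05 per ion, and reports PASS/WARN
(missing ion)/FAIL, plus the per-sample summed intensity as a biomass
proxy. QC runs on the **raw** aligned matrix: the standards gauge
measurement noise, and normalization would transfer the cohort effect's
intensity share onto them, confounding the check. Note the three-ion
all-must-pass rule has an inherent ~14% false-alarm rate under the null
(no multiplicity correction, by design fidelity to the published rule).

## Annotation (annotate)

The candidate database is generated combinatorially — TG with 45–57 total
acyl carbons and 0–8 double bonds, DG with 24–40 and 0–6 — rather than
fetched from online resources (which carry little validation above
1400 Da); records are deduplicated by formula, so positional isomers such
as DG 12:0/17:0 vs 13:0/16:0 are one record. Accurate-mass search
enumerates (candidate, adduct) pairs within a ppm tolerance, sorted by
absolute error. Standards (sodiated TG 54:3 at 907.79 Th/335.8 Å² with
fragments 603.55/339.29/265.26; PI 33:1 at 822.62 Th/318.2 Å²; DG
14:1/14:1 at 243.3 Å²) are stored with their printed values verbatim — the
PI entry's printed m/z is not re-derivable from a PI 33:1 composition and
is deliberately not "corrected". Standards are matched at 15 ppm (the PI
case prints an 11 ppm error).

Sodiated-TG fragmentation is encoded as three neutral-loss rules per
distinct acyl chain: loss of the sodium carboxylate (DG-like ion), further
loss of one acyl ketene (MG-like ion), and the acylium cation. For
triolein these give 603.53, 339.29 and 265.25 Th. Protonated-TG rules are
not encoded (not demonstrated for this matrix). The PI negative rule
requires the characteristic 259.02-Da head-group neutral loss; its absence
contradicts a PI candidate outright.

MSI levels: level 1 = mass (|ppm| < 10) + CCS (|Δ| < 2%) + confirmed
fragments; level 2 = mass + CCS; level 3 = mass only; contradicted
fragments void the annotation. The thresholds are deliberately looser than
the best demonstrated case (5 ppm / 0.2%) and tighter than the accepted
"comparable" case (2.4% CCS is level 3 territory by default); both are
config-exposed.

## Pipeline, determinism and problem sizes

`run_pipeline()` chains the stages with one master seed (simulation uses
the seed, the Gibbs sampler seed + 1) and is bit-reproducible; the run
directory includes a manifest with the config's MD5 and package/R
versions. Features enter the differential stage when detected in at least
half the smaller group (standard presence filtering; it removes the
~20 000 singleton noise rows and keeps the ~90 real features).

Test-suite problem sizes are chosen for a laptop-minute budget: unit tests
use 4–8-sample cohorts; the parameter-recovery check pools five replicate
20 + 20 cohorts (~150 planted effect features) and asserts the pooled flag
rate ≥ 90% at p < 0.05 and probability_up > 0.95, false positives ≤ 7%,
and majority QC PASS — pooled rates, because each per-dataset rate is a
stochastic quantity whose single-cohort fluctuation is larger than the
margin being asserted.

## Known limitations

- Input is centroided peak lists; vendor raw formats and profile spectra
  are out of scope, as is the retention-time dimension.
- The charge assigner trusts isotope evidence only; it will not infer
  charge from cluster membership.
- The Bayesian model is a re-specified mixture (the published description
  names the priors and sampler but not the full generative model); its
  interface — p, Λ, Gibbs, 100 iterations, log-ratio/CI/probability
  outputs — is preserved.
- PI lipids are carried only as standards with literal values; no PI
  formula expansion.
- Kendrick mass-defect analysis, spectral-library cosine scoring,
  sn-isomer and double-bond-position resolution, and site-effect
  classifiers are deliberately out of scope.
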