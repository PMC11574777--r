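---
title: "Quadratic phenotypic optimization for drug-combination screens: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quadratic phenotypic optimization for drug-combination screens: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qpopr)
```

## The problem and the model

Functional precision medicine screens measure how a patient's tumor cells
respond ex vivo to drugs, and use those measurements to guide therapy.
Single-drug sensitivities do not capture combination effects, and testing
every combination of a k-drug panel at three dose levels would require 3^k
wells — 531,441 for k = 12. qpopr implements the quadratic phenotypic
optimization approach: a small designed subset of combinations is measured,
a second-order response surface is fitted, and the surface is then evaluated
at *all* 3^k dose-level combinations to rank them.

The response is normalized cell viability (NCV): the viability signal of a
treated well divided by the mean signal of untreated negative-control wells
on the same plate (1 = no effect, 0 = complete kill). Dose levels are coded
0 (absent), 1 (low), 2 (high) and enter the regression as normalized doses
x = 0, 0.5, 1, so coefficients are comparable across drugs regardless of
molar concentration. The fitted model is the full quadratic polynomial

  y(x) = b0 + sum_i b_i x_i + sum_i b_ii x_i^2 + sum_{i<j} b_ij x_i x_j,

with 1 + 2k + k(k−1)/2 coefficients (91 for k = 12). Negative linear
coefficients mean single-agent efficacy, the quadratic terms absorb
dose-response curvature between the three tested levels, and negative
interaction coefficients mean synergy beyond additivity. The model is
deliberately mechanism-agnostic: it interpolates the phenotype, it does not
explain it.

Estimation is ordinary least squares on the full 91-term model. The design
supports it (155 runs ≥ 91 terms, full column rank), so no term selection or
regularization is applied; the fit is therefore unique, fast and exactly
reproducible. Adjusted R² — 1 − (1 − R²)(n − 1)/(n − p − 1) with p the
number of non-intercept terms — is the reported robustness diagnostic.

## The experimental design

The test points form an orthogonal-array composite design (OACD): a
two-level fractional factorial at the extreme levels {absent, high},
concatenated with a three-level orthogonal array that contributes the
center level. For 12 drugs this is a 2^(12−5) fraction (128 runs) plus the
27-run three-level array: 155 test combinations.

Construction choices worth recording:

* **Fractional-factorial generators.** For each supported panel size the
  generator words are stored as data and re-validated at build time. All
  generator base words are distinct with odd length ≥ 3, which forces every
  word of the defining relation to have even length ≥ 4 — i.e. resolution at
  least IV (no main effect aliased with any two-factor interaction). The
  package does not take this on faith: every build runs an exhaustive alias
  check on the constructed matrix.
* **Joint estimability.** Resolution IV alone does not guarantee that the
  *combined* design estimates all pairwise interactions: two-factor
  interactions aliased within the two-level portion must be separated by the
  three-level portion. The stored generator sets and the assignment of
  27-run-array columns to drugs were screened computationally so that the
  quadratic model matrix of the combined design has full column rank; the
  rank is re-verified on every `generate_oacd()` call. At some panel sizes
  (9, 11, 13) this required a larger two-level portion than the minimal
  resolution-IV fraction, because the 27-run array could not break all
  interaction aliases of the smaller fractions.
* **No extra center points.** The design adds no replicated center runs
  beyond the three-level array; replication enters through replicate wells
  of the same design row, if the layout provides them.
* **Dose caps.** The high tested concentration of each drug is validated
  against min(10% Cmax, IC10) where those values are supplied, keeping ex
  vivo dosing clinically achievable and preventing any single drug from
  dominating the screen.

## Plate processing and quality control

Wells are normalized to the mean of the plate's untreated negative controls;
replicate design wells are averaged (arithmetic mean, with the sample SD
retained for reporting). NCV values above 1 are retained — growth relative
to control is informative — and nothing is winsorized by default.

Assay quality is summarized on raw signals with sample (n−1) standard
deviations: Z' = 1 − 3(σ_pos + σ_neg)/|μ_pos − μ_neg| and
SSMD = (μ_neg − μ_pos)/√(σ_neg² + σ_pos²). A run is excluded when Z' falls
strictly below 0.7; the boundary value passes, since exclusion is defined by
Z' < 0.7. An excluded run yields a structured report with no model — the QC
gate is an expected outcome, not an error. The positive control is whatever
cytotoxic reference the layout declares; Z' on raw rather than normalized
signals is a package choice (Z' is invariant to the normalization's positive
scaling anyway).

## Ranking and report summaries

`enumerate_and_rank()` scores all 3^k coded combinations and sorts ascending
by predicted NCV, so rank 1 is the strongest predicted kill. Ties are broken
lexicographically on the level vector, making the ranking deterministic.
Report summaries are derived from the full ranking: the top-10 lists for
two- and three-drug combinations, and the pairwise-interaction
("polygonogram") matrix whose (i, j) entry is the minimum predicted NCV over
the four assignments of drugs i and j to levels {1, 2} with all other drugs
absent (diagonal: best single-drug value). Projection — other drugs at
zero — rather than marginalization is used because the display answers
"what could this pair do on its own".

A clinical regimen is scored with each administered drug at its highest
tested level and everything else absent; that score, compared against the
0.65 NCV cutoff, is the predicted responder / non-responder call (scores
exactly at the cutoff are non-responders, since responders are defined
strictly below it). Predicted NCV is never clipped; classification applies
to the raw score.

## Concordance statistics

The 2×2 confusion table (true positive = predicted responder with clinical
response; CR, CRi and PR all count as response) yields sensitivity,
specificity, PPV, NPV and accuracy, each with a 95% binomial interval.
Clopper–Pearson is the default interval; the continuity-corrected Wilson
interval is selectable because published concordance intervals are not
always derived from a single method and auditors may need both. Fisher's
exact test uses the standard two-sided minimum-likelihood rule (sum of
hypergeometric probabilities not exceeding that of the observed table);
degenerate margins return p = 1 with a warning rather than an error.

ROC analysis treats lower scores as more responder-like. AUC is computed
from the rank statistic with tie averaging (identical to the trapezoidal
area), and the operating threshold is chosen by maximizing Youden's
J = sensitivity + specificity − 1 over midpoints between adjacent distinct
scores, reporting the lowest maximizer on ties. Paired comparisons of two
candidate combinations across the same patients use the two-sided paired
t-test per subgroup; zero-variance difference vectors are flagged
degenerate instead of producing a misleading p-value.

## The synthetic-data generator

No patient-level raw data are published for screens of this kind, so the
package ships a generator that emulates the *statistical* structure the
pipeline assumes, making every stage testable end to end.

* **Truth surfaces.** Each synthetic patient has a ground-truth quadratic
  surface: baseline exactly 1; per-drug top-dose kill fractions drawn
  uniformly from 0.10–0.40; dose-response curvature expressed as the
  half-dose effect fraction (0.4–0.6 of the top-dose effect, 0.5 = linear);
  a weak *antagonistic* interaction background with mean
  saturation × Σ(effects)/npairs (saturation 1.2) — overlapping cytotoxic
  mechanisms saturate rather than stack — plus configurable synergy pairs
  whose strengths receive only a small jitter (SD 0.01).
* **Viability floor.** A quadratic with meaningful single-agent effects goes
  negative when many drugs stack, which a viability readout cannot do. All
  drug-effect terms are therefore rescaled, when necessary, so the lowest
  predicted NCV over the design rows equals the viability floor (default
  0.10). Scaling is a monotone transform of the surface (y = 1 + s·effect),
  so it preserves the combination ranking; the applied factor is stored in
  `attr(truth, "calibration_scale")`. This guarantee is what makes the
  zero-noise simulate → normalize → fit round trip exact.
* **Plates.** Raw design-well signal = 10,000 RLU × max(0, truth NCV +
  Gaussian noise), default noise SD 0.05 NCV units, with triplicate wells
  per design row by default (the assay's standard replication; replicate
  NCVs are averaged before fitting, and a triplicate 155-row run plus
  controls exceeds one 384-well plate, so well identifiers then become
  plain sequential labels). Negative controls read near 10,000 RLU and
  cytotoxic positive controls near 2% of it; control wells get 40% of the
  treated-well noise SD, reflecting that undosed homogeneous wells vary
  less than dispensed treatments (and giving default plates Z' ≈ 0.85–0.90,
  comfortably above the 0.7 gate).
* **Cohorts.** Each patient receives an independent surface, one plate, a
  regimen sampled from a configurable pool (default: the doublet of a
  hypomethylating agent plus a BCL-2 inhibitor most frequent at 38%,
  mirroring its clinical prevalence), and a clinical label equal to the
  true-surface call (true regimen NCV < 0.65) XOR-flipped with probability
  ε (default 0.1). Tying labels to the same 0.65 rule the classifier uses
  isolates pipeline correctness from biological validity — deliberately.
  Disease-stage (ND/RR, default 20:9) and ELN-risk tags are drawn
  independently of the surfaces; subgroup analyses on synthetic cohorts
  therefore test bookkeeping, not biology.
* **Calibration scenarios.** With zero plate noise the fitted surface equals
  the truth, so cohort misclassification comes only from flipped labels and
  overall accuracy converges to 1 − ε at any responder prevalence. The
  *conditional* rates (sensitivity, specificity) converge to 1 − ε only in
  a balanced cohort: with prevalence r, zero-noise sensitivity is
  0.9r/(0.9r + 0.1(1 − r)), which equals 0.9 only at r = 0.5. The
  calibration scenario therefore uses a regimen mix whose true responder
  rate is ≈ 0.5 (weights 0.30/0.36/0.11/0.15/0.08 over the default pool,
  estimated once from the generator's regimen score distributions). This is
  a property of the experiment's design, chosen before running it, not a
  quantity fitted to any observed test outcome.
* **Serial resistance.** One patient, several runs: the resistant drug's
  linear coefficient starts at −0.5 (then floor-calibrated with the rest of
  the surface) and moves toward 0 by 0.1 per run, everything else held
  fixed. Weakening one drug only raises predictions, so the floor guarantee
  survives the drift and the drug's single-agent NCV increases strictly
  across runs.

What the generator does *not* emulate: spatial plate effects (edge wells,
dispensing gradients), heteroscedastic or multiplicative noise, correlated
patient surfaces, any mechanistic link between subgroup tags and drug
response, and real inter-patient variance structure (unpublished). Passing
tests on synthetic data therefore demonstrate that the *pipeline* is
correct — designs are estimable, fits recover known truths, statistics match
their definitions — not that the quadratic model is biologically adequate
for any particular tumor type.

## Numerical conventions and problem sizes

* Coded levels {0,1,2} map to regression inputs {0, 0.5, 1}.
* Ranking tie-break: lexicographic on the level vector, leftmost drug most
  significant.
* QC boundary inclusive: Z' = 0.7 passes.
* NCV = 0.65 classifies as non-responder.
* Fits use QR decomposition with an explicit rank check; rank deficiency is
  an error instructing a design check, never a silent pseudo-inverse.
* Simulation-based tests use: 500 seeds for small-panel coefficient
  unbiasedness, 200 seeds for 12-drug recovery (noise SD 0.05) and for
  serial-trend recovery, 2000 patients for label-noise calibration, and
  full enumeration (3^12 = 531,441) for the ranking checks. These sizes
  give comfortable margins on the assertions while keeping the default test
  run fast.

## Known limitations

* The quadratic surface cannot represent saturation: predictions at
  many-drug corners can fall below 0 or above 1 and are reported unclipped.
  Rankings are still well-defined; absolute NCV predictions far from the
  design region should not be over-interpreted.
* The OACD contains no runs with only one or two active drugs, so
  single-drug and doublet predictions are extrapolations with substantial
  leverage (h ≈ 14.5 for a single drug at top dose, h ≈ 21 for a doublet on
  the 12-drug design). Their standard error is noise_sd × √h — several times
  the per-well noise. Consequences: regimen scores carry real estimation
  uncertainty at realistic noise, and a serial drift of 0.1 NCV per run in a
  drug's single-agent effect is recovered monotonically only when the
  per-run noise SD is below about 0.01 (the serial-trend recovery test runs
  in that regime; at noise 0.02 the recovery rate is only ~65%, exactly as
  OLS theory predicts).
* Enumeration is bounded at 3^13 combinations; larger panels need a
  different search strategy and are refused explicitly.
* The pairwise interaction matrix projects pairs in isolation; it is not a
  marginal effect over realistic co-administration backgrounds.
* Confidence intervals for concordance metrics are exact per metric but not
  simultaneous across metrics.
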