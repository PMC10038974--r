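---
title: "Solanidine metabolic ratios as a CYP2D6 poor-metabolizer classifier: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Solanidine metabolic ratios as a CYP2D6 poor-metabolizer classifier}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(solapheno)
```

## Scientific background

CYP2D6 activity varies enormously between patients because the *CYP2D6* gene
is highly polymorphic. Genotype panels translate a diplotype — two star
alleles, possibly with a gene duplication — into a predicted metabolizer
phenotype; the clinically critical group is the poor metabolizers (PMs), who
carry two lack-of-function alleles and no CYP2D6 activity. Solanidine, a
dietary alkaloid from potatoes, is cleared by CYP2D6, so the serum ratio of
a solanidine metabolite to solanidine itself collapses by orders of
magnitude in PMs. `solapheno` implements the full analysis chain that turns
this observation into a validated classifier: genotype translation,
(optional) targeted HRMS re-extraction, truncation and ratio computation,
stratified cohort splitting, ROC threshold derivation with validation-cohort
evaluation, and genotype/age/sex regression models — plus a calibrated
simulator that makes the whole chain testable end to end.

## Genotype translation

The supported panel is the eight-allele laboratory panel: defective *3, *4,
*5, *6; reduced-function *9, *10, *41; wild-type *1. The phenotype grouping
is the DPWG/CPIC-style consensus used by the reference laboratory, with two
deliberate properties:

* ***1/red counts as NM.*** Current CPIC activity scoring places *1/*41 in
  IM; the laboratory grouping implemented here predates that boundary and
  keeps *1/red in NM. We implement the laboratory grouping because the
  reference model's contrasts are defined on it.
* **Any duplication involving a reduced or defective allele is
  inconclusive.** Copy-number assays do not reveal *which* allele is
  duplicated, so *1/red xN, *1/def xN and pooled Red/def xN genotypes are
  split into cohorts but excluded from ROC and regression analyses. The
  pooled group also absorbs Red/red and Def/def duplications, which the
  reference cohort never observed; we make no claim about their activity.

## The outcome model and residual-SD calibration

Each of the eight outcomes (seven ln metabolite-to-solanidine ratios and the
ln solanidine concentration, nmol/L) follows

$$y = \beta_0 + \beta_{male}\,\mathrm{male} + \beta_{age}(\mathrm{age}-\bar a)
      + \beta_{g[i]} + \varepsilon,\qquad
      \varepsilon \sim N(0, \sigma^2),$$

with the *1/*1 female mean-age patient as reference. The reference
coefficient matrix is in `sola_ref_params()`. The reference parameterization
includes each model's $R^2$ but not $\sigma$; the generator therefore
calibrates

$$\sigma = \sqrt{\mathrm{Var}(X\beta)\,\frac{1-R^2}{R^2}},$$

where $\mathrm{Var}(X\beta)$ is evaluated analytically under the covariate
mixture: categorical genotype, Bernoulli sex, truncated-normal age (exact
truncated moments). Calibration uses the seven conclusive genotype groups
renormalized, since the published $R^2$ values come from fits that excluded
inconclusive genotypes. For the M414 ratio this gives $\sigma \approx 1.90$
ln-units; an OLS refit on a large simulated cohort then recovers both the
coefficients and $R^2$ (the parameter-recovery tests assert this at
n = 100,000).

Design choices the data could not pin down, decided once and kept:

* **Homoscedastic residuals across genotype groups.** Only pooled models are
  reported, so group-specific variances would be invented structure.
* **Outcomes independent given covariates.** No residual cross-metabolite
  correlations are reported; the generator draws outcomes independently.
  Consequences: joint statistics across markers (e.g. multi-marker rules)
  simulated here will look slightly cleaner than in real serum, where
  shared exposure and matrix effects correlate residuals.
* **Inconclusive groups borrow the contrast of their non-duplicated
  counterpart** (*1/red xN → *1/red, etc.). They never enter model fits, so
  this only shapes their simulated areas.
* **Age centered on the configured population mean** in generation, and on
  the analysis-sample mean in fitting, mirroring what an analyst can
  actually compute.

## Areas, detection limits and truncation

Concentrations are lognormal by construction
(`solanidine_conc = exp(ln C)`); the solanidine peak area is
`conc × area_per_nM` with a default response factor of 1000 area units per
nmol/L, chosen so the default detection limits land in the same magnitude
range (≈600–1300 area units) as the reference truncation constants.
Metabolite areas are `area_solanidine × exp(lnMR)`, so ratios are exact on
fully detected data.

Per-analyte limits of detection are solved deterministically
(`calibrate_lod()`): under the model, each analyte's ln area is a finite
normal mixture over genotype × sex cells, and the limit reproducing a target
detection fraction (reference values 76% for solanidine, 71/42/91/87/98/61/71%
for M402–M444) is the corresponding mixture quantile found by root-finding —
no simulation, no tuning. Undetected areas are then truncated to **half the
minimum detected area** of the analyte, ratios use the truncated areas, and
a patient leaves metabolite *m*'s analyses only when solanidine *and* *m*
are both undetected. For undetected solanidine the truncation area is pushed
through the same area→concentration mapping, keeping the concentration model
defined for everyone. Truncation constants are derived from the analysis
population after all subject exclusions by default, and can be pinned (e.g.
to previously published constants) for reproducing earlier analyses.

Note an instructive consequence visible in the worked examples: fitting the
model on truncation-imputed (censored) simulated data attenuates the large
negative PM contrasts relative to the latent model, exactly as it would on
real data. Model-level validation therefore uses the `lod = "none"` preset;
the censored preset exercises the robustness of the *classifier*, not the
recovery of latent coefficients.

## Splitting, ROC and evaluation conventions

* **Stratified 4:1 split** on PM and UM phenotypes (third stratum: everyone
  else), validation share `round(n/5)` with half rounded *up* — the only
  rounding that sends 58 PMs to 46 test / 12 validation every time.
  Inhibitor users are removed before splitting; inconclusive genotypes are
  split but flagged.
* **Thresholds at midpoints** between adjacent distinct scores (±∞
  sentinels), predictions inclusive (`≤`/`≥`). Midpoints avoid the
  ambiguity of thresholds placed on observed values; software conventions
  differ here, so derived thresholds may differ from other tools by half a
  gap.
* **"Optimal" = maximum Youden J**, ties broken toward higher specificity
  (a false PM call is the costly error — it would trigger an unwarranted
  dose reduction), then toward the candidate calling fewer patients PM.
* **AUC** is trapezoidal and equals the Mann–Whitney statistic exactly
  (property-tested against pair counting); the 95% CI and the test against
  the chance diagonal use DeLong's placement variance (one-sided z for
  AUC > 0.5), clipped to [0, 1].
* **MCC is defined as 0** (and flagged) when a confusion-matrix margin is
  empty.
* **Fisher's exact test** (cohort balance) is the two-sided tail-sum of
  hypergeometric table probabilities ≤ the observed — base R's convention,
  verified against brute-force enumeration; t-tests are Student's
  (equal-variance), as in the reference analysis.
* **Dunnett many-to-one comparisons** (the genotype-subgroup ANOVA
  follow-up) are adjusted by Monte-Carlo evaluation of the null maximum
  |t| with a shared pooled-variance draw (10^5 draws, fixed seed), which is
  simple to verify against permutation and multivariate-t references; the
  suite checks agreement with `multcomp` to 0.02.

## HRMS module

The extraction front end works on centroided full-scan runs: XICs sum
centroid intensities within ±5 ppm of the theoretical [M+H]+ m/z (computed
from the molecular formula via monoisotopic masses when not given); the
window is evaluated as m/z bounds so the ±5.00 ppm boundary is exact.
Integration uses a parameter-light robust rule — baseline = median intensity
outside the ±0.3 min retention window, peak = largest contiguous
above-baseline region inside it, area = trapezoid, detection requires
exceeding baseline + 3·MAD. Identity confirmation requires an MS2 scan whose
precursor matches within 10 ppm and which contains the m/z 98.0967 iminium
fragment within 0.005 Da (absolute, because ppm windows are sub-millidalton
at m/z 98). Solanidine is quantified through a free-intercept OLS line over
the 2–60 nmol/L calibrators. Expected retention times are configuration
inputs, and only solanidine's formula (C27H43NO) is assumed known; metabolite
m/z values must be user-configured. The statistical pipeline never requires
spectra — this module exists to produce the peak-area table where raw mzML
files are available.

## Problem sizes and determinism

All simulation sizes were chosen as the package's own validation design:
parameter-recovery and concentration-mean checks at n = 100,000 (Monte-Carlo
SE on the Def/def M414 contrast ≈ 0.02, comfortably inside the ±0.05
acceptance band), classifier sensitivity/specificity at n = 50,000, property
tests on hundreds of small random instances, Dunnett at 10^5–2×10^5 null
draws. Every stochastic step is seeded; `generate_cohort()`, the split and
the full `run_all()` are bit-reproducible given their configuration.

## Limitations

The generator emulates the *reported* structure of the reference cohort; it
does not model potato-intake behaviour (solanidine exposure enters only
through the ln-concentration model), pharmacokinetic time courses, assay
drift, residual correlation between metabolites, inhibitor effect sizes
(none are published — `inhibitor_effects` must be user-specified), or
per-genotype detection patterns. Passing tests demonstrate internal
consistency and faithful implementation of the published model, not
performance on new patient populations; the single-laboratory,
single-country provenance of the reference parameters limits transferability
of the pinned thresholds wherever potato consumption or assay sensitivity
differ.
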