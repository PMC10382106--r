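---
title: "Normative models of perioperative neonatal brain growth"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Normative models of perioperative neonatal brain growth}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neonorm)
```

## The problem

Infants with critical or serious congenital heart disease (CHD) typically
undergo surgery or catheter intervention in the first weeks of life. Group
comparisons of brain volumes blur the question a clinician actually asks:
*is this infant's brain growing as expected for their age and sex, and did
the perioperative period change that?* The normative-modelling answer is to
estimate, from a healthy reference cohort, the full conditional distribution
of each regional brain volume given postmenstrual age (PMA) at scan,
postnatal days and sex, and to score every individual scan against it.

`neonorm` implements that pipeline end to end:

1. **Normative curves.** For each of 13 regional volumes (total tissue,
   cortical gray matter, white matter, cerebellum, brainstem, extracerebral
   CSF, ventricles, and left/right caudate, lentiform and thalamus) a
   Gaussian-process (GP) regression is fitted to a reference cohort of term
   infants scanned between 37 and 45 weeks PMA.
2. **Deviation Z-scores.** A scan's deviation is
   `z = (observed - mu_pred) / sigma_pred`, using the GP's predictive mean
   and predictive SD *of a new observation*.
3. **Growth trajectories.** With paired pre- and post-operative scans,
   `delta_z = z_post - z_pre` measures the change in an infant's position
   relative to peers: negative values mean growth slowed over the
   perioperative window.
4. **Extreme deviations.** Scores and slope changes are flagged against
   thresholds 1.65, 2.3 and 2.6, whose standard-normal tail levels are
   0.05, 0.01 and 0.005 (`normal_tail()`).
5. **Clinical associations.** A nonparametric battery relates `delta_z`
   per region to the clinical course, with Benjamini–Hochberg adjustment
   within each 13-region family.

Because no individual-level scan data are distributed with the package, a
synthetic cohort generator with known ground truth stands in for both
cohorts, making every stage testable.

## The Gaussian-process normative model

For one region, volumes `y` are modelled as a zero-mean GP over inputs
`x = (pma, pnd, sex01)` after centring `y` on its training mean:

```
k(x, x') = sf^2 * exp(-0.5 * sum_d (x_d - x'_d)^2 / len_d^2)
         + wl^2 * (pma - 40) * (pma' - 40)
         + sn^2 * 1{x == x'}
```

an anisotropic RBF kernel over the three covariates, a linear kernel in
centred PMA, and white observation noise. The rationale: neonatal volume
growth over 37–45 weeks is smooth and close to linear with mild curvature,
so the linear kernel carries the trend, the RBF absorbs curvature and any
smooth covariate interplay, and the white-noise term is the irreducible
between-infant spread. Sex enters as a 0/1 input dimension with its own
length-scale: a large fitted `len_sex` shrinks the sex effect towards zero,
a small one lets the curves separate — a data-driven compromise between
"one curve" and "two independent curves". One model is fitted per region on
both sexes jointly; per-sex centile displays are a plotting convention, not
separate models.

Hyperparameters (`len_pma`, `len_pnd`, `len_sex` in weeks/days/sex-units;
`sf`, `wl`, `sn` in mL) maximise the log marginal likelihood with analytic
gradients via L-BFGS-B on the log scale, with 5 seeded random restarts
around data-driven initial values (`gp_control(restarts = 5)`). Ties are
broken by the higher marginal likelihood, then the lower noise SD. Bounds
keep length-scales in [0.25, 200] weeks (and analogous ranges for the other
inputs) and SD parameters within 1e-4 to 50 times the response SD, which
prevents degenerate zero-noise interpolation. A jitter of 1e-8 stabilises
every Cholesky factorisation.

Two choices matter for interpretation:

* **`sigma_pred` includes the observation noise.** The Z-score is a
  deviation of an *observation*, not of the latent mean; only then are
  held-out healthy infants approximately standard normal, which is what the
  tail-probability reading of the thresholds assumes.
* **Raw mL scale by default** (`gp_control(scale = "log")` switches to
  log-volumes). The reference window is narrow enough that multiplicative
  growth is well approximated additively; the log option exists for users
  who prefer strictly positive predictive envelopes.

Prediction outside the training PMA range extended by `margin` (default 1
week, chosen so that a 37–45-week reference supports post-operative scans
up to the 46-week ceiling) warns by default and errors under
`gp_control(strict = TRUE)`.

## What the simulator emulates — and what it does not

`simulate_normative()` draws one scan per infant: gestational age at birth
from a truncated normal matching a term reference cohort (median 40.1
weeks, IQR 39.1–41), scan PMA uniform on [37, 45] (never before birth), sex
Bernoulli(0.5), postnatal days derived as `round(7 * (pma - ga))` so the
three covariates are mutually consistent, and volumes as quadratic mean
curves plus heteroscedastic Gaussian noise whose SD changes linearly with
PMA (default 3% per week, a mild, realistic age trend that exercises the
predictive-variance pathway). The default curve constants
(`default_curve_params()`) give plausible term-neonate volumes — total
tissue around 360 mL at 40 weeks — and are configuration, not estimates.
Total tissue volume is never drawn: it is always the sum of cortical gray
matter, white matter, cerebellum, brainstem, total deep gray matter and
hippocampus+amygdala. The last two compartments are simulated only so this
summation rule holds; no normative curve is fitted for them. Because the
components share the same fractional SD trend, the implied total-tissue
residual SD (root-sum-of-squares under independence) keeps the same
linear-in-PMA form.

`simulate_chd()` draws paired scans around a surgery day, with clinical
covariates from right-skewed log-normals truncated at plausible bounds and
calibrated to a surgical cohort's medians and IQRs (surgery day 12 (7–14.25),
bypass 153 (128–162) min, PICU 4 (3–5) days, ventilation and inotropes
3 (2–4) days, creatinine 39 (34–46) umol/L, renal replacement 6/36,
necrotising enterocolitis 4/36, CHD categories 20/12/4 over 36). Scan
timing is truncated so that the pre-operative scan precedes surgery, the
post-operative scan follows it, and post-operative PMA stays below 46
weeks. Effects are injected on the *true* Z scale: per region,
`z_pre ~ Normal(baseline, 1)` and
`delta_z = drift + sum(beta * (covariate - reference)) + noise`, after
which observed volumes are reconstructed as `mu(x) + z * sigma(x)` through
the generating curves — so the generative model and the scoring model agree
by construction, and the returned ground truth satisfies
`delta_z = z_post - z_pre` to machine precision. Covariate effects are
centred at reference exposures (`covariate_refs()`): `drift` is the
expected slope change of a typically-exposed infant and `beta` only spreads
infants around it, which keeps region-level medians interpretable and
leaves rank correlations untouched. The default effect list emulates the
qualitative published pattern: tissue regions start about 0.8 SD below the
normative mean and CSF above it, region-specific drifts slow growth most in
brainstem and cerebellum, intensive-care days act on cortical gray matter,
white matter, cerebellum, brainstem and left thalamus (total tissue
inherits a mixture through summation), bypass on brainstem and right
caudate, creatinine on brainstem, caudates and right thalamus, and age at
surgery on brainstem and right lentiform. The `drift` term is a deliberate
extension of the covariate-effect design: the cohort-wide post-operative
slowing reported in practice is not attributable to any measured covariate,
and a constant displacement is the simplest way to carry it. Bypass
minutes are simulated for every infant rather than only the ~86% who
undergo bypass; the complete covariate simplifies pairwise-complete
analyses and removes a missingness mechanism that nothing downstream
exercises.

The simulator does **not** emulate: images or segmentations, brain-injury
lesions (injury enters only as boolean covariates), correlations between
regions beyond the total-tissue summation, covariate-covariate dependence
(each clinical variable is drawn independently), or non-Gaussian residuals.
Passing tests therefore demonstrate that the pipeline recovers what this
generative family encodes — they cannot certify behaviour under real
segmentation artefacts, regionally correlated noise, or confounded clinical
courses.

## Trajectories, thresholds and the census

`delta_z` is the raw difference of the two Z-scores, *not* divided by the
inter-scan interval: the slope change is defined at the two observed
time points, and inter-scan time is tested separately as a covariate.
Thresholds are applied to `delta_z` on the same 1.65/2.3/2.6 scale as
single-scan scores, without rescaling, even though the difference of two
unit-normal scores has variance above 1 under independence — this mirrors
standard practice for this analysis, and the `census()` output records the
denominator so any reader can reinterpret the rates. Comparisons are
strict (`>`): boundary values are unflagged; flags are antisymmetric in the
sign of `delta_z`. Region-level missingness (for instance cortical
volumes excluded after injury corrupts their segmentation) propagates to a
missing `delta_z` without dropping the infant's other regions, and the
census denominator counts infants with at least one non-missing slope.

## The statistical battery

All tests are two-sided and rank-based, with mid-ranks for ties:

* `wilcoxon_paired()` — pre vs post Z per region. "Compare Z-scores
  before and after surgery" is read as the *paired* signed-rank test, since
  the data are paired by infant; zero differences are dropped before
  ranking (Wilcoxon's original rule). Exact p for at most 25 untied
  non-zero differences, otherwise normal approximation with continuity
  correction.
* `kruskal_wallis()` — slope change across CHD categories (tie-corrected H,
  chi-squared p).
* `mann_whitney()` — binary covariates (renal replacement, necrotising
  enterocolitis); exact p when the smaller group has at most 8 untied
  observations; effect reported as the Hodges–Lehmann median of pairwise
  differences.
* `fisher_exact()` — proportions of deviations across categories; the 2x2
  path is exact by the point-probability rule, larger tables are exact up
  to total count 40 and seeded Monte-Carlo beyond (both paths are exposed,
  since either may be appropriate for a 3-category breakdown).
* `spearman()` / `partial_spearman()` — continuous covariates.
  The partial version mid-ranks every variable, residualises the ranks of
  the two variables of interest on the covariate ranks by least squares,
  and correlates the residuals, with a t approximation on `n - 2 - k`
  degrees of freedom. With zero covariates (or a constant covariate, which
  is just the intercept projection) it reduces exactly to the plain
  Spearman rho. Collinear covariate ranks are an error naming the
  covariate.
* `bh_fdr()` — Benjamini–Hochberg step-up adjustment. One family per
  region-by-predictor table (13 regions), matching per-table adjusted-p
  reporting; no cross-predictor correction is applied. Missing region
  results are excluded from the family size and restored as missing.

`run_region_family()` wires one test across the 13 regions and adjusts
within the family; `run_full_analysis()` executes the full plan:
pre-vs-post Wilcoxon; Kruskal–Wallis by CHD category; Spearman against age
at surgery, inter-scan interval, surgery-to-scan interval, ventilation,
inotropes and somatic Z-score changes; partial Spearman for PICU days given
age at surgery, bypass and circulatory arrest given PICU days, and
creatinine given age at measurement; Mann–Whitney for renal replacement and
necrotising enterocolitis; plus exposure-level somatic cross-checks.

## Numerical and reproducibility choices

Every stochastic entry point takes a seed and restores the caller's RNG
state, so identical configurations give byte-identical outputs
(`run_full_analysis()` twice with the same `run_config()` serialises
identically, and the provenance block records the seed and content hashes
needed to re-run a bundle). Degenerate inputs are handled explicitly: an
all-zero paired difference vector returns p = 1 with a warning, a fully
tied Kruskal–Wallis sample returns H = 0, zero rank variance gives a
missing correlation with a warning, and empty contingency categories are
dropped before testing so they cannot change the p-value.

## Known limitations

* **Held-out calibration is bounded by the reference-cohort size.** A
  normative curve estimated from `n` infants absorbs that sample's mean
  offset (SD about `1/sqrt(n)` in Z units — 0.068 at n = 219) and its noise
  estimate inherits the sampling error of a sample SD (about 5% at
  n = 219). Per-region held-out mean Z and SD(Z) therefore scatter by
  roughly those amounts around 0 and 1 even when the model family matches
  the generator exactly; the package's calibration suite measures this
  directly.
* The white-noise kernel is homoscedastic; against the generator's mild
  PMA-dependent residual SD this leaves a few-percent age trend in
  calibration that a heteroscedastic noise model would remove.
* `delta_z` thresholds keep the single-scan scale (above); census rates at
  a given threshold are not directly comparable to single-scan tail
  probabilities.
* The battery is intentionally faithful to a small-cohort design (n = 36);
  at that size only large effects survive FDR within a 13-region family.

## Problem sizes used by the test-suite experiments

The packaged experiments use: a 219-infant reference and 2000 held-out
scans for calibration; 500 replicates of a 36-infant null cohort for the
family-wise FDR check; and 100 replicate surgical cohorts of n = 200 for
covariate-effect recovery, scored against a single fixed normative
reference (the reference is one fixed object in the design, so refitting it
per replicate would only re-estimate the same 13 models). End-to-end
reproducibility checks run a reduced configuration (70 normative infants,
24 surgical, 2 optimisation restarts) — small enough to run twice in a few
seconds, large enough to exercise every family.
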