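---
title: "Methods: lifespan trajectories, harmonization and centiles for cortical thickness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lifespan trajectories, harmonization and centiles for cortical thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models, the tunable parameters and why their defaults are what they are, the
numerical decisions, what the synthetic cohort generator does and does not
emulate, and the known limitations. Everything quantitative asserted here is
computed by the test suite or by `scripts/acceptance.R`; nothing is quoted
from elsewhere.

## Data model and quality control

A cohort table is one row per subject: `subject_id`, `site_id`, `sex`,
`age` (years), and 68 thickness columns (mm) named
`<L|R>_<region>_thickavg` over the 34 bilateral Desikan–Killiany regions.
Analyses use complete cases only; rows with unparseable sex, out-of-bounds
age (default support [3, 90] years) or any missing regional value are
excluded with logged counts. No imputation is attempted — listwise deletion
is the only missing-data rule, matching standard consortium practice for
this data type.

Quality control flags a regional value when it lies more than `k = 5` raw
median absolute deviations from its site's median for that region. Two
decisions needed making where convention is silent:

* **MAD = 0.** When at least half the site's values are identical the MAD is
  zero; dividing is meaningless. We flag any value different from the
  median, which preserves the "k MADs" intent in the degenerate limit.
* **Minimum site size (`min_site_n`, default 8).** A median and MAD over a
  handful of subjects flags mostly noise, and because a subject is dropped
  if *any* of 68 regions is flagged, small-site false positives compound
  rapidly. Sites below the threshold pass through unflagged. Users
  replicating a strict per-site protocol can set `min_site_n = 3`.

One systematic side effect is worth knowing: within wide-age sites the true
age trend places the youngest and oldest subjects in the tails of the site
distribution, so aggressive MAD QC preferentially trims age extremes. At
realistic site sizes the trend itself widens the MAD enough that this is
rare; at strongly scaled-down simulations it is visible.

Age groups are early, middle and late life. The printed labels are integer
year ranges 3–29, 30–59, 60–90; real-valued ages are assigned by the
half-open intervals [3, 30), [30, 60), [60, 90], so middle life starts at
exactly 30.0 years, every age in the support maps to exactly one group, and
the integer boundary years land in the groups their labels suggest.

## Fractional-polynomial trajectories

For each region the mean thickness is modelled as an FP in age with powers
from {−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 denoting ln) and degree up to 4. A
repeated power multiplies the previous term by another ln(age), so powers
(0, 1, 1) give columns ln a, a, a·ln a. The candidate family — all power
multisets of size 1–4 — holds 494 models. Sex enters as a single female
indicator; no sex-by-age interaction is fitted in the main model
(sex-stratified analyses simply re-run the pipeline per stratum).

*Centering.* The response and every design column are mean-centered per
region, so the fitted intercept is identically zero and reported curves
re-add the response mean. This reproduces the zero-intercept convention
without altering slopes. Ages are used untransformed (all ≥ 3, so powers and
logs are defined); re-scaling age is unnecessary at double precision for the
sizes involved.

*Exhaustive scan.* Ranking 494 models per region uses precomputed centered
cross-products over the 32 distinct basis terms plus sex, solving each
model's small normal system (with column scaling and a condition-number
guard that discards numerically singular candidates). Per-degree winners are
then refit by QR for exact residuals. Normal equations are used only for
ranking, where RSS differences sit far above their ~1e−10 relative error;
reported fits never come from the fast path.

*Selection.* "Choose the lowest adequate degree" is operationalized as an
ascending closed test: degree d+1 replaces degree d only when the partial
F-test of the per-degree best fits has p < α, with α = 0.01 by default (the
permutation-calibrated threshold; `permutation_alpha()` reruns the
comparisons on ages permuted within site and reports how often a degree > 1
model would be accepted under that null). Every degree-d model is nested in
some degree-(d+1) model — a multiset's basis columns are a subset of any
extension's — so the per-degree minimum RSS is non-increasing and the F
statistic non-negative, even though the two *winners* need not be nested
pair-wise. A descending variant (start at degree 4, step down while the
higher degree is not a significant improvement) is available behind a flag.
Exact RSS ties are broken by canonical (sorted) power order, and the grid
argmax behind `age_at_max()` breaks ties toward the youngest age, so a flat
curve reports the start of the support. Trajectory summaries
(`age_at_max`, shape labels) are evaluated over the configured study range
[3, 90] rather than the possibly QC-narrowed observed range.

*Uncertainty.* Coefficient covariance is computed both conventionally and
clustered by site with the CR1 small-sample factor (via `sandwich`), since
residual scanner dependence survives harmonization. The partial F-test uses
the plain RSS-based statistic; the robust covariance informs coefficient
inference, not the closed test.

## Site harmonization

Harmonization follows the empirical-Bayes location/scale (ComBat) model:
per region v and site i, standardized residuals
z = (y − α − Xβ)/σ receive site location γ*_iv and scale δ*_iv estimates
shrunk toward cross-region priors (normal for location; inverse-gamma for
scale, hyperparameters by method of moments), solved by the usual iterative
conditional-means scheme to a 1e−6 tolerance (maximum 500 iterations). The
adjusted value is y* = σ(z − γ*)/δ* + α + Xβ.

Decisions:

* **Covariate design.** The model must be told which structure is biology.
  Default: the female indicator plus an FP(0, 1, 1) age basis
  (ln a, a, a·ln a) — flexible enough that nonlinear age signal is preserved
  rather than absorbed into site effects. The design is configurable, and a
  covariate-free fit is available.
* **Variance denominators.** Pooled and per-site variances divide by n, not
  n − 1, so a single-site fit yields γ* = 0, δ* = 1 exactly and
  `apply_combat()` is then the identity. Reference implementations using
  n − 1 agree with ours to O(1/n) (the test suite bounds the discrepancy
  explicitly).
* **Idempotence.** Refitting on already-harmonized data returns site effects
  at numerical zero when no covariates are modelled. With covariates, the
  per-site residual rescaling reintroduces tiny covariate projections
  (≪ data scale but not 1e−6); with EB, shrinkage leaves similarly tiny
  residual site means. This is a property of the model class, not a defect.
* The parametric-prior variant only; regions are harmonized independently.

`fit_combat()` and `apply_combat()` are deliberately split so a model
estimated on one sample can harmonize later rows from known sites.

## Correlations and interindividual variability

Within each age group, Pearson correlations between age and thickness are
computed for all subjects and per sex (cells under 4 subjects are omitted
with a warning). Male and female correlations are compared with the
independent-groups Fisher z test — the applicable comparison for disjoint
samples: z = (atanh r₁ − atanh r₂)/√(1/(n₁−3) + 1/(n₂−3)). Regional
significance thresholds (defaults 0.0007 and 0.0002) are configuration
constants, not derived quantities.

Variability analysis converts each residual of the selected FP model into a
per-subject dispersion score ln(e² + ε), ε = 1e−12, and runs a one-way ANOVA
on the scores across age groups; per-group mean squared residuals (Σe²/n_t)
are reported untransformed alongside. The log transform counteracts the
strong right skew of squared residuals; the ANOVA's calibration is
asymptotic in the group sizes, and the type-I property test therefore uses
groups in the hundreds (at ~200 per group the test is measurably
anti-conservative at extreme thresholds). The Bonferroni default 0.0007
(68 regions × 3 groups) is configurable.

Per-site SDs are pooled per region and age group by DerSimonian–Laird
random-effects meta-analysis of the bias-corrected log-SD, effect
ln s + 1/(2(n−1)) with sampling variance 1/(2(n−1)); the headline "pooled
SD" is exp of the pooled effect. DL was chosen as the standard closed-form
estimator for this effect type; the implementation is ten lines and is
cross-checked against an independent reference implementation in the tests.
The SD-versus-surface-area association uses Spearman rank correlation;
constant input (undefined ranks) returns ρ = 0 with a warning rather than
an error, so pipelines over degenerate synthetic regions keep running.

## LMS centiles

Centile curves come from the Box–Cox Cole–Green model: at age t the
response satisfies z = ((y/μ)^λ − 1)/(λσ) (λ ≠ 0; the log form at λ = 0)
with z standard normal. The three curves are penalized cubic P-splines —
20 interior equally spaced knots, second-order difference penalty — with
the penalty of each curve tuned (by root-finding on the eigenvalues of the
whitened penalty) to hit a target effective df. Backfitting uses Fisher
scoring with the expected information: weight (1 + 2λ²σ²)/σ² for the
log-link μ curve, 2 for the log-link σ curve, and 7σ²/4 for λ, whose score
is evaluated by a central difference of the per-observation log-likelihood
(robust at λ near 0). μ and σ are positive by construction through their
log links; fitted σ is additionally clamped to [1e−4, 2] and λ to [−4, 4]
to keep early iterations inside the plausible region.

Defaults and their reasons:

* **df (λ, μ, σ) = (1, 4, 2).** A constant λ, a gently flexible median and
  a near-constant coefficient of variation; thickness skew is mild and a
  free λ curve is the dominant instability source.
* **`edf = "auto"`** runs a coordinate GAIC search: μ over 2–8, then σ over
  2–8, then λ over 1–3, minimizing GAIC = −2ℓ + k·(total edf) with k = 2.
  A full 3-way grid would multiply runtime sevenfold for little benefit at
  these smoothness levels.
* **Convergence.** Outer iterations stop when the log-likelihood changes by
  less than 1e−3 + 1e−6·n (scale-aware; well below one GAIC unit); failure
  to converge within 200 iterations is an error carrying diagnostics, never
  a silent result.
* **Support.** Curves are evaluable only inside the fitted age range;
  out-of-support queries are refused rather than extrapolated, and centile
  tables restrict the requested grid to each stratum's observed range.
* Centile levels are the 13 conventional values 0.4–99.6%. Monotonicity in
  the level is guaranteed analytically whenever the power argument
  1 + λσz is positive (violations raise an error naming the ages) and is
  re-asserted on every produced table.

A known limitation, verified empirically during development: the *joint*
(λ, μ, σ) df triple selected by GAIC is not stable across replicate cohorts
— adjacent-df GAIC differences for the weakly identified λ and σ curves are
O(1) and flip with sampling noise, at k = 2 and stiffer penalties alike.
The μ-curve df, which carries the scientific content, is stable when the
data identify it decisively, and that is the stability the test suite
asserts. Fitted centiles are insensitive to these adjacent-df flips.

## The synthetic cohort generator

The generator exists so that every downstream stage has a ground truth. Its
preset mirrors the pooled study's structure: 83 sites with the published
per-site sizes (scalable), age ranges and sex splits (~52% female overall);
region-specific FP mean curves anchored at plausible adult thickness values;
additive site shifts γ ~ N(0, 0.1 mm) and residual scale factors
δ = exp(N(0, 0.1)); Gaussian residuals with SD 0.15 mm (the middle of the
plausible 0.1–0.2 mm band), consistent with the near-normal FP residuals
this kind of data shows. Shapes: monotone decline (steeper before the third
decade; a region-specific factor varies the rate) for 60 regions, an
inverse-U peaking at 65 years for entorhinal and temporopolar cortex, and a
shallow U with minimum at 55 years for the anterior cingulate. A +0.01 mm
male offset is the default sex effect. Ages are uniform within each site's
range — the site table provides only ranges, and uniformity is the neutral
choice; a consequence is that the pooled age histogram is flatter than a
real consortium's.

Reproducibility: each site draws from its own RNG stream derived from the
master seed and the site id, so generation is bit-identical regardless of
site order or subsetting of the site list.

What the generator does *not* emulate — and hence what passing tests cannot
show: measurement artifacts and segmentation failures (QC true positives),
non-Gaussian or heteroscedastic residuals within site, site-by-age
interactions, correlated residuals across regions, and any real regional
effect sizes. Tests on this generator validate the estimators' mechanics
and calibration, not the biology.

## Simulation sizes in the test suite

The suite exercises the study conditions at sizes chosen to keep a complete
run in minutes on one core while leaving Monte-Carlo margins wide:
selection calibration uses 100 replicate cohorts of n = 5,000 per truth
shape; harmonization recovery uses three sites of 700; centile coverage
uses n = 10,000 with a held-out half; meta-analytic recovery uses 20 sites
of 200; the end-to-end shape-recovery checks run the preset at 10% scale
(with the full-scale run, ~17,000 subjects, exercised once in the
property suite). `scripts/acceptance.R` recomputes the same quantities from
scratch under a caller-supplied seed.
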