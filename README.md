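# cortlife

Modelling age-related change in regional cortical thickness across
multi-site lifespan cohorts.

Cortical thickness, estimated per Desikan–Killiany region from T1-weighted
MRI, declines with age in a regionally heterogeneous way, and pooled
multi-site samples are the only practical way to cover ages 3–90 with
adequate power. Pooling brings two statistical problems this package
addresses end to end: scanner/site effects that must be removed without
erasing the biology, and the need for flexible, honest trajectory models and
normative reference ranges. `cortlife` is aimed at neuroimaging
statisticians and consortium analysts working with subject-level tables of
regional thickness (one row per subject; 68 bilateral regions), and at
methodologists who want a fully synthetic, ground-truth-known testbed for
this class of pipelines.

## What the package computes

* **Fractional-polynomial (FP) age trajectories.** Thickness is regressed on
  transformed ages with powers drawn from
  {−2, −1, −0.5, 0, 0.5, 1, 2, 3} (0 = ln), degree up to 4; a repeated power
  p contributes an extra `age^p · ln(age)` term, e.g. powers (0, 1, 1) give

  `E[y] = β0 + β1 ln a + β2 a + β3 a ln a`

  All 494 candidate models are fitted per region; per-degree best fits are
  compared by partial F-tests in an ascending closed test at α = 0.01, with
  standard errors clustered by site (CR1). Summaries include R², the age at
  maximum fitted thickness, and a shape label (decline / inverse-U /
  attenuated-U).
* **Empirical-Bayes site harmonization (ComBat).** Per region, a
  location/scale model with parametric EB shrinkage removes site shifts
  `γ` and scale factors `δ` while preserving a configurable age + sex
  design; the fitted model can be applied to new rows from known sites.
* **Age-group statistics.** Pearson correlations between age and thickness
  within early (3–29), middle (30–59) and late (60–90) life, with
  male–female comparison via the independent-groups Fisher z test.
* **Interindividual variability.** One-way ANOVA on log squared residuals of
  the selected FP model across age groups; per-site SDs pooled by
  DerSimonian–Laird random-effects meta-analysis of the bias-corrected
  log-SD (effect `ln s + 1/(2(n−1))`, variance `1/(2(n−1))`); Spearman
  association between regional SD and surface area.
* **LMS normative centiles.** Box–Cox Cole–Green (λ, μ, σ) curves estimated
  by penalized maximum likelihood with cubic P-splines, effective df chosen
  by GAIC; 13 centiles (0.4–99.6) per region, sex and hemisphere, plus
  z-scores for individual observations.
* **Synthetic cohort generator.** An 83-site, 68-region preset mirrors the
  published cohort structure (site sizes, age ranges, sex splits; ~52%
  female overall) with known trajectory shapes — monotone decline for most
  regions, inverse-U for entorhinal/temporopolar, attenuated-U for anterior
  cingulate — so every stage is testable without restricted data.

## Worked example

```r
library(cortlife)

gen <- generate_cohort(enigma_like_config(scale = 0.1, seed = 1))
cohort <- qc_cohort(gen$cohort)                       # 5-MAD per site/region
cohort <- cohort[!(cohort$site_id %in%
                   names(which(table(cohort$site_id) < 2))), ]
harmonized <- apply_combat(fit_combat(cohort), cohort)

cohort
#> <cohort_table> 1378 subjects, 68 regions, 79 site(s); ages 3.6-90, 54% female

select_fp_model(harmonized, "L_superiorfrontal_thickavg")
#> <fp_selection> region L_superiorfrontal_thickavg: powers (0.5) (degree 1),
#>   R^2 = 0.5785, age at max = 3 y

select_fp_model(harmonized, "L_entorhinal_thickavg")
#> <fp_selection> region L_entorhinal_thickavg: powers (2,2) (degree 2),
#>   R^2 = 0.0725, age at max = 64.7 y
```

The superior frontal gyrus behaves like most of the cortex: age explains a
large share of the variance (R² = 0.58), the fitted curve declines
monotonically, and the maximum sits at the youngest age studied (3 y). The
entorhinal cortex is the characteristic exception: age explains little
variance (R² = 0.07) and the fitted inverse-U peaks in late life (64.7 y) —
both patterns propagate from the generator's ground truth. Normative
centiles for one region and stratum:

```r
cent <- build_centile_tables(harmonized,
                             regions = "L_superiorfrontal_thickavg",
                             grid = c(10, 30, 60, 80))
cent[cent$sex == "female", c("age", "c2.5", "c50", "c97.5")]
#>   age  c2.5   c50 c97.5
#>    10 2.586 2.894 3.201
#>    30 2.375 2.676 2.977
#>    60 2.150 2.450 2.749
#>    80 2.015 2.315 2.614
```

The full pipeline (QC → harmonize → FP selection → correlations →
variability + meta-analysis → centiles) runs from one config:

```r
manifest <- run_pipeline(pipeline_config(out_dir = "out", scale = 0.05,
                                         seed = 1))
```

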