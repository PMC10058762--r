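# dnastraj

Dietary non-adherence score trajectories and all-cause mortality.

## The problem

Traditional diet-quality indices score each food group against its
recommended intake and add the points up, so two very different diets can
receive the same total. An alternative is to treat a diet as a point in
food-group space and measure how far it sits from the guideline-recommended
pattern: with intakes \(x_i\) and guideline reference intakes \(y_i\) over
\(n\) food groups (ten, in the default configuration),

```
DNAS = sqrt( sum_i (x_i - y_i)^2 )
```

— the Euclidean distance between the observed and recommended intake
vectors, computed after each group is divided by its reference intake so
that the reference pattern maps to the all-ones point and no single group's
units dominate. A score of 0 means perfect adherence; larger scores mean
larger deviation from the recommended *proportions*, not just amounts.

`dnastraj` implements the full analysis pipeline around this score for
longitudinal cohorts:

* **Scoring** — guideline tables as data (`guideline_spec()`,
  `load_guideline()`), ratio/grams/z-score normalization, Euclidean or
  Manhattan distance, panel scoring (`score_panel()`).
* **Trajectory modelling** — latent-class linear mixed models of score on
  age (class-specific intercept and slope, subject-level random intercept),
  fitted by a monotone EM with a quasi-Newton polish (`fit_lctm()`),
  class-count selection by BIC (`select_n_classes()`), posterior
  classification (`classify()`).
* **Mortality** — person-year rates with Poisson intervals
  (`person_year_rates()`), sequentially adjusted Cox proportional-hazards
  ladders (`sequential_models()`), and restricted-cubic-spline Cox
  dose-response curves with data-driven knot selection (`fit_rcs_cox()`).
* **Simulation** — a synthetic longitudinal cohort generator with known
  ground truth (`generate_cohort()`), eligibility filtering
  (`apply_exclusions()`), and an end-to-end reproducible pipeline
  (`run_pipeline()`).

It is written for epidemiologists and biostatisticians who want either the
score itself or a tested reference implementation of the trajectory +
survival analysis around it.

## Worked example

```r
library(dnastraj)

guideline <- default_guideline()              # 10 food groups, g/day
cohort <- generate_cohort(cohort_config(n_subjects = 1000, seed = 2))

dnas <- score_panel(cohort$panel, guideline)
head(dnas, 3)
#>   subject_id round age_years    score
#> 1     S00001  2004  39.48375 4.165452
#> 2     S00001  2006  41.48375 4.140127
#> 3     S00001  2009  44.48375 3.358333

fit <- fit_lctm(dnas, G = 3, n_starts = 5, seed = 1)
fit
#> Latent-class trajectory model: 3 class(es), 1000 subjects
#>  class intercept    slope slope_se  p_slope      pi
#>      1     3.076 -0.01491 0.008135 0.066924 0.08927
#>      2     4.753 -0.00388 0.002809 0.167187 0.69536
#>      3     5.980  0.01331 0.004877 0.006358 0.21538
#> tau2 = 0.3326  sigma2 = 0.3942  logLik = -4959.27  BIC = 9987.63
```

Class 1 collects subjects with low scores (good adherence) that improve
slightly with age (negative slope); class 3 collects high and worsening
scores — intercepts, slopes and shares all sit near the generator's
configured truth. Feeding the classes into the survival stage:

```r
surv <- merge(cohort$survival,
              classify(fit)[, c("subject_id", "modal_class")],
              by = "subject_id")
names(surv)[names(surv) == "modal_class"] <- "class"
person_year_rates(surv)
#>   group n_events person_years      rate       lo       hi       flag
#> 1     1        3     601.2367  4.989715  1.60929 15.47096 few events
#> 2     2      144    5116.0625 28.146646 23.90524 33.14058
#> 3     3       39    1053.2955 37.026648 27.05285 50.67756

sequential_models(surv)$table[c(1, 2, 7, 8), ]
#>     model class       HR       lo       hi            p
#> 1 Model 1     2 5.669892 1.807139 17.78927 0.0029367349
#> 2 Model 1     3 7.462723 2.305875 24.15233 0.0007959558
#> 7 Model 4     2 5.565577 1.764034 17.55955 0.0034094808
#> 8 Model 4     3 7.402334 2.271225 24.12555 0.0008975956
```

The mortality gradient across classes (5, 28, 37 deaths per 1000
person-years) mirrors the generator's configured rates, and the hazard
ratios barely move down the adjustment ladder because the default
generator links no covariate to the hazard — simulate with
`covariate_log_hr` to study confounding and attenuation.
`fit_rcs_cox(surv)` adds the continuous dose-response curve of
baseline score against mortality, anchored at HR = 1 at its reference
score, and `run_pipeline()` wires all stages together with CSV/JSON
outputs and a manifest.

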