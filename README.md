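# comorbscreen

Stratified comorbidity screening and time-order analysis for longitudinal
hospital diagnosis registries.

## What problem this solves

Inpatient registries record, per hospital stay, the diagnoses coded as
level-3 ICD-10 codes (e.g. E66 obesity, F32 depressive episode). Given an
index diagnosis, two questions arise for epidemiologists working with such
claims data:

1. **Which diagnoses are associated with the index diagnosis**, once age and
   calendar period are adjusted for? `comorbscreen` anchors every patient to
   one (age decade × 2-year calendar window) stratum, builds per-stratum
   2×2 tables, and pools them with the Mantel–Haenszel estimator

   *OR*<sub>MH</sub> = Σᵢ aᵢdᵢ/nᵢ ÷ Σᵢ bᵢcᵢ/nᵢ,

   with a Robins–Breslow–Greenland confidence interval and the
   Cochran–Mantel–Haenszel chi-square test (1 df, no continuity
   correction). Pairs with fewer than 100 co-occurring patients are
   filtered as quality control; the survivors form a single Bonferroni
   family, and a pair is called significant when OR > 1.5 and
   p<sub>corr</sub> < 0.01.

2. **Which diagnosis tends to come first?** Among dual-diagnosed patients,
   the time-order ratio TOR(A→B) = N(A first) / N(B first) is computed per
   delay class (same stay, ≤360 days, 361–1080, >1080), with an exact
   two-sided binomial sign test (doubled smaller tail) against the null
   that neither direction dominates. Same-stay ties are reported but enter
   neither the ratio nor the test.

The package also ships a **synthetic registry generator** with two injected
ground truths — an odds multiplier θ applied per stratum on the odds scale,
and a direction bias ρ with P(exposure first) = ρ/(1+ρ) — plus a
`confounded_scenario()` in which prevalences rise with age so the crude OR
is biased while the stratified estimate is not. Every estimator is
validated against these known truths in the test suite. Cohort utilities
(chapter filtering to A–N, all-or-nothing washout exclusion, per-patient
first occurrences), sex-stratified screens, sex-specific ORs among the
exposed, and a somatic-exclusion sensitivity analysis complete the
pipeline.

## Worked example

Simulate a registry with a known θ = 2.5 and ρ = 2 under age confounding,
prepare the cohort, and screen:

```r
library(comorbscreen)
library(dplyr)

cfg <- confounded_scenario(
  generator_config(n_patients = 50000, theta = 2.5, rho = 2, seed = 42)
)
reg <- generate_registry(cfg)

ev  <- reg |> filter_chapters() |> apply_washout()
f   <- first_occurrences(ev)
s   <- assign_strata(f, patient_profiles(ev), "E66")

scr <- screen_comorbidities(f, s, comorbidity_codes = "F32")
tidy(scr) |> select(code_b, age_decade, or_mh, ci_low, ci_high,
                    p_corr, n_cooccur, significant)
#> # A tibble: 8 × 8
#>   code_b age_decade or_mh ci_low ci_high   p_corr n_cooccur significant
#>   <chr>  <chr>      <dbl>  <dbl>   <dbl>    <dbl>     <int> <lgl>
#> 1 F32    10-19       1.80  0.775    4.16 5.01e- 1         6 FALSE
#> 2 F32    20-29       1.97  1.21     3.22 1.64e- 2        19 FALSE
#> 3 F32    30-39       2.49  1.81     3.42 1.89e- 8        51 FALSE
#> 4 F32    40-49       2.26  1.75     2.92 4.26e-10        84 FALSE
#> 5 F32    50-59       2.13  1.71     2.67 3.31e-11       117 TRUE
#> 6 F32    60-69       2.23  1.83     2.71 1.61e-15       160 TRUE
#> 7 F32    70-79       2.43  2.04     2.90 7.55e-24       230 TRUE
#> 8 F32    all         2.28  2.07     2.51 3.42e-66       667 TRUE
```

The pooled estimate (2.28, CI 2.07–2.51) brackets the injected θ = 2.5 at
its confidence level; decades with fewer than 100 co-occurring patients are
filtered (`significant = FALSE` regardless of p) — exactly the behaviour a
registry-scale screen needs to avoid sparse-cell artefacts. Directionality:

```r
op <- ordered_pairs(f, "E66", "F32", profiles = patient_profiles(ev))
compute_tor(op)
#> # A tibble: 4 × 9
#>   code_a code_b gap_class n_a_first n_b_first n_tie   tor   p_binomial
#> 1 E66    F32    same_stay         0         0   162 NA    NA
#> 2 E66    F32    lt_1y           133        60     0  2.22  0.000000157
#> 3 E66    F32    1y_to_3y        115        71     0  1.62  0.00155
#> 4 E66    F32    gt_3y            85        41     0  2.07  0.000110
```

Across delay classes the exposure is coded first about twice as often as
the comorbidity — the injected ρ = 2 — and the exact sign test rejects the
symmetric null in every delayed class. `autoplot(scr)` and `autoplot(...)`
on a TOR table draw the forest plot and the starred TOR chart;
`run_full_analysis()` + `write_report_bundle()` produce the full CSV bundle
(associations, TOR, sex strata, sensitivity, characteristics table) with a
JSON metadata sidecar recording seeds, thresholds, the Bonferroni family
size and the record counts at every filter step.

A thin command-line wrapper with `simulate`, `cohort`, `screen`, `tor`,
`sexstrat`, `sensitivity`, `report` and `all` subcommands lives at
`inst/cli/comorbscreen-cli.R`; demo YAML configs are under `inst/extdata/`.

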