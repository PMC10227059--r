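---
title: "Stratified comorbidity screening and time-order analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stratified comorbidity screening and time-order analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(comorbscreen)
library(dplyr)
```

## The problem

National hospital-stay registries record, for every inpatient admission, the
set of diagnoses coded at that stay as level-3 ICD-10 codes (a chapter letter
plus two digits, e.g. E66 for obesity, F32 for a depressive episode). Such
data support two questions about an index diagnosis:

1. **Association screening** — which diagnoses co-occur with the index
   diagnosis more often than expected, after adjusting for age and calendar
   period?
2. **Directionality** — among patients who eventually carry both diagnoses,
   which one tends to be recorded first, and at what delay?

`comorbscreen` implements both analyses as a tested, reproducible pipeline,
together with a synthetic registry generator whose effect sizes are known by
construction, so every estimator in the package can be validated by
parameter-recovery and calibration studies.

## Cohort construction

Raw registries cover chapters A–Z; chapters O–Z (pregnancy, perinatal,
malformations, unspecific findings, external causes, health-service
contacts) are removed (`filter_chapters()`). A **washout** rule
(`apply_washout()`) then removes — entirely, all-or-nothing — every patient
with an inpatient stay during an initial era (by default 1997–2002), so the
retained cohort enters the observation period 2003–2014 with five-plus years
free of hospital contact and a comparable baseline health status.

Each patient is reduced to per-code **first occurrences**
(`first_occurrences()`): the earliest admission date carrying the code, ties
across same-date stays broken by the smallest stay id (a deterministic,
auditable rule).

Patients are then **anchored once** (`assign_strata()`): exposed patients at
the first occurrence of the index code, unexposed patients at their first
admission. The anchor fixes the patient's age decade (seven decades, 10–19
through 79) and 2-year calendar window (2003–04 … 2013–14). Registries
record birth year only, so age is computed in completed years under a fixed
mid-year (July 1) birthday convention, applied identically everywhere.

*Design choice — single-stratum anchoring.* A patient observed over a decade
of calendar time ages across decade boundaries, and nothing in the data
dictates a unique placement. We deliberately anchor each patient to exactly
one (decade, window) cell, because the Cochran–Mantel–Haenszel machinery
requires disjoint strata: a patient contributing to two cells would be
double-counted and the pooled variance would be wrong. The policy string is
emitted in run metadata (`metadata.json`) so alternative policies are
auditable; comorbidity presence is any first occurrence during 2003–2014,
not restricted to the anchor window, since the window stratification serves
confounding adjustment, not exposure timing.

## The association model

For a pair (exposure $A$, comorbidity $B$) and stratum $i$ (an age decade ×
window cell), the 2×2 table counts $a_i$ (both), $b_i$ ($A$ only), $c_i$
($B$ only), $d_i$ (neither), with $n_i$ their sum. The pooled
Mantel–Haenszel odds ratio is

$$\widehat{OR}_{MH} \;=\; \frac{\sum_i a_i d_i / n_i}{\sum_i b_i c_i / n_i},$$

whose log receives the Robins–Breslow–Greenland (RBG) variance estimator —
chosen because it is consistent in both asymptotic regimes (few large
strata, many sparse strata), which matters here: young decades can
contribute very sparse cells. The test is the CMH chi-square (1 df, no
continuity correction)

$$X^2 = \frac{\big(\sum_i a_i - \sum_i E_i\big)^2}{\sum_i V_i},\qquad
E_i = \frac{(a_i+b_i)(a_i+c_i)}{n_i},\quad
V_i = \frac{(a_i{+}b_i)(c_i{+}d_i)(a_i{+}c_i)(b_i{+}d_i)}{n_i^2(n_i-1)}.$$

Degenerate strata ($n_i \le 1$ or a zero margin) contribute nothing and are
flagged; a zero MH denominator yields an explicit *undefined* sentinel
rather than an estimate. We intentionally do **not** add 0.5 continuity
padding: padding silently changes estimates, whereas a sentinel forces the
caller to handle the degenerate case.

### Screening rules

Three thresholds, all configurable:

| parameter | default | meaning |
|---|---|---|
| `min_occurrence` | 100 patients | pairs with fewer co-occurrences are filtered as quality control |
| `or_threshold` | 1.5 | minimum pooled OR for a significant call |
| `alpha` | 0.01 | corrected significance level |

The Bonferroni family is the set of all (pair × decade) tests surviving the
occurrence filter, pooled across age groups — a single family, the most
conservative defensible reading; $m$ is recorded in run metadata. The
pooled-across-decades ("all") row is a summary over the same strata and
receives the same $m$. A pair is significant only under the full
conjunction: filter passed **and** $OR_{MH} >$ threshold **and**
$p_{corr} < \alpha$.

Risk ratios are not computed; the pooled odds ratio is the reported effect
measure.

## Time-order analysis

For dual-diagnosed patients the signed gap between first-occurrence dates
defines a direction; patients whose two codes share one stay (or one date)
are *ties*. Patients split into four delay classes: same stay, at most
roughly one year (360 days), one to three years (≤ 1080 days = 3 × 360),
and beyond. We use a 360-day year consistently and assign boundary days to
the lower class; both choices are configurable (`edges`), including
five-year windowings for sensitivity checks, which relabel classes
generically.

The **time-order ratio** for a class is
$TOR(A \to B) = N(A\ \text{first}) / N(B\ \text{first})$: values above 1
mean the exposure tends to be coded first. Ties are counted and their share
reported, but they enter neither the ratio (a ratio of directed counts
cannot absorb ties) nor the test. Under the null that both directions are
equally likely, the directed counts are Binomial($n$, ½); the exact
two-sided p-value doubles the smaller tail,
$p = \min\{1,\, 2\min(P(X \le k), P(X \ge k))\}$. This doubled-tail
convention is stated explicitly rather than delegated to
`stats::binom.test()`, whose two-sided rule (minimum-likelihood) differs for
asymmetric cases. Plots annotate classes with conventional stars at
0.05/0.01/0.001 on the **uncorrected** p-values; multiplicity correction of
TOR tests is left to the user, since the Bonferroni family of the screen
does not extend naturally to them.

## Sex stratification and sensitivity analysis

`sex_stratified_run()` repeats the entire screen within one sex.
`sex_specific_or()` asks a different question — among *exposed* patients,
is the comorbidity more frequent in women than in men? — via a sex ×
comorbidity 2×2 per window, pooled with the same MH estimator (one
estimator everywhere, female in the numerator). `sensitivity_exclude()`
removes, patient-level and idempotently, everyone ever carrying configured
somatic codes (default diabetes E11, hypertension I10, coronary artery
disease I25) and reruns the screen, probing whether psychiatric links
persist without those risk carriers. Exclusion is bounded to the
observation window because the washout leaves no earlier data to consult.

## The synthetic registry generator

`generate_registry()` emulates the structure of a national inpatient
registry with two injected ground truths:

* **θ (theta)** — an odds multiplier applied, per (age decade, sex) stratum,
  to each comorbidity's odds given exposure. Applying θ on the odds scale,
  with prevalences constant across calendar windows, makes the MH
  common-odds-ratio assumption hold *exactly* by construction, so parameter
  recovery is a sharp test of the estimator rather than of a model
  approximation.
* **ρ (rho)** — the target ratio of exposure-first to comorbidity-first
  orderings among dual-diagnosed patients with distinct dates;
  $P(\text{exposure first}) = \rho/(1+\rho)$.

Default conditions (fixed once, documented here): exposure prevalence 5%
and comorbidity prevalence 4% (flat across strata), a 25% washout share,
2.8 stays per patient on average with stay lengths of 1 + Poisson(4.5)
days, a 25% chance that a dual diagnosis is coded at a single stay, and —
absent any distributional facts about delays beyond the four classes —
equal weights on the three delayed classes with gaps drawn uniformly within
1–360, 361–1080 and 1081–3240 days. These are free modelling choices, not
estimates. `confounded_scenario()` replaces the flat prevalences with
age-increasing gradients (exposure 3→15%, comorbidity 2→14% across the
seven decades) so that age confounds the crude OR upward while θ is
unchanged — the canonical stratification test-bed.

Two structural decisions matter for unbiasedness and are worth spelling
out. First, the exposure's first-occurrence date (the anchor) is drawn
*independently* of dual status and direction; the comorbidity is placed at
anchor ± gap (clipped to the observation period). Window membership
therefore carries no information about comorbidity status, which keeps the
within-window odds ratio at θ. Second, every patient receives an entry stay
at the anchor date itself, so the unexposed anchor (first admission)
coincides with the drawn anchor — without it, patients with no tracked
diagnosis would drift to later windows and bias within-window tables.

Randomness uses one substream per generation phase (and per draw kind
within each code), each a single vectorized call ordered by patient:
enlarging `n_patients` appends draws without perturbing earlier patients,
and identical (config, seed) pairs are byte-identical.

What the generator does **not** emulate: real coding practice (repeat
codings carry no information here), mortality and censoring, outpatient
care, seasonal admission patterns, and realistic national prevalence
calibration. Passing recovery tests therefore demonstrates that the
estimators are correct and calibrated under the stated model — not that any
particular real-world estimate is right.

## Validation studies shipped in the test suite

The package's claims are backed by simulations run at fixed problem sizes,
chosen to make Monte-Carlo error small relative to the tolerance being
asserted:

* **Oracle equivalence** — on 100 random small series, the MH estimate,
  RBG interval and CMH statistic match independent transcriptions of the
  published formulas to 10 significant digits, and
  `stats::mantelhaen.test(correct = FALSE)` to 10 decimals.
* **Parameter recovery** — θ = 2.5 under the confounded scenario: one run
  at n = 100,000 (CI contains θ) and CI coverage over 300 replicates at
  n = 5,000, required to fall in [93%, 97%].
* **Type-I error** — θ = 1 confounded: 2,000 replicates at n = 3,000;
  the CMH rejection rate at α = 0.01 must stay within exact binomial 99%
  bounds of 0.01 while the crude OR is demonstrably biased above 1.1 at
  n = 100,000.
* **Directionality** — ρ = 2 with over 1,000 ordered pairs recovers
  TOR ∈ [1.8, 2.2] at p < 0.001; under ρ = 1, 2,000 small replicates keep
  the exact test's size at or below the nominal 0.05 (the attainable size
  of an exact test is ≤ nominal).

## Numerical and degenerate-input conventions

* Zero MH denominators and all-degenerate CMH series return flagged
  sentinels (`"undefined"` / `"degenerate"`), never errors or padded
  estimates; `p_raw = 1` when no stratum is usable.
* `TOR` with zero B-first counts is the `NA` sentinel, counts still
  reported; `TOR(A→B)·TOR(B→A) = 1` wherever both are defined.
* Bonferroni: `p_corr = min(1, m·p_raw)` — monotone, never below `p_raw`,
  capped at 1; `m ≤ 0` is rejected.
* First-occurrence ties: smallest stay id; gap-class boundaries: lower
  class; hospital days: inclusive (release − admission + 1).

## Known limitations

* The single-anchor stratification is a modelling decision, not a fact of
  the data; patients near decade boundaries are placed by their anchor age
  only.
* The registry records hospital (inpatient) diagnoses only; nothing here
  corrects for under-coding, and co-diagnosis percentages are percentages
  of hospital patients, not population prevalences.
* TOR is descriptive: it is not a hazard model and makes no claim about
  causation; left-truncation at the observation start compresses long gaps
  for late-anchored patients.

## A minimal session

```{r example, eval = FALSE}
cfg <- confounded_scenario(
  generator_config(n_patients = 50000, theta = 2.5, rho = 2, seed = 42)
)
reg <- generate_registry(cfg)

ev  <- reg |> filter_chapters() |> apply_washout()
f   <- first_occurrences(ev)
s   <- assign_strata(f, patient_profiles(ev), "E66")

scr <- screen_comorbidities(f, s, comorbidity_codes = "F32")
tidy(scr)       # per-decade and pooled ORs, CIs, corrected p, flags
glance(scr)     # family size m, thresholds, counts
autoplot(scr)   # forest plot by decade

op  <- ordered_pairs(f, "E66", "F32", profiles = patient_profiles(ev))
compute_tor(op) # TOR per gap class with exact sign-test p-values
```
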