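# ibp — individual behavioral profiling for preclinical treatment-response studies

Preclinical tests of psychiatric drugs usually compare *group averages*,
which hides the fact that — as in human PTSD pharmacotherapy — only a
fraction of individuals respond to treatment. **ibp** implements the
*individual behavioral profiling* analysis used in rodent stress/trauma
models: every animal is scored parameter-by-parameter against cutoffs
anchored on a concurrent control population, classified as trauma
**affected** or **unaffected** by a k-of-m rule, and — after treatment —
previously affected animals are classified as treatment **responders** or
**non-responders**. The proportion of responders, rather than any averaged
group effect, becomes the primary measure of drug efficacy.

The package is aimed at behavioral neuroscientists and biostatisticians
analyzing per-animal tables exported from tracking software (water-associated
zero maze, elevated plus maze, open field, social recognition test).

## The classification rule

For each behavioral parameter *j* with control mean *m_j* and control
sample SD *s_j* (denominator *n* − 1), the cutoff is

```
c_j = m_j − s·s_j   (pathological side: low)      flag if  x_ij < c_j
c_j = m_j + s·s_j   (pathological side: high)     flag if  x_ij > c_j
```

with SD multiplier *s* = 1 by default, equality never flagged, and cutoffs
re-estimated per time point from the concurrent controls. An animal is

* **affected** iff it is flagged on at least *k* = 4 of the *m* = 7
  profile parameters post-trauma;
* a **responder** iff, being previously affected, it shows fewer than *k*
  flagged parameters post-treatment.

Two seven-parameter profiles ship built-in: `IBP1` (identical parameter
set at both time points) and `IBP2` (five shared parameters; the two open
field readouts used post-trauma are replaced by two elevated-plus-maze
readouts post-treatment). Derived parameters are computed by
`anxiety_index()` (100·(closed-arm + center time)/total time) and
`preference_index()` (100·(unfamiliar − familiar)/(unfamiliar +
familiar)); `normalize_densitometry()` and `percent_of_baseline()` cover
the western-blot and electrophysiology normalizations used in downstream
validation of the classification.

The statistical layer mirrors the field's standard pipeline:
`fisher_exact_2x2()` for classification proportions, and
`compare_groups()`, a Shapiro–Wilk-gated choice between one-way ANOVA with
Bonferroni post hoc and Kruskal–Wallis with Dunn post hoc.
`simulate_cohort()` generates synthetic cohorts (equicorrelated Gaussian
parameters, configurable affected/responder fractions and effect size)
with ground-truth labels for end-to-end validation.

## Worked example

`worked_example()` returns a fixed 12-animal toy cohort (5 controls, 7
trauma-exposed, both time points) whose arithmetic can be checked by hand:
every parameter's control values are a permutation of 10, 12, 14, 16, 18,
so every cutoff is 14 ± √10 (sample SD = 3.16228 → lower cutoff 10.83772,
upper 17.16228).

```r
library(ibp)
fit <- ibp(worked_example(), "IBP1")
summary(fit)
#> Individual behavioral profiling fit (IBP1, post_trauma)
#>   rule: affected if >= 4 of 7 parameters beyond 1 control SD
#>   cutoffs anchored on 5 'control' animals
#>   control: affected 0/5 (  0%), unaffected 5/5 (100%)
#>   exposed: affected 4/7 (57%), unaffected 3/7 (43%)
```

Animal E02 (values 8, 20, 9, 14, 19, 18, 15) is beyond the cutoff on
exactly 5 parameters — total distance 8 < 10.83772, closed-arm time
20 > 17.16228, closed-arm distance 9 < 10.83772, WAZM freezing
19 > 17.16228, EPM freezing 18 > 17.16228 — hence affected. The full
two-time-point pipeline adds the responder stage:

```r
rep <- run_pipeline(pipeline_config(cohort = worked_example()))
rep
#> IBP pipeline report (IBP1)
#> post_trauma classification:
#>   control: affected 0/5 (  0%), unaffected 5/5 (100%)
#>   exposed: affected 4/7 (57%), unaffected 3/7 (43%)
#> treatment response among previously affected:
#>   exposed: non_responder 2/4 (50%), responder 2/4 (50%)
#> affectedness vs control, group exposed: Fisher exact test (two_sided): p = 0.08081, odds ratio = 0
```

E02 and E03 drop below 4 flags after treatment (responders); E05 retains
all 7 and E06 retains 4 (non-responders). `write_report(rep, "out/")`
writes the per-animal flags, proportions, test table, JSON bundle and a
text summary.

Classification proportions are compared with Fisher's exact test, e.g. an
affected/unaffected split of 2/14 in controls vs 41/31 in trauma-exposed
animals:

```r
fisher_exact_2x2(matrix(c(2, 14, 41, 31), 2, byrow = TRUE))
#> Fisher exact test (two_sided): p = 0.001733, odds ratio = 0.108
```

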