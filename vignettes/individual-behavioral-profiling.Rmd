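---
title: "Individual behavioral profiling: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Individual behavioral profiling: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ibp)
```

## The problem

Averaged group effects hide individual variability in treatment response.
In human PTSD pharmacotherapy only a minority of patients remit fully
under SSRIs; a preclinical analysis that reports a single group mean per
behavioral test cannot represent this. Individual behavioral profiling
(IBP) instead classifies *each animal*, using a battery of behavioral
parameters, and makes the *proportion* of affected animals (after trauma)
and of responders (after treatment) the quantities of interest.

## The classification model

Let $x_{ij}$ be animal $i$'s value on parameter $j$, and let $m_j$, $s_j$
be the mean and sample standard deviation (denominator $n-1$) of the
concurrent control group. The cutoff for parameter $j$ is $m_j \pm
\lambda s_j$, with the sign determined by the parameter's *pathological
direction* and multiplier $\lambda = 1$ by default. Animal $i$ is
*flagged* on $j$ when $x_{ij}$ lies strictly beyond the cutoff on the
pathological side; with flags $f_i = \sum_j \mathbf{1}[\text{flagged}]$
over the $m = 7$ profile parameters,

* post-trauma: affected $\iff f_i \ge k$, with $k = 4$;
* post-treatment (previously affected animals only): responder $\iff
  f_i < k$.

This is a deterministic rule once the cutoffs are estimated; the
"fitting" step of `ibp()` is exactly the estimation of the cutoff table
from the controls, which is why the package exposes it with the classic
modelling interface (`coef()` returns the cutoff table, `predict()`
classifies new animals against it).

Key analytic consequences, both verified in the test suite:

* For an infinite homogeneous Gaussian population scored against its
  *true* mean and SD with one-sided directions and independent
  parameters, the per-parameter flag rate is $\Phi(-1) \approx 0.1587$
  and the affected rate is the binomial tail
  $P(\mathrm{Bin}(7, \Phi(-1)) \ge 4) \approx 0.0148$.
* With cutoffs *estimated* from a small control group (and the controls
  scored against their own plug-in cutoffs), and with correlated
  parameters, the control self-classification rate is substantially
  higher than 1.48% — small-sample noise in the cutoffs and positive
  correlation of the flags both fatten the $k$-of-$m$ tail. This is why a
  control group can legitimately show a double-digit "affected"
  percentage without anything being wrong.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `k` | 4 | flags needed for "affected" (of `m` = 7) |
| `sd_multiplier` | 1 | cutoff width, in control SDs |
| `control_scoring` | `"plug_in"` | how controls are scored against their own cutoffs |
| `responder_mode` | `"post_count"` | responder criterion (see below) |
| `alpha` | 0.05 | omnibus significance gating post-hoc tests |
| `alpha_normality` | 0.05 | per-group Shapiro–Wilk level |

`k`, `m` and the 1-SD width are the published rule; they are exposed
because the rule generalizes (the classification principle, not the
specific battery, is the method).

**Pathological directions.** The rule is published only as "either lower
or higher than the cut-off"; no parameter-by-parameter table of
directions exists. The shipped directions are therefore an inference from
which tail the affected groups occupy in the published group contrasts:
distances traveled, open-arm/center times and the social preference index
are flagged *low* (less exploration, less social memory = worse);
freezing, closed-arm time and the anxiety index are flagged *high*. Users
can override any direction via a custom profile (`write_profile()` /
`read_profile()`), and `two_sided` is available per parameter.

**Responder criterion.** The published wording differs between the two
profiles: "less than 4 affected parameters" (IBP1) vs "recovery in at
least 4 parameters" (IBP2). Because IBP2 swaps two parameters between
time points, a literal per-parameter pre/post "recovery" match is
undefined for 2 of the 7 parameters. The package therefore defaults to
`post_count` (fewer than $k$ flags post-treatment) and offers
`recovered_count` (at least $k$ *unflagged* post-treatment parameters) as
the alternative operationalization; with $k = 4$, $m = 7$ the two rules
coincide, so the choice is immaterial for the shipped profiles and is
kept only for non-default $k$.

**Plug-in vs leave-one-out control scoring.** By default controls are
scored against cutoffs computed from the *full* control group (the
simplest reading of the published procedure). This is slightly
anti-conservative for small control groups, since each control
contributes to its own cutoff. `control_scoring = "leave_one_out"`
re-estimates the cutoffs without the scored animal; excluding an animal
can only move the estimated mean away from it, so leave-one-out flags are
a superset of plug-in flags for the same control (a property the tests
assert). Exposed animals are unaffected by the choice.

## Numerical and procedural choices

* **Sample SD** with denominator $n-1$: the control cohort is a sample;
  the source is silent on the estimator.
* **Strict inequality at the cutoff**: "lower or higher *than*" the
  cutoff; a value exactly equal to a cutoff is never flagged. This only
  matters for exactly representable values and is pinned by a test.
* **Per-time-point cutoffs**: cutoffs are re-estimated from the
  concurrent controls at each time point for both profiles (explicit in
  the IBP2 description; applied to IBP1 for consistency).
* **Degenerate inputs**: a zero control SD collapses the cutoff onto the
  mean and raises a warning naming the parameter; fewer than 2 complete
  controls is an error; incomplete records are labeled `unclassifiable`
  and excluded from denominators but never silently dropped (imputation
  would fabricate flags).
* **Affectedness is affine-equivariant**: rescaling a parameter (units,
  calibration) rescales its cutoffs identically, so labels are invariant
  — asserted as a property test.

## The statistical layer

Classification distributions are compared with the **Fisher exact test**
(two-sided by the minimum-likelihood convention, the standard two-sided
rule; the implementation is `stats::fisher.test`, cross-checked in the
tests against a full hypergeometric enumeration oracle). The reported
odds ratio is the sample odds ratio $ad/bc$. The two-sided convention is
a deliberate choice: the published moderate p-values for the
cross-experiment comparisons are only reproduced under it.

Group-level comparisons of continuous measures use a **normality-gated**
procedure: Shapiro–Wilk per group; if *every* group passes at
`alpha_normality`, one-way ANOVA with Bonferroni-corrected pairwise
t-tests (pooled SD), otherwise Kruskal–Wallis with **Dunn's** rank-based
pairwise test. Dunn's test is implemented in the package (pairwise z
statistics on the pooled tie-corrected ranking) because no installed
package provides it; its arithmetic is pinned against hand-computed rank
sums in the tests. Multiplicity adjustment for Dunn is Bonferroni over
all pairs, and the adjustment method is recorded in the result since the
published methods do not name one. Post-hoc p-values are reported *only*
when the omnibus p is below `alpha`. No variance-homogeneity test is
applied (the published pipeline uses none). A constant group is treated
as failing the normality gate (Shapiro–Wilk is undefined for it) rather
than erroring, so mixed degenerate/non-degenerate data still get the
nonparametric path; fully constant data across groups is an error.

## The synthetic cohort generator

No raw per-animal behavioral data are deposited for this design, so the
package ships a generator that produces cohorts with the structure the
analysis assumes, plus ground-truth labels:

* **Controls** draw their $m$ parameters from a Gaussian one-factor
  model: a latent "anxiety" factor loads $\sqrt{\rho}$ on every parameter
  *in its pathological direction* (a high-anxiety animal travels less
  *and* freezes more), giving equicorrelation $\rho$ between the
  sign-aligned deviations. Loading the factor on the raw scale instead
  would make the shared factor push low- and high-pathological parameters
  in opposite pathological senses — a biologically meaningless structure
  that also suppresses, rather than inflates, the $k$-of-$m$
  false-positive rate. Default $\rho = 0.2$: correlated but far from
  collinear readouts.
* **Exposed** animals are truly affected with probability
  `affected_fraction` (default 0.6, in the range published cohorts show);
  affected animals shift by `effect_size_delta` control SDs (default 2, a
  severe phenotype) in the pathological direction on a random subset of
  `affected_param_count` parameters (default 5 of 7, so the 4-of-7
  boundary is exercised rather than saturated).
* **Post-treatment**, a `responder_fraction` (default 0.4, matching the
  under-half response rates seen with SSRIs) of affected animals revert
  to the control distribution (`responder_residual_delta` allows partial
  reversion); non-responders retain the full shift. Shifted-parameter
  positions index the *ordered* per-time-point parameter list, so the
  five shared IBP2 parameters stay aligned across the swap.
* Default group sizes (16 controls, 93 exposed) are the study sizes of
  the design the analysis comes from. Control means (100) and SDs (15)
  are arbitrary round numbers — no distributional summaries are published
  — and carry no empirical content; every classification result is
  invariant to them by the affine-equivariance property.

What the generator does **not** emulate: skewed or bounded readouts
(times near floor, percentages near ceiling), heteroscedasticity between
groups, session-to-session carryover, or any bout-level structure of the
underlying videos. Passing the recovery tests therefore shows the
pipeline is correct *under its own assumptions*, not that real behavioral
data meet them; with strongly skewed real data the Gaussian 1-SD cutoff
covers a different tail fraction than $\Phi(-1)$.

## Problem sizes used in validation

The test suite and acceptance script validate at sizes chosen to give
tight Monte-Carlo error while remaining desk-scale: $10^5$ animals for
the analytic-limit check (3 binomial SEs $\approx 0.001$), 20 seeds of
50 + 200 animals for parameter recovery, 1,000 random small cohorts for
brute-force oracle equivalence, 1,000 simulated control cohorts for the
finite-sample inflation property, and 2,000 null replicates for the
type-I error of the gated comparison (expected within $0.05 \pm 0.015$).

## Known limitations

* The rule is univariate per parameter; no multivariate or model-based
  classification is attempted (deliberately — the published rule *is* the
  method; improving it is out of scope).
* Directions are an inference, not published fact (see above); a user
  with different readouts must supply their own.
* Plug-in control scoring makes the control "affected" rate depend on
  control group size; compare `leave_one_out` when that rate is itself a
  quantity of interest.
* The Fisher odds ratio is the unconditional $ad/bc$, chosen for
  transparency; it differs from the conditional MLE reported by some
  software.
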