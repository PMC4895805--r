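---
title: "Dose-normalized methotrexate response: model, conventions, and simulator"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dose-normalized methotrexate response: model, conventions, and simulator}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtxresponse)
```

## The scientific problem

Methotrexate (MTX) is the anchor disease-modifying drug in rheumatoid
arthritis (RA), but response varies widely between patients, and the dose a
clinician settles on varies too. A raw before/after change in disease
activity therefore conflates two things: how much a patient improved, and
how much drug it took. This package implements a dose-normalized response
measure for longitudinal RA cohorts and the comparison machinery around it:
scoring, windowed areas, responder classification, folate-pathway genotype
grouping, and nonparametric group tests, plus a synthetic cohort generator
so the whole chain is testable end to end without patient data.

## Disease activity: DAS28-CRP

Disease activity at each clinic visit is the 28-joint Disease Activity
Score with CRP:

$$\mathrm{DAS28} = 0.56\sqrt{T28} + 0.28\sqrt{S28}
  + 0.36\ln(\mathrm{CRP}+1) + 0.014\,\mathrm{VAS} + 0.96$$

with tender-joint count $T28$ and swollen-joint count $S28$ (0–28), patient
global assessment VAS on a 0–100 scale (the 0.014 coefficient matches the
100&nbsp;mm convention), and CRP concentration. `das28_crp()` validates
component ranges and is strictly increasing in every component; its minimum
is the constant 0.96.

One deliberate non-choice: the formula consumes CRP **as given**. Clinical
laboratories report CRP in mg/dL or mg/L, and published uses of the formula
are not consistent about which scale they fed it; the package applies no
silent conversion, and the unit is whatever the input tables use. The
synthetic generator produces values on an mg/dL-like scale (baseline median
near 1.3).

## Windowed areas and index R

For an analysis window $(t_0, t_1)$ in months (0–3 and 0–6 by default),
`das28_auc()` integrates the piecewise-linear interpolant of the visit-level
scores — the trapezoidal rule on the visit grid. If no visit falls exactly
on a window edge, the edge value is linearly interpolated between the
bracketing visits; the trapezoidal rule is only well defined with explicit
edge values, and interpolation is the assumption-free completion of the
piecewise-linear model. Windows not covered by the visit grid raise a
coverage error rather than extrapolating.

The **improved DAS28 area** measures improvement against a common ceiling: a
hypothetical patient pinned at DAS28 = 10 for the whole window, giving
reference areas of exactly 30 score-months over 0–3 months and 60 over 0–6
months,

$$\mathrm{improved\ area} = 10\,(t_1-t_0) - \mathrm{AUC}_{\mathrm{DAS28}}.$$

Anchoring to the fixed ceiling rather than to each patient's own baseline
adjusts for baseline heterogeneity without making small baselines
incomparable. A trajectory above the reference would make the improved area
negative; this is reported with a warning, never clipped.

**Index R** divides the improved area by the cumulative MTX dose over the
same window:

$$R = \frac{\mathrm{improved\ DAS28\ area}}{\mathrm{cumulative\ MTX\ dose}}
  \quad [1/\mathrm{mg}],$$

improvement bought per milligram. It is homogeneous of degree $-1$ in dose
(doubling every weekly dose halves $R$) and invariant to how a constant
dose schedule is split into intervals — both properties are tested.

Cumulative dose converts months to weeks at **exactly 4 weeks per month**,
so a 0–3-month window holds 12 weekly doses and 8 mg/week accumulates to
96 mg. This keeps dose arithmetic on the round scale clinicians use for
"12 weeks of treatment"; a calendar-exact factor (365.25/12/7 ≈ 4.35) is
available through the `weeks_per_month` argument of every dose-consuming
function and is recorded in the run manifest when changed.

## Disease-control classification (months 6–12)

A patient is in **good control** when (a) the weekly MTX dose stayed fixed
across every dose interval intersecting months 6–12, and (b) DAS28 above
the threshold of 2 was recorded at clinic visits "less than once per
month". That phrase is ambiguous between two readings, and
`control_criteria()` implements both:

* **default** — the total exceedance count over the window is strictly less
  than the window length in months (fewer than 6 in a 6-month window, an
  average below one per month);
* **strict** (`strict_mode = TRUE`) — no exceedance at all, i.e. DAS28 held
  at ≤ 2 for the whole window.

The strict good set is provably a subset of the default good set (tested as
a property). The mode in force is written to the run manifest, so reports
are auditable. Patients with no visits inside the window raise an
indeterminate-status error rather than receiving a silent label; how missed
visits inside the window should be handled is a genuinely open question in
this design, and the package surfaces it instead of guessing.

## Genotype grouping

Five folate-pathway SNPs are compared, each collapsed to the two groups the
analysis actually contrasts (homozygous for one allele vs any carrier of
the other):

| SNP | reference group | comparison group |
|---|---|---|
| RFC1 80G>A (rs1051266) | G/G | A allele |
| FPGS 1994G>A (rs10106) | G allele | A/A |
| GGH −401C>T (rs3758149) | C/C | T allele |
| MTHFR 1298A>C (rs1801131) | A allele | C/C |
| TYMS 3′-UTR −6/+6 (rs16430) | −6/−6 | +6 allele |

Allele order is normalized ("A/G" ≡ "G/A"), a Unicode minus is accepted in
TYMS calls, and malformed calls fail with the offending string. One
labelling wrinkle is inherited from the source literature: the GGH variant
appears both as "−401C>T" and under a "452" label in different places; the
package uses the promoter-position key `ggh_401` (rs3758149) throughout and
leaves the discrepancy visible here rather than silently resolving it.

## Statistics

Two-group comparisons use the Mann-Whitney U test, two-sided throughout
(group differences of both signs occur, and no sidedness is assumed).
`mann_whitney()` has two engines:

* **exact** — the permutation null of the rank sum over all
  $\binom{n_1+n_2}{n_1}$ group assignments, ties handled natively through
  mid-ranks. Mid-ranks are multiples of ½, so doubled ranks are integers
  and the full distribution is obtained by a subset-sum dynamic program —
  equivalent to complete enumeration (the test suite proves equality
  against a brute-force enumerator over all assignments) but polynomial
  time. Counts stay below $2^{53}$ for the sizes involved, so
  double-precision counting is exact.
* **approximate** — normal approximation with tie-corrected variance and a
  0.5 continuity correction.

`method = "auto"` uses the exact engine up to a combined sample size of 40
(which covers a 21-patient cohort with room to spare) and the approximation
beyond. On tie-free moderate samples the two agree to well under 0.01
(tested). When every pooled value is identical the p-value is 1 by
convention and the result is flagged.

Summaries are reported as median (25th–75th percentile) with quartiles by
linear interpolation between order statistics at positions $1+(n-1)q$ — R's
quantile type 7 — and the convention is recorded in the manifest. No
multiple-testing correction is applied across the five genotype
comparisons or the six control-status comparisons: each p-value is reported
as-is against the 0.05 convention, matching how such preliminary
pharmacogenetic screens are conventionally reported; adjust downstream if
desired.

`build_table2()` produces the six control-status comparisons (cumulative
dose, improved area, index R × two windows); `build_table3()` the five
genotype comparisons of 0–6-month index R. A SNP with an empty group is
skipped with a warning, not an error.

## The synthetic cohort generator

`generate_cohort()` emulates the structure of a small retrospective MTX
cohort; its defaults are the study conditions the package is tested under:

| parameter | default | rationale |
|---|---|---|
| `n_patients`, `n_good` | 21, 7 | the 7 good / 14 poor split of the motivating design |
| `visit_times` | 0, 1, …, 12 months | monthly clinic visits |
| `baseline_das28_mean`, `_sd` | 4.0, 1.0 | baseline DAS28 median 4.00; draws truncated to the observed 2.31–6.66 range |
| `good_decline_rate` | 0.5 /month | good responders settle below the DAS28 = 2 threshold before month 6 |
| `poor_decline_rate` | 0.15 /month | poor responders improve but typically stay above 2 through months 6–12 |
| `measurement_noise_sd` | 0.3 | visit-to-visit wobble of a composite clinical score |
| `weekly_dose_levels` | 6, 8, 10 mg/week | 0–3-month cumulative doses of 72–120 mg, bracketing the reported 96–118 mg medians |
| `genotype_group_probabilities` | 15/21, 4/21, 10/21, 2/21, 13/21 | the reported genotype-group margins out of 21 |

The trajectory model is deliberately the simplest one that makes the
windowed areas controllable: DAS28 declines linearly from baseline at the
responder group's rate, floored at 0, with i.i.d. Gaussian noise per visit
on the target score. Components are then **back-filled** so that the score
formula remains the single source of truth: VAS is set to 10× the target
(clamped to 0–100), CRP to an exponential map of the target calibrated so a
baseline near 4 yields CRP near 1.2 mg/dL, and the joint-count terms absorb
the residual with $T28 = S28$, rounded to integers in [0, 28]. The DAS28
recomputed from the rounded components is the ground truth stored with the
visit. Noise enters exactly once (through the target), so a zero-noise,
zero-decline configuration produces exactly constant trajectories — a
degenerate case the tests rely on. Rounding moves the realized score by at
most about 0.2 from the target, and the formula's floor of 0.96 means
targets below ~1 are realized as ~1; both are inherent to demanding that
components, not scores, are the primitive data.

`genotype_effect_on_R` multiplies the decline rate of carriers of the RFC1
comparison group (the contrast of principal interest in this design); at
its default of 1 the generator is an exact null for all five genotype
comparisons, which is how the type-I-error property is tested.

What the generator does **not** emulate: dose titration (each patient keeps
one constant weekly dose — dose changes must be injected explicitly to
exercise the poor-control "dose change" path), dropout and missed visits,
within-patient correlation of component errors (VAS, CRP and counts are
collinear given the target, which real data are not), per-allele
Hardy-Weinberg structure (genotypes are sampled at the two-group level the
analysis uses), and any toxicity-driven discontinuation. Passing tests on
this simulator therefore validate the *analysis machinery* — scoring,
integration, classification, testing — not any claim about real RA
trajectories.

## Numerical and operating characteristics

Choices a re-implementer would need:

* trapezoidal integration knots are the union of window edges and interior
  visits; edge values by linear interpolation (`stats::approx`);
* quartiles: type 7; ranks: mid-ranks (`base::rank` default);
* exact-test extremeness: $|U - n_1 n_2/2| \ge$ the observed deviation,
  evaluated in integer arithmetic on doubled rank sums, so no floating
  tolerance enters the exact p-value;
* dose intervals are half-open $[s, e)$, must tile the window without gaps
  or overlaps, and coverage failures are errors, not silent zeros.

The test suite measures, at the scales chosen for routine runs: empirical
type-I error of the genotype comparison under the null generator over
1000 replicate 21-patient cohorts (observed rejection rate ≈ 0.038 at
nominal 0.05 — slightly conservative, as expected for an exact test on
discrete small-sample nulls); and label/effect recovery over 200 replicates
of a well-separated, noise-free configuration (decline rates 1.0 vs 0.0,
single 8 mg/week dose level, baseline sd 0.5), where classification
recovers the true labels in every replicate and the 0–6-month index-R
comparison is significant at 0.05 in every replicate. The well-separated
scenario holds the dose level fixed deliberately: index R divides by dose,
so dose heterogeneity is variance for the comparison — with the default
mixed dose levels the same effect is detected in only ~70% of replicates,
a real (and clinically relevant) property of dose-normalized statistics,
not an artifact.

## Limitations

The improved-area reference of DAS28 = 10 is near the formula's practical
ceiling but not a bound; noisy scores above 10 would produce negative
improved areas (flagged). The classification rule is stricter than common
EULAR/ACR responder definitions and is not benchmarked against them here.
The exact test's conservatism at $n = 21$ means true size ~0.04 at nominal
0.05; with two patients in a group (as for MTHFR C/C at its configured
frequency) the smallest attainable two-sided p is far above 0.05, so
"non-significant" for such contrasts carries little information — a
small-sample reality the package reports rather than hides.
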