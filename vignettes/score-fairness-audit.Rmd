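---
title: "Auditing a clinical risk score across demographic groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing a clinical risk score across demographic groups}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fairaudit)
```

## The audit model

We observe, for each individual, a risk score $\hat Y \in (0,1)$ — the
predicted probability of an emergency hospital admission or death within one
year — a binary outcome $Y$, demographic covariates (age, sex, SIMD
deprivation decile, ethnicity, urban/rural and mainland/island residence),
and, for individuals with $Y=1$, the kind of event (admission, or death
without a prior admission) together with an ICD-10 code: the primary
admission diagnosis, or the primary cause of death for deaths without an
admission. Scores are stored as probabilities; the familiar integer 1–99
presentation of deployed scores is treated purely as a percentage display
convention, since the audit conditions on thresholds such as
$\hat Y < 0.1$.

A *comparison* is a pair of groups defined on one grouping variable
(`group_spec()`): M/F for sex; age $\ge 65$ versus $\le 25$ (the middle is
excluded); the most versus least deprived quintile, built from the top and
bottom two SIMD deciles; white versus non-white ethnicity; urban/rural; and
mainland/island. Rows with a missing grouping value are excluded from that
comparison only. All metrics sweep a cutoff grid, by default
$c = 0.01, 0.02, \dots, 0.99$, and a "positive prediction" is
$\hat Y \ge c$ throughout; "below the cutoff" is the strict $\hat Y < c$.

Per comparison the audit computes:

* **Score CDFs** $P(\hat Y < c \mid G = g)$ with pointwise 95% Wilson
  intervals (demographic parity).
* **Counterfactual CDFs**: with $w_g(s)$ the target group's weight on
  stratum $s$ (age band $\times$ sex $\times$ SIMD decile) and
  $F_{g',s}$ the source group's within-stratum score CDF,
  $\sum_s w_g(s)\,F_{g',s}(c)$ — the distribution $g$ would show if its
  scores came from $g'$, covariate profile held fixed. Intervals come from
  a stratified bootstrap that resamples within the strata of $g'$.
* **ROC / AUROC** with the half-credit tie convention (the standardised
  rank-sum estimator; scores have display granularity, so ties are real)
  and the placement-value (DeLong) variance estimator for the AUROC
  standard error. This choice is recorded in the run manifest; any
  asymptotically valid estimator would do, and ours is cross-checked
  against an independent implementation in the test suite.
* **Calibration curves**: by default 20 equal-width score bins (quantile
  binning by flag), per bin the mean score against the observed event rate
  with Wilson intervals; bins under `min_count` (default 50) are omitted
  and reported.
* **FOR / FDR curves**: $\mathrm{FOR}(c) = P(Y=1 \mid \hat Y < c)$ and
  $\mathrm{FDR}(c) = P(Y=0 \mid \hat Y \ge c)$, with Wilson intervals.
  Cutoffs whose conditioning set is empty are *undefined* and carried as
  missing values end to end — never silently zero.
* **Standardised (adjusted) FOR / FDR**: the within-stratum rate averaged
  under a fixed reference strata distribution,
  $\sum_s w_{\mathrm{ref}}(s)\,\mathrm{FOR}_s(c)$, which removes
  between-group differences mediated by age, sex and deprivation.
* **False-negative decomposition**: among a group's events, the proportion
  of each admission type among all events ($A$) versus among events with
  $\hat Y < 0.1$ ($B$), separately for admissions and for deaths without
  admission; $B - A > 0$ marks types the score disproportionately fails to
  anticipate. Admission types are the uppercased first letter of the
  ICD-10 code mapped through a configurable table whose fixed defaults
  group S, T, V, X, Y as *external* causes and letter R as *abnormality
  NEC*; letter-level grouping is an approximation for letters shared
  across chapters, and the map is editable (`admission_type_map()`).

## Design choices in the open corners

**Stratification when the group is a stratum dimension.** Counterfactual
reweighting and direct standardisation use age-band × sex × SIMD-decile
cells (5-year age bands, 0–4 … 85–89, 90+ by default: fine enough to absorb
age confounding, coarse enough to keep cells occupied). When the grouping
variable is itself one of those dimensions — the age, sex and deprivation
comparisons — the two groups occupy disjoint cells and no reweighting is
possible, so the audit drops that dimension from the stratification for
that comparison (`strata_vars`): the sex comparison matches on age and
SIMD, and so on. Requesting an impossible adjustment (e.g. standardising
the over-65 group to the under-25 group's age-band distribution) raises a
named no-overlap error rather than returning something vacuous.

**Reference distribution for paired adjusted curves.** The reference is
selectable: the pooled distribution of the two compared groups (default,
making the pair commensurable), the comparator group, or the group itself.
For the paired choices the reference is restricted to the strata occupied
by *both* groups and renormalised. This common-support restriction matters:
without it, strata empty in the smaller group are dropped and renormalised
for one curve of the pair but not the other, and the resulting support
mismatch biases the pair's difference by an amount comparable to its
confidence width (we observed exactly this at $n = 10^5$ with a 5:1 group
size ratio).

**Empty strata and empty conditioning sets** are dropped with the remaining
reference weights renormalised, and the dropped reference mass is reported
per cutoff (`dropped_mass`); no imputation, no model assumptions,
transparent diagnostics.

**Intervals** are pointwise 95% throughout, never simultaneous: Wilson for
raw proportions; percentile bootstrap (default 1000 replicates, seeded) for
reweighted or standardised curves, resampling within strata; for
decomposition contrasts, a nonparametric bootstrap over the group's
*events*, which automatically respects the nesting of low-score events
within all events. Curve differences combine the inputs' interval
half-widths by variance addition, preserving percentile asymmetry. The
stratified bootstrap exploits that every curve metric depends on a score
only through its position relative to the grid: a stratum reduces to
counts over (score bin, outcome) cells, and within-stratum resampling is a
multinomial draw over those cells, which keeps $10^5$ rows × 1000
replicates in seconds.

## The synthetic cohort generator

There is no deposited data to run an audit like this against — cohorts of
scored individuals with one-year outcomes live in protected national health
records — so the generator is a first-class module whose role is
*structural realism plus known ground truth*, not fidelity to any deployed
score's risk surface.

Defaults emulate a national general-population cohort: 45.4% male; age as a
three-component normal mixture (weights 0.170/0.615/0.215 on components
centred at 9, 42 and 74 years), rounded and clamped to 0–105, tuned to mean
43.3 and SD 23.8; SIMD decile weights putting 21.5% in the most and 18.7%
in the least deprived quintile; ethnicity white/non-white/missing =
0.668/0.218/0.114 with the *probability* of missingness rising with age
(log-odds slope 0.045/year, intercept calibrated on the realised ages so
the overall missing fraction is matched) — so ethnicity-missing individuals
are systematically older, a non-random missingness pattern real linked
records exhibit; urban residence depending on deprivation quintile
(96.5%/91.9% urban in the extremes, 75.9% between, marginally 83.3%); and
1.86% island residence.

True one-year risk is logistic:
$\mathrm{logit}\,p = \beta_0 + \beta_a(\mathrm{age}-43.3) +
\beta_m \mathbf{1}[\mathrm{male}] + \beta_d(\mathrm{SIMD}-5.5) +
\varepsilon$, with individual noise $\varepsilon \sim N(0, \sigma^2)$
representing risk heterogeneity the score *does* capture. Outcomes are
Bernoulli($p$); the reported score equals $p$ (clipped into (0.01, 0.99),
mirroring the 1–99 display convention) unless a per-group calibration
distortion (shift/scale on the log-odds) is configured. Defaults
$\beta_0 = -2.65$, $\beta_a = 0.011$, $\beta_m = 0.10$, $\beta_d = -0.03$,
$\sigma = 0.18$ give a one-year event rate near 7% and scores concentrated
below 0.2 — deliberately modest gradients, chosen once: deployed
emergency-admission scores are heavily concentrated at low values, and the
concentration keeps every default calibration bin either populated by
$\ge 10^4$ individuals or too small to report, so calibration claims rest
on solid bins. Direct group effects (non-white, rural, island) default to
zero, making score ⟂ group | (age, sex, SIMD) hold exactly — the null that
counterfactual and adjusted curves are designed to recover. Dependence
knobs (`urban_age_slope`, `female_age_shift`, nonzero group coefficients,
`calibration_distortion`, `inject_group_miscalibration()`) create the
alternatives.

Events are typed: the probability that an event is a death without prior
admission rises logistically with age (so the cause-of-death rule is
exercised), and the ICD-10 first letter is drawn from a per-cell mixture
over (4 age bands × sex × deprivation half), with external causes
concentrated in the young and in males, circulatory/neoplastic causes in
the elderly, and obstetric codes only in females aged 15–44. Generated
codes are letter + "00" (only the first letter is consumed downstream); a
full-code table can be configured.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: longitudinal hospital-activity and prescribing
histories (the feature space of real scores), model-based score error
structure (the synthetic score is the true risk unless distorted, so its
AUROC is the attainable ceiling given noise), geographic micro-structure,
and within-letter ICD-10 composition. Tests against the generator validate
the *estimators* — that the audit recovers distributional differences,
miscalibration, mediation structure and composition shifts that are truly
present — not any claim about a particular deployed score.

## Numerical conventions

* "Less than the cutoff" is strict (`<`) everywhere, matching the
  probability statements defining the metrics; ties at the cutoff count as
  positive predictions.
* Undefined estimates propagate as `NA` with `n_effective = 0`.
* Wilson intervals use the group size at the conditioning set; the `se`
  column is $\sqrt{\hat p(1-\hat p)/n}$ for Wilson curves and the
  bootstrap SD for bootstrap curves.
* All randomness flows from explicit seeds; `run_audit()` expands one root
  seed per (comparison, stage) with a fixed affine-modular scheme, so a
  re-run reproduces the bundle byte for byte (PDF figures are written
  uncompressed with their date metadata normalised for this reason).
* Problem sizes in the shipped tests: enumeration oracles on cohorts of at
  most 20 rows (60 random cohorts, several cutoffs each); generator-based
  recovery checks at $n = 10^5$ with 300–1000 bootstrap replicates.

## Known limitations

Letter-level admission typing conflates chapters sharing a letter (D:
blood disorders and some neoplasms). The counterfactual matches on
covariate strata only — with richer inputs one could match on clinical
history, which the cohort schema deliberately omits. Confidence bands are
pointwise: statements over many cutoffs at once inherit strong positive
correlation across cutoffs (beyond the score's maximum, all cutoffs carry
literally the same conditioning set), so "the interval excludes zero at x%
of cutoffs" summaries should be read as descriptions of curves, not
family-wise tests. Standardised comparisons are only defined on common
stratum support; groups defined by a stratum dimension are standardised
over the remaining dimensions.
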