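# fairaudit

Fairness audit of clinical risk scores across demographic groups.

## The problem

Deployed clinical risk scores — such as national emergency-admission risk
scores that estimate an individual's probability Ŷ of an emergency hospital
admission or death within one year — are consumed through thresholds: a
practitioner acts when Ŷ ≥ c. Even a score that is well calibrated in every
demographic group can then have very different *consequences* across groups,
because groups differ in their score distributions. `fairaudit` implements a
reusable, audited pipeline for quantifying that differential behaviour across
comparisons defined by age, sex, deprivation (SIMD decile), ethnicity and
urban/rural or mainland/island residence:

- **Demographic parity** — the score CDF per group, P(Ŷ < c | G = g), over a
  cutoff grid, with pointwise Wilson intervals, and **counterfactual CDFs**:
  the distribution group *g* would show if its scores were drawn from group
  *g′* while holding *g*'s distribution over age-band × sex × SIMD strata
  fixed, isolating group effects not mediated by those covariates.
- **Discrimination and calibration** — per-group ROC curves, AUROC
  = P(Ŷ₁ > Ŷ₂ | Y₁ = 1, Y₂ = 0) with a placement-value (DeLong) standard
  error and half-credit tie handling, and binned reliability curves.
- **Error-rate curves** — the false omission rate FOR(c) = P(Y = 1 | Ŷ < c)
  and false discovery rate FDR(c) = P(Y = 0 | Ŷ ≥ c) per group across the
  cutoff grid, raw and **directly standardised** to a fixed reference
  distribution over age–sex–SIMD strata (removing differences mediated by
  those covariates), with stratified-bootstrap intervals.
- **False-negative decomposition** — among events, the composition of
  admission types (from the first letter of the ICD-10 primary diagnosis, or
  primary cause of death for deaths without a prior admission) among all
  events (A) versus among low-score events with Ŷ < 0.1 (B); the contrast
  B − A with bootstrap intervals flags admission types the score
  disproportionately fails to anticipate.

Real cohorts of this kind live in protected national health records, so the
package ships a **synthetic cohort generator** with known ground truth:
configurable demographic marginals (including non-random ethnicity
missingness that rises with age and urban residence that depends on
deprivation), a logistic true-risk model, controllable per-group calibration
distortion, and covariate-dependent admission-type mixtures. Every stage of
the audit is exercised end-to-end against this generator, with brute-force
enumeration oracles on small cohorts.

## Worked example

```r
library(fairaudit)

cfg    <- generator_config(n = 50000, seed = 3)
cohort <- generate_cohort(cfg)$cohort

g     <- assign_group(cohort, builtin_group_specs()$deprivation)
most  <- g == "most_deprived"
least <- g == "least_deprived"

au_most  <- auroc_with_se(cohort$score[most],  cohort$outcome[most])
au_least <- auroc_with_se(cohort$score[least], cohort$outcome[least])
```

```
AUROC most deprived:  0.591 (SE 0.010)
AUROC least deprived: 0.596 (SE 0.011)
```

Discrimination is statistically indistinguishable between the deprivation
extremes — as expected here, since the generator's score *is* the true risk.
The consequences of thresholding still differ:

```r
f <- curve_difference(
  for_curve(cohort$score[most],  cohort$outcome[most],  group_label = "most"),
  for_curve(cohort$score[least], cohort$outcome[least], group_label = "least"))
f[c(5, 10, 20), c("cutoff", "estimate", "lower", "upper")]
```

```
  cutoff estimate    lower  upper
1   0.05  0.01032 -0.00490 0.0285
2   0.10  0.00868  0.00109 0.0163
3   0.20  0.01520  0.00787 0.0225
```

At a 10% cutoff, individuals in the most deprived quintile who fall below
the threshold carry an absolute one-year event risk about 0.9 percentage
points higher than their least-deprived counterparts (95% interval 0.1–1.6):
false negatives are costlier there, purely because the deprived group's risk
distribution sits higher. The false-negative decomposition shows *which*
admissions hide below the threshold:

```r
dt <- decomposition_table(cohort, most, threshold = 0.1,
                          n_boot = 500, seed = 4)
head(dt[dt$event_kind == "admission",
        c("category", "n_all", "A", "B", "diff", "lower", "upper")])
```

```
         category n_all     A     B    diff   lower  upper
1 abnormality_NEC   107 0.132 0.149  0.0164  0.0027 0.0302
2     circulatory    80 0.099 0.089 -0.0104 -0.0249 0.0025
3       digestive    99 0.123 0.114 -0.0088 -0.0237 0.0040
4       endocrine    16 0.020 0.018 -0.0014 -0.0076 0.0043
5        external   179 0.222 0.246  0.0243  0.0079 0.0398
6   genitourinary    54 0.067 0.069  0.0017 -0.0087 0.0115
```

External-cause admissions (ICD-10 letters S, T, V, X, Y — accidents,
self-harm, assault, complications) make up 22% of this group's admissions
but 25% of the admissions the score scored below 10% (B − A = +0.024,
interval excluding zero): they are disproportionately unanticipated.

The full audit — all six comparisons × all metrics, with figures and a
manifest — runs from one seeded configuration:

```r
cfg <- audit_config(output_dir = "bundle",
                    generator = generator_config(n = 1e5, seed = 1),
                    seed = 1)
run_audit(cfg)
render_report("bundle")   # bundle/report.md
```

A thin command-line front end is included at `inst/cli/fairaudit.R`
(`generate`, `run`, `report` subcommands). An example cohort file in the
package's delimited-text schema is at
`inst/extdata/synthetic_cohort_300.csv`.

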