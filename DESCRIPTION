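Package: fairaudit
Title: Fairness Audit of Clinical Risk Scores Across Demographic Groups
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An audited pipeline for evaluating the differential behaviour of
    a probabilistic emergency-admission risk score across demographic groups.
    Provides score-distribution (demographic parity) curves, counterfactual
    score distributions via covariate-strata reweighting, group-wise ROC/AUROC
    and calibration curves, false omission and false discovery rate curves with
    direct standardisation over age-sex-deprivation strata, and a decomposition
    of false negatives by admission type from ICD-10 diagnosis codes. Includes
    a configurable synthetic cohort generator with known ground truth so that
    every stage of the audit can be exercised and tested without access to
    protected health records, and an orchestrator that runs the full audit from
    a single seeded configuration into a reproducible file bundle.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
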