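Package: ancempower
Title: Targeted Learning of Women's Empowerment Effects on Antenatal Care Attendance
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline linking survey-based women's empowerment
    indices to antenatal care (ANC) attendance in clustered household
    surveys. Constructs WEAI-style equal-domain-weight empowerment scores,
    SWPER-style principal-component indices, and the WAMI socioeconomic
    index; estimates pairwise average treatment effects of empowerment
    category on ANC outcomes by targeted maximum likelihood estimation
    (TMLE) with convex Super Learner ensembles for the outcome regression
    and propensity score, village-clustered influence-curve standard
    errors, and parametric G-computation with cluster bootstrap as a
    robustness check. Includes a synthetic cohort generator with known
    counterfactual ground truth and a Monte-Carlo validation harness for
    parameter recovery, double robustness, and confidence-interval
    coverage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
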