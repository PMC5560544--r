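Package: calfsid
Title: Acid-Base Derivation and Mortality Prognosis for Critically Ill
    Neonatal Calves with Diarrhea
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for the quantitative workup of neonatal calf diarrhea
    cohorts: Henderson-Hasselbalch and simplified strong ion (physicochemical)
    acid-base derivations with calf-specific constants (bicarbonate, van Slyke
    base excess, anion gap, Atot, measured strong ion difference, strong ion
    gap, unidentified strong ions), rule-based SIRS and septicemia
    classification, classification trees with Gini splitting, surrogate
    splits and cross-validated cost-complexity pruning, univariate odds
    ratios and backward-Wald logistic regression with Hosmer-Lemeshow
    goodness of fit, ROC/Youden cutpoint and decile survival analysis, a
    synthetic cohort generator that emulates the marginal structure of a
    large hospital population, and published prognostic models embedded as
    scoring functions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    rpart,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
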