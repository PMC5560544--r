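---
title: "Methods: acid-base derivation, synthetic cohorts and mortality modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acid-base derivation, synthetic cohorts and mortality modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(calfsid)
```

This vignette is the package's own account of the models it implements,
the choices that were genuinely open, and what the test suite does and does
not establish.

## The physicochemical acid-base model

Neonatal calves with diarrhea develop strong ion (metabolic) acidosis
driven largely by D-lactate absorbed after ruminal/intestinal bacterial
fermentation, plus unmeasured strong anions. Two complementary frameworks
are computed per calf by `derive_acid_base()`:

* **Henderson–Hasselbalch**: actual bicarbonate
  `HCO3 = S * pCO2 * 10^(pH - pK1')` with the plasma constants for calves
  (`pK1' = 6.105`, `S = 0.0307` mmol/L per mm Hg), the in vitro base excess
  by the van Slyke equation with hemoglobin buffering (hemoglobin in g/dL —
  the buffering coefficients require this unit), and the anion gap.
* **Simplified strong ion model**: the nonvolatile weak acid pool
  `Atot = 0.343 * total protein (g/L)` with `pKa = 7.08` (experimentally
  determined for calf plasma), its dissociated charge
  `A- = Atot / (1 + 10^(pKa - pH))`, the measured strong ion difference
  `SIDm = Na + K - Cl - D-lactate - L-lactate`, the strong ion gap
  `SIG = A- - AG` (negative = unmeasured strong anion excess), and
  `USI = SIG + D-lactate + L-lactate`, the strong ion difference still
  unexplained after crediting the measured lactates.

Two identities hold by construction and are enforced to 1e-9 in the tests:
`USI = SIG + D-lactate + L-lactate` and `USI + SIDm = A- + HCO3`. The
second is the useful cross-check: it ties the strong-ion bookkeeping to the
Henderson–Hasselbalch bicarbonate through the anion gap.

**Temperature correction.** Analyzers measure at 37 °C; conversion to the
patient's rectal temperature uses the standard linear-in-log clinical
forms, `pH_T = pH - 0.0146 (T - 37)`, `pCO2_T = pCO2 * 10^(0.019 (T-37))`,
`pO2_T = pO2 * 10^(0.0052 (T-37))`. These exact slopes are an assumption
(analyzer firmware varies, and the pO2 slope in particular differs between
algorithms); they are exposed in `acid_base_constants()` so a user can
match their own analyzer. The derived quantities deliberately use the 37 °C
values, matching analyzer convention for reported bicarbonate and base
excess; temperature-corrected gas columns are appended separately when
requested.

**Validation.** Physiologically impossible inputs (pH outside 6.0–8.0,
negative concentrations, temperature outside 25–43 °C) are errors;
implausible-but-possible patterns (sodium at or below chloride) are
warnings, because they occur in real records through transcription error
yet can also be legitimate extreme pathology.

## Clinical rules

SIRS follows the two-of-four rule: leukocytes outside 5–12 G/L, rectal
temperature outside 38.5–39.5 °C, heart rate > 120/min, respiratory
rate > 36/min. Reference intervals are inclusive (a value *on* the limit is
normal), matching the strict `>` of the rate criteria. A calf with missing
inputs is classified positive if the observed criteria already reach two,
and indeterminate otherwise — never silently negative, because downstream
models use SIRS as a covariate and a silent negative would bias them.
Clinical septicemia is SIRS plus at least one suspicion sign (marked
mucosal hyperemia, injected episcleral vessels, mucosal/subscleral
bleeding, hypopyon). The published regression model for septicemia
probability (age, recumbency, absent suckling reflex, focal infection) has
no printed coefficients in the mortality study; it is supported as a
user-supplied model JSON scored at the `>= 0.3` threshold.

## The synthetic cohort generator

The generator (`simulate_cohort()`) defines the study conditions for every
simulation-based test. Its defaults are fixed, not tuning knobs:

* **Marginals** (`analyte_reference()`): per-analyte median and quartiles
  of the surviving calves of the reference population (survivors are 78% of
  the cohort, so their margins dominate). Strongly right-skewed analytes —
  lactates, urea, creatinine, enzyme activities, leukocyte/thrombocyte
  counts, potassium, phosphorus, age — use a shifted log-normal whose three
  parameters match the three quartiles exactly
  (`shift = (q25*q75 - med^2) / (q25 + q75 - 2*med)`); the rest use a
  normal matched to median and half-IQR. Samples are winsorized to
  plausibility bounds, which preserves every quantile strictly inside the
  bounds (unlike conditional truncation, which would shift them).
* **Clinical prevalences** (`clinical_prevalences()`): the per-category
  counts of the study's univariate table (e.g. absent suckling reflex
  512/1,328, cachexia 198/1,386, hypothermia 572/1,400). The rectal
  temperature margin (mean 38.707, sd 0.9) is chosen so that
  P(T < 38.5) equals the printed 40.9% hypothermia prevalence. Heart and
  respiratory rate margins (110 ± 25, 32 ± 10) are package choices (the
  study prints no margins for them) set so the emergent SIRS prevalence
  (~65%) approximates the printed 62%.
* **Dependence**: a Gaussian rank copula on configured pairs only, default
  rho = 0.3 for pH–pCO2 and L-lactate–creatinine. True inter-analyte
  correlations are unreported; the links are recorded in the sidecar JSON
  and everything else is sampled independently.
* **Outcome**: Bernoulli from the published clinical + laboratory logistic
  model applied to the generated features. Binary features (pH < 6.85,
  glucose < 3.2, ...) are *computed* from the continuous draws, never
  sampled, so their prevalence emerges from the margins. With the default
  margins the emergent mortality is ~22%, matching the study's 22.4%
  without any explicit calibration — a useful coherence check on the
  margins and prevalences.
* **Expert-review outcome**: `outcome_predicted` flips 57/313 of
  non-survivor labels to survivors (the re-allocation rate of the study's
  independent record review), at random.
* **Missingness** is injected last, after outcome assignment, at the
  per-column rates implied by the study's table footnotes, so outcome
  generation always sees complete data (MCAR by construction).

What the generator does **not** emulate: joint structure beyond the two
copula links (real acid-base panels are strongly cross-correlated through
hydration status), treatment effects, time structure, and any systematic
(non-random) missingness. Passing tests therefore demonstrate correctness
of the pipeline's statistics under the study's marginal structure, not
fidelity of any multivariate feature of real clinical data.

## Classification trees

`grow_tree()` is a from-scratch Gini partitioner with deterministic
semantics chosen for reproducibility:

* every midpoint between consecutive distinct observed values is evaluated;
  ties in the impurity decrease go to the earlier variable, then the
  smaller cutpoint;
* 3-point clinical scores are ordered numeric (splits at 1.5/2.5), flags
  0/1;
* cases missing the split variable contribute no impurity decrease, and are
  routed by surrogate splits — the best-agreeing split of another variable,
  kept only when its agreement beats the send-everyone-with-the-majority
  baseline — falling back to the majority direction;
* growth stops at `min_split = 20`, `min_bucket = 7`, or when the
  root-scaled Gini decrease falls below `cp = 0.001` (grow generously,
  prune honestly). These controls mirror common recursive-partitioning
  practice and are exposed in `tree_control()`.

Pruning is weakest-link cost-complexity on misclassification risk, with the
subtree chosen by the **lowest** 10-fold cross-validated error (the 1-SE
rule is available behind a flag but off by default, because the analysis
this emulates selected the minimum). Folds are stratified by outcome — the
22% event rate makes unstratified folds noticeably noisier — and seeded.
Ties in the CV error go to the smaller tree. On label-permuted data no
split reduces misclassification systematically, so the weakest-link
sequence collapses early and the pruned tree is the root in the large
majority of seeds; the test suite requires >= 16/20.

The test suite cross-checks root splits against `rpart` (the same Gini
criterion) on complete data, and `best_split()` against a naive
double-loop exhaustive search.

A note on scale: on a 1,400-calf synthetic cohort the pruned tree typically
retains only the strongest split (CNS involvement). The rarer planted
effects (ileus at 2.3% prevalence) carry too few events per node at this
size to survive CV pruning reliably; the recovery tests therefore use
either noiseless planted rules (exact recovery required) or larger cohorts
(coefficient recovery at n = 50,000).

## Regression and evaluation

* Univariate odds ratios are the closed-form 2x2 `ad/bc` with Wald
  intervals (`z = 1.96`), the arithmetic behind single-predictor logistic
  regression; zero cells get the Haldane–Anscombe 0.5 correction with a
  warning (unexercised on the study's tables, which have none).
* Multivariable fits use `stats::glm` (binomial IRLS) with a tightened
  convergence tolerance; each model is fitted on the complete cases of its
  own columns, reporting n. Coefficients beyond 15 on the logit scale
  raise a perfect-separation error naming the term.
* Backward Wald elimination removes the largest-p term while p > 0.01 and
  refits; it never removes a term at or below the threshold, and logs the
  elimination order.
* Hosmer–Lemeshow groups are rank-based deciles with ties sharing a group
  (so a model with k < 10 distinct risks gets exactly k groups), df = g-2.
  The tie-collapsing rule of the original analysis software is not
  documented, so printed HL statistics are treated as metadata, not
  reproduction targets.
* Mann–Whitney U uses exact enumeration for small tie-free samples and the
  tie-corrected normal approximation otherwise; two identical constant
  samples return U = n1 n2 / 2 and p = 1 rather than a 0/0.
* ROC/AUC and the DeLong CI come from pROC; the Youden-optimal cutpoint
  maximizes sensitivity + specificity - 1 with ties to the lowest
  threshold.
* Decile survival analysis bins by rank (ties stay together; merged bins
  are reported with a warning), compares each decile to the reference
  decile by Pearson chi-square without continuity correction at the
  Bonferroni-adjusted level 0.05/9 (displayed as P <= 0.006). "The decile
  best within the reference range" is interpreted as the bin with the
  greatest overlap fraction between its value interval and the reference
  interval, ties resolved by bin median closest to the interval midpoint;
  this verbal-rule interpretation is recorded in the output attributes.

## Published models as scoring functions

`published_models()` embeds the four printed multivariable models with
coefficients, SEs, cutpoints (0.25 / 0.27 / 0.27 / 0.19) and published
performance (AUC 0.77 / 0.71 / 0.84 / 0.69). Classification uses
`probability >= cutpoint`; whether the original analysis used `>=` or `>`
at the cutpoint is not stated, and `>=` is chosen for consistency with the
septicemia rule's stated `>= 0.3`. The published AUCs, sensitivities,
specificities and Hosmer–Lemeshow statistics were estimated on the real
hospital population and are **not reproducible** from synthetic data; they
are carried as read-only metadata. The package's own measurements on
synthetic cohorts land nearby (AUC ~0.76 vs 0.77; Youden cutpoint ~0.25 vs
0.25; pH-rule sensitivity/specificity ~12%/96% vs 10.9%/97.1%), which is
emulation, not reproduction.

One further printed-value caveat: the complicated-navel-infection odds
ratio computes to 3.31 from its printed counts while the table prints 3.32
(presumably rounded from unrounded regression output); the package stores
the printed value as metadata and documents the discrepancy.

## Numerical and scale choices

Derived values are stored at full precision; display rounding (1 dp for
acid-base panels) is left to the caller. Simulation-based tests use sizes
chosen to balance statistical resolution against runtime: identity suites
at 10^4 panels, quantile-matching checks at 10^5 draws, coefficient
recovery at 20 seeds x 50,000 calves, tree recovery at 2,000, elimination
calibration at 200 runs x 400. The interfaces are data-frame-first and
return tibbles so the pipeline composes with dplyr; there is no shell
entry point — `run_report()` is the end-to-end driver and
`scripts/acceptance.R` the reproduction script.

## Known limitations

* The generator's independence structure understates real multivariate
  pathology (e.g. the dehydration axis linking PCV, protein, urea,
  creatinine and lactate).
* Surrogate-split quality on synthetic data is optimistic: with mostly
  independent margins there is often no good surrogate, whereas real
  clinical variables are collinear.
* The published septicemia model's coefficients are not shipped (they are
  not printed in the mortality study); only the scoring plumbing and the
  0.3 threshold are.
* Hosmer–Lemeshow degrees of freedom can differ from the printed ones for
  models with few binary terms, because the original tie-collapsing rule is
  unknown.
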