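#' Run the full prognostic analysis pipeline on a cohort
#'
#' Replicates the analysis order of the reference study on a cohort table:
#' acid-base derivation, SIRS/septicemia classification, univariate odds
#' ratios for the clinical categories, decile survival analysis for
#' selected analytes, classification tree growth and cross-validated
#' pruning, logistic regression on the tree's binary features with backward
#' Wald elimination, and ROC/Youden evaluation of the fitted and published
#' models. All outputs are written to `out_dir` as CSV/JSON plus a
#' plain-text log; the bundle is deterministic given the cohort, the
#' configuration and `seed`.
#'
#' @param cohort Cohort data frame or path to a cohort CSV
#'   (see [read_cohort()]).
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for fold assignment.
#' @param outcome Outcome column to analyze.
#' @param tree_predictors Candidate split variables; defaults to the
#'   clinical flags/scores plus the laboratory panel.
#' @param decile_variables Analytes for decile survival analysis.
#' @param alpha Backward-elimination Wald threshold.
#' @return Invisibly, a list with the main result objects (`univariate`,
#'   `deciles`, `tree`, `pruning_path`, `features`, `model`, `roc`,
#'   `cutpoint`).
#' @export
run_report <- function(cohort, out_dir, seed = 1,
                       outcome = "outcome_observed",
                       tree_predictors = NULL,
                       decile_variables = c("ph", "na", "glucose", "ggt"),
                       alpha = 0.01) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  cohort <- tibble::as_tibble(cohort)
  if (!outcome %in% names(cohort)) {
    abort(sprintf("outcome column '%s' not found", outcome),
          class = "calfsid_missing_columns")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run_log.txt")
  log_lines <- c(
    sprintf("calfsid %s report", as.character(utils::packageVersion("calfsid"))),
    sprintf("n = %d, outcome = %s, seed = %d", nrow(cohort), outcome, seed)
  )

  if (!"usi" %in% names(cohort)) cohort <- derive_acid_base(cohort)
  sirs_ready <- all(c("leukocytes", "rectal_temp", "heart_rate",
                      "resp_rate") %in% names(cohort))
  if (sirs_ready) {
    cohort <- classify_clinical_septicemia(classify_sirs(cohort))
  }
  cohort$hypothermia <- as.integer(cohort$rectal_temp < 38.5)
  write_cohort(cohort, file.path(out_dir, "cohort_derived.csv"))

  if (nrow(cohort) < 20) {
    writeLines(c(log_lines,
                 "cohort too small for modelling stages; derivation only"),
               log_path)
    abort("cohort has fewer than 20 rows; only the derived cohort was written",
          class = "calfsid_small_cohort")
  }

  univ <- univariate_odds(cohort, outcome = outcome)
  write.csv(univ, file.path(out_dir, "univariate_odds.csv"),
            row.names = FALSE)

  deciles <- purrr::map(
    setNames(decile_variables, decile_variables),
    function(v) decile_survival(cohort, v, outcome = outcome)
  )
  dec_long <- purrr::imap_dfr(deciles, function(d, v) {
    dplyr::mutate(tibble::as_tibble(d), variable = v, .before = 1)
  })
  write.csv(dec_long, file.path(out_dir, "decile_survival.csv"),
            row.names = FALSE)

  if (is.null(tree_predictors)) {
    candidates <- c(
      "abdominal_emergency", "cns_involvement", "orthopedic_problems",
      "bronchopneumonia", "navel_infection", "body_condition", "posture",
      "behavior", "suckling_reflex", "enophthalmos",
      "ph", "pco2", "hco3", "base_excess", "anion_gap", "sid_m", "sig",
      "usi", "na", "k", "cl", "glucose", "d_lactate", "l_lactate",
      "total_protein", "urea", "creatinine", "ggt", "ast", "thrombocytes",
      "leukocytes", "pcv"
    )
    tree_predictors <- intersect(candidates, names(cohort))
  }
  grown <- grow_tree(cohort, outcome = outcome,
                     predictors = tree_predictors)
  pruned <- prune_by_cv(grown, cohort, seed = seed)
  tree_json <- list(
    nodes = pruned$tree$nodes,
    pruning_path = tibble::as_tibble(pruned$path),
    seed = seed
  )
  jsonlite::write_json(tree_json, file.path(out_dir, "tree.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)

  feats <- extract_binary_predictors(pruned$tree)
  results <- list(univariate = univ, deciles = deciles,
                  tree = pruned$tree, pruning_path = pruned$path,
                  features = feats)
  if (nrow(feats) > 0) {
    cohort2 <- materialize_predictors(cohort, feats)
    full <- fit_logistic(cohort2, outcome = outcome, terms = feats$feature)
    final <- backward_eliminate(full, cohort2, alpha = alpha)
    model <- as_calf_model(final)
    write_model_json(model, file.path(out_dir, "fitted_model.json"))
    keep <- complete.cases(cohort2[final$terms])
    scores <- score_cohort(cohort2[keep, ], model, on_missing = "na")
    roc <- roc_curve(scores$probability, cohort2[[outcome]][keep])
    cut <- youden_optimal(roc)
    metrics <- dplyr::bind_cols(glance(roc), cut)
    write.csv(metrics, file.path(out_dir, "evaluation.csv"),
              row.names = FALSE)
    results$model <- final
    results$roc <- roc
    results$cutpoint <- cut
    log_lines <- c(log_lines,
                   sprintf("tree features: %s",
                           paste(feats$label, collapse = "; ")),
                   sprintf("final model terms: %s",
                           paste(final$terms, collapse = "; ")),
                   sprintf("AUC %.3f; Youden cutpoint %.3f",
                           roc$auc, cut$threshold))
  } else {
    log_lines <- c(log_lines,
                   "pruned tree is the root: no features for regression")
  }
  writeLines(log_lines, log_path)
  invisible(results)
}
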