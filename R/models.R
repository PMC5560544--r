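#' Construct a logistic prognostic model
#'
#' A `calf_model` is an intercept plus named terms, each either a raw
#' covariate (`op = "identity"`) or a binary feature defined by a threshold
#' rule on a cohort column (`op` one of `"<"`, `"<="`, `">"`, `">="` with a
#' `threshold`). The model scores a cohort through the inverse logit of its
#' linear predictor and is serializable to JSON.
#'
#' @param intercept Intercept coefficient.
#' @param terms A data frame with columns `term` (label), `variable`
#'   (cohort column), `op`, `threshold`, `estimate` and optionally `se`.
#' @param intercept_se Standard error of the intercept (optional).
#' @param metadata Named list of read-only metadata (e.g. the published
#'   classification cutpoint, AUC, sensitivity/specificity, fitted n).
#' @return An object of class `calf_model`.
#' @export
#' @examples
#' m <- calf_model(
#'   intercept = -2,
#'   terms = tibble::tibble(term = "recumbent", variable = "posture",
#'                          op = ">=", threshold = 3, estimate = 3)
#' )
#' score_cohort(tibble::tibble(posture = c(1, 3)), m)
calf_model <- function(intercept, terms, intercept_se = NA_real_,
                       metadata = list()) {
  terms <- tibble::as_tibble(terms)
  needed <- c("term", "variable", "op", "estimate")
  if (!all(needed %in% names(terms))) {
    abort(paste0("`terms` must have columns: ", paste(needed, collapse = ", ")))
  }
  if (!"threshold" %in% names(terms)) terms$threshold <- NA_real_
  if (!"se" %in% names(terms)) terms$se <- NA_real_
  ok_ops <- c("identity", "<", "<=", ">", ">=")
  if (!all(terms$op %in% ok_ops)) {
    abort(paste0("`op` must be one of: ", paste(ok_ops, collapse = ", ")))
  }
  structure(
    list(intercept = as.numeric(intercept),
         intercept_se = as.numeric(intercept_se),
         terms = terms[c("term", "variable", "op", "threshold",
                         "estimate", "se")],
         metadata = metadata),
    class = "calf_model"
  )
}

#' @export
print.calf_model <- function(x, ...) {
  cat("<calf_model> logistic scoring model\n")
  cat(sprintf("  intercept: %.3f\n", x$intercept))
  for (i in seq_len(nrow(x$terms))) {
    t <- x$terms[i, ]
    rule <- if (t$op == "identity") t$variable else
      sprintf("%s %s %s", t$variable, t$op, format(t$threshold))
    cat(sprintf("  %-28s (%s): %+.3f\n", t$term, rule, t$estimate))
  }
  if (!is.null(x$metadata$cutpoint)) {
    cat(sprintf("  classification cutpoint: %.2f\n", x$metadata$cutpoint))
  }
  invisible(x)
}

term_values <- function(data, terms) {
  missing_cols <- setdiff(unique(terms$variable), names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("cohort is missing model input column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "calfsid_missing_columns")
  }
  vals <- purrr::pmap(terms, function(term, variable, op, threshold, ...) {
    x <- data[[variable]]
    switch(op,
      identity = as.numeric(x),
      "<" = as.numeric(x < threshold),
      "<=" = as.numeric(x <= threshold),
      ">" = as.numeric(x > threshold),
      ">=" = as.numeric(x >= threshold)
    )
  })
  mat <- do.call(cbind, vals)
  colnames(mat) <- terms$term
  mat
}

#' Score a cohort with a logistic model
#'
#' Computes, for each row, the probability from the inverse logit of the
#' model's linear predictor, and (when the model metadata carries a
#' `cutpoint`) the high-risk classification `probability >= cutpoint`.
#' Binary threshold terms are computed from the raw columns; there is no
#' silent zero-imputation: rows with a missing term input either raise a
#' structured error (`on_missing = "error"`, default) naming the fields, or
#' yield `NA` probabilities (`on_missing = "na"`).
#'
#' @param data Cohort data frame.
#' @param model A [calf_model()].
#' @param on_missing `"error"` or `"na"`.
#' @return A tibble with `probability` and, if a cutpoint is available,
#'   logical `high_risk`.
#' @export
score_cohort <- function(data, model, on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  stopifnot(inherits(model, "calf_model"))
  data <- tibble::as_tibble(data)
  mat <- term_values(data, model$terms)
  any_na <- rowSums(is.na(mat)) > 0
  if (any(any_na) && on_missing == "error") {
    bad <- colnames(mat)[colSums(is.na(mat)) > 0]
    vars <- model$terms$variable[match(bad, model$terms$term)]
    abort(paste0("missing model input value(s) for: ",
                 paste(unique(vars), collapse = ", ")),
          class = "calfsid_missing_inputs")
  }
  lp <- model$intercept + as.vector(mat %*% model$terms$estimate)
  out <- tibble::tibble(probability = invlogit(lp))
  if (!is.null(model$metadata$cutpoint)) {
    out$high_risk <- out$probability >= model$metadata$cutpoint
  }
  out
}

#' @exportS3Method
tidy.calf_model <- function(x, ...) {
  est <- c(x$intercept, x$terms$estimate)
  se <- c(x$intercept_se, x$terms$se)
  z <- est / se
  tibble::tibble(
    term = c("(Intercept)", x$terms$term),
    estimate = est,
    std.error = se,
    statistic = z,
    p.value = 2 * pnorm(-abs(z)),
    odds.ratio = c(NA_real_, exp(x$terms$estimate)),
    conf.low = c(NA_real_, exp(x$terms$estimate - 1.96 * x$terms$se)),
    conf.high = c(NA_real_, exp(x$terms$estimate + 1.96 * x$terms$se))
  )
}

#' @exportS3Method
glance.calf_model <- function(x, ...) {
  md <- x$metadata
  tibble::tibble(
    n = md$n %||% NA_integer_,
    n_terms = nrow(x$terms),
    cutpoint = md$cutpoint %||% NA_real_,
    auc = md$auc %||% NA_real_,
    sensitivity = md$sensitivity %||% NA_real_,
    specificity = md$specificity %||% NA_real_,
    log_likelihood = md$log_likelihood %||% NA_real_,
    converged = md$converged %||% NA
  )
}

#' Write / read a model JSON file
#'
#' The JSON schema stores the intercept (estimate, se), the term table and
#' the metadata list, and round-trips exactly: probabilities from a
#' reloaded model equal the original's.
#'
#' @param model A [calf_model()].
#' @param path File path.
#' @return `write_model_json()` returns `path` invisibly;
#'   `read_model_json()` returns a `calf_model`.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "calf_model"))
  obj <- list(
    intercept = list(estimate = model$intercept, se = model$intercept_se),
    terms = model$terms,
    metadata = model$metadata
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  terms <- tibble::as_tibble(obj$terms)
  terms$threshold <- as.numeric(terms$threshold)
  terms$se <- as.numeric(terms$se)
  calf_model(
    intercept = obj$intercept$estimate,
    terms = terms,
    intercept_se = obj$intercept$se %||% NA_real_,
    metadata = as.list(obj$metadata)
  )
}

#' Published prognostic models for calf diarrhea mortality
#'
#' The four multivariable logistic models printed for this 1,400-calf
#' hospital population, embedded with their coefficients, standard errors,
#' optimal classification cutpoints and published performance metadata.
#' Two models predict the observed outcome (death before discharge), two
#' the expert-predicted outcome (euthanized calves judged likely survivors
#' re-allocated to the survival group):
#'
#' * `clinical_laboratory_observed` — ileus/abdominal emergency, CNS
#'   involvement, orthopedic problems, cachectic body condition, venous
#'   blood pH < 6.85; cutpoint 0.25.
#' * `laboratory_observed` — sodium >= 151 mmol/L, glucose < 3.2 mmol/L,
#'   GGT < 31 U/L, thrombocytes < 535 G/L; cutpoint 0.27.
#' * `clinical_laboratory_predicted` — nine terms incl. rectal temperature
#'   < 35.2 C and pCO2 >= 65.2 mm Hg; cutpoint 0.27.
#' * `laboratory_predicted` — glucose < 2.9 mmol/L, AST > 79 U/L;
#'   cutpoint 0.19.
#'
#' The published AUC, sensitivity, specificity and Hosmer-Lemeshow values
#' are carried as read-only metadata: they were estimated on the original
#' hospital population and are reference points for emulation, not
#' quantities this package recomputes.
#'
#' @return A named list of four [calf_model()] objects.
#' @export
#' @examples
#' reg <- published_models()
#' score_cohort(
#'   tibble::tibble(abdominal_emergency = 0, cns_involvement = 0,
#'                  orthopedic_problems = 0, body_condition = 1, ph = 7.18),
#'   reg$clinical_laboratory_observed
#' )
published_models <- function() {
  trm <- function(term, variable, op, threshold, estimate, se) {
    tibble::tibble(term = term, variable = variable, op = op,
                   threshold = threshold, estimate = estimate, se = se)
  }
  list(
    clinical_laboratory_observed = calf_model(
      intercept = -2.082, intercept_se = 0.098,
      terms = dplyr::bind_rows(
        trm("ileus_abdominal_emergency", "abdominal_emergency", ">=", 1,
            3.761, 0.550),
        trm("cns_involvement", "cns_involvement", ">=", 1, 2.978, 0.347),
        trm("orthopedic_problems", "orthopedic_problems", ">=", 1,
            2.037, 0.271),
        trm("cachectic_body_condition", "body_condition", ">=", 3,
            1.640, 0.181),
        trm("ph_below_6.85", "ph", "<", 6.85, 1.594, 0.292)
      ),
      metadata = list(
        outcome = "observed", n = 1385, cutpoint = 0.25,
        auc = 0.77, auc_ci = c(0.73, 0.80),
        sensitivity = 0.66, specificity = 0.85,
        hosmer_lemeshow = list(chisq = 2.89, df = 1, p = 0.089)
      )
    ),
    laboratory_observed = calf_model(
      intercept = -1.958, intercept_se = 0.096,
      terms = dplyr::bind_rows(
        trm("sodium_151_or_more", "na", ">=", 151, 1.462, 0.195),
        trm("glucose_below_3.2", "glucose", "<", 3.2, 1.282, 0.178),
        trm("ggt_below_31", "ggt", "<", 31, 1.075, 0.198),
        trm("thrombocytes_below_535", "thrombocytes", "<", 535,
            0.846, 0.180)
      ),
      metadata = list(
        outcome = "observed", n = 1380, cutpoint = 0.27,
        auc = 0.71, auc_ci = c(0.67, 0.75),
        sensitivity = 0.59, specificity = 0.79,
        hosmer_lemeshow = list(chisq = 6.98, df = 3, p = 0.073)
      )
    ),
    clinical_laboratory_predicted = calf_model(
      intercept = -3.151, intercept_se = 0.158,
      terms = dplyr::bind_rows(
        trm("ileus_abdominal_emergency", "abdominal_emergency", ">=", 1,
            4.200, 0.570),
        trm("cns_involvement", "cns_involvement", ">=", 1, 3.147, 0.377),
        trm("rectal_temp_below_35.2", "rectal_temp", "<", 35.2,
            1.736, 0.399),
        trm("total_protein_below_43.8", "total_protein", "<", 43.8,
            1.271, 0.260),
        trm("pneumonia", "bronchopneumonia", ">=", 1, 1.234, 0.206),
        trm("resp_rate_62_or_more", "resp_rate", ">=", 62, 1.211, 0.315),
        trm("recumbency", "posture", ">=", 3, 1.110, 0.187),
        trm("ast_152_or_more", "ast", ">=", 152, 1.060, 0.243),
        trm("pco2_65.2_or_more", "pco2", ">=", 65.2, 1.012, 0.266)
      ),
      metadata = list(
        outcome = "predicted", n = 1350, cutpoint = 0.27,
        auc = 0.84, auc_ci = c(0.81, 0.88),
        sensitivity = 0.69, specificity = 0.88,
        hosmer_lemeshow = list(chisq = 5.55, df = 4, p = 0.24)
      )
    ),
    laboratory_predicted = calf_model(
      intercept = -2.161, intercept_se = 0.104,
      terms = dplyr::bind_rows(
        trm("glucose_below_2.9", "glucose", "<", 2.9, 1.371, 0.198),
        trm("ast_above_79", "ast", ">", 79, 1.227, 0.148)
      ),
      metadata = list(
        outcome = "predicted", n = 1398, cutpoint = 0.19,
        auc = 0.69, auc_ci = c(0.65, 0.73),
        sensitivity = 0.62, specificity = 0.72,
        hosmer_lemeshow = list(chisq = 0.11, df = 1, p = 0.74)
      )
    )
  )
}

#' Profound acidemia rule
#'
#' Flags calves with jugular venous blood pH strictly below 6.85, the
#' single laboratory threshold the classification tree analysis associated
#' with observed mortality. Missing pH yields `NA` (indeterminate).
#'
#' @param data Cohort data frame with a `ph` column.
#' @return The input tibble with a logical `ph_rule_flag` column.
#' @export
apply_ph_rule <- function(data) {
  if (!"ph" %in% names(data)) {
    abort("apply_ph_rule() requires a `ph` column",
          class = "calfsid_missing_columns")
  }
  dplyr::mutate(tibble::as_tibble(data), ph_rule_flag = .data$ph < 6.85)
}
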