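#' SIRS classification from admission vitals and leukocyte count
#'
#' A calf meets the systemic inflammatory response syndrome (SIRS)
#' definition when at least two of four criteria are fulfilled: abnormal
#' leukocyte count (outside 5-12 G/L), abnormal rectal temperature (outside
#' 38.5-39.5 degrees C), tachycardia (> 120 beats/min), and tachypnea
#' (> 36 breaths/min). Reference intervals are inclusive, so a value is
#' abnormal only strictly outside them; the tachycardia and tachypnea
#' cutoffs are strict `>`.
#'
#' Missing inputs never silently count as negative: a calf with a missing
#' criterion is classified positive if the observed criteria already
#' suffice, and indeterminate (`NA`) otherwise. A negative classification
#' requires all four criteria observed.
#'
#' @param data Cohort data frame with columns `leukocytes` (G/L),
#'   `rectal_temp` (C), `heart_rate` (beats/min), `resp_rate` (breaths/min).
#' @return The input tibble with logical columns `leukocyte_abnormal`,
#'   `temp_abnormal`, `tachycardia`, `tachypnea`, integer
#'   `sirs_criteria_met` (count among observed criteria) and logical `sirs`.
#' @export
classify_sirs <- function(data) {
  required <- c("leukocytes", "rectal_temp", "heart_rate", "resp_rate")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("classify_sirs() requires column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "calfsid_missing_columns")
  }
  data <- tibble::as_tibble(data)
  crit <- cbind(
    data$leukocytes < 5 | data$leukocytes > 12,
    data$rectal_temp < 38.5 | data$rectal_temp > 39.5,
    data$heart_rate > 120,
    data$resp_rate > 36
  )
  n_met <- rowSums(crit, na.rm = TRUE)
  n_obs <- rowSums(!is.na(crit))
  dplyr::mutate(
    data,
    leukocyte_abnormal = crit[, 1],
    temp_abnormal = crit[, 2],
    tachycardia = crit[, 3],
    tachypnea = crit[, 4],
    sirs_criteria_met = as.integer(n_met),
    sirs = dplyr::case_when(
      n_met >= 2 ~ TRUE,
      n_obs == 4 ~ FALSE,
      TRUE ~ NA
    )
  )
}

#' Clinical septicemia classification
#'
#' A calf is classified as clinically septicemic when it meets the SIRS
#' definition and septicemia is clinically suspected from at least one of:
#' marked hyperemia of mucous membranes, injected episcleral vessels,
#' mucosal or subscleral bleeding, or hypopyon.
#'
#' @param data Cohort data frame; [classify_sirs()] is applied first unless
#'   a `sirs` column is already present. Suspicion flags
#'   (`hyperemia_mucosae`, `injected_scleral_vessels`, `mucosal_bleeding`,
#'   `hypopyon`) are 0/1 or logical; absent flag columns count as 0.
#' @return The input tibble with a logical `clinical_septicemia` column.
#' @export
classify_clinical_septicemia <- function(data) {
  if (!"sirs" %in% names(data)) data <- classify_sirs(data)
  flags <- c("hyperemia_mucosae", "injected_scleral_vessels",
             "mucosal_bleeding", "hypopyon")
  present <- intersect(flags, names(data))
  suspicion <- if (length(present) == 0) {
    rep(FALSE, nrow(data))
  } else {
    rowSums(as.matrix(data[present]) > 0, na.rm = TRUE) > 0
  }
  dplyr::mutate(tibble::as_tibble(data),
                clinical_septicemia = .data$sirs & suspicion)
}

#' Model-based septicemia prediction
#'
#' Scores each calf with a user-supplied logistic septicemia model (the
#' published model on age, recumbency, absent suckling reflex and presence
#' of a focal infection carries no printed coefficients here, so it must be
#' supplied as a model file; see [read_model_json()]). A calf is predicted
#' septicemic when the calculated probability is at or above `threshold`
#' (default 0.3, the operating point quoted with 69% sensitivity / 75%
#' specificity).
#'
#' @param data Cohort data frame providing the model's input columns.
#' @param model A `calf_model`, e.g. from [read_model_json()].
#' @param threshold Probability cutoff; classification uses `>=`.
#' @return The input tibble with `septicemia_probability` and logical
#'   `predicted_septicemia` columns.
#' @export
predict_septicemia <- function(data, model, threshold = 0.3) {
  scored <- score_cohort(data, model)
  dplyr::mutate(
    tibble::as_tibble(data),
    septicemia_probability = scored$probability,
    predicted_septicemia = scored$probability >= threshold
  )
}
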