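#' ROC curve with AUC and DeLong confidence interval
#'
#' Builds the full ROC curve over all distinct score thresholds (via pROC),
#' with the trapezoidal AUC — equal to the tie-corrected rank statistic —
#' and its DeLong 95% CI. Higher scores must indicate higher event risk.
#'
#' @param scores Numeric risk scores.
#' @param labels Event labels (`"died"`/`"survived"`, 0/1 or logical;
#'   event = death).
#' @return An object of class `calf_roc`: a list with `curve` (tibble of
#'   `threshold`, `sensitivity`, `specificity`), `auc`, `auc_ci`, `n_pos`,
#'   `n_neg`.
#' @export
#' @examples
#' roc <- roc_curve(c(0.9, 0.2, 0.7, 0.1), c(1, 0, 1, 0))
#' roc$auc
roc_curve <- function(scores, labels) {
  y <- as_event(labels)
  ok <- !is.na(scores) & !is.na(y)
  scores <- scores[ok]
  y <- y[ok]
  if (length(unique(y)) < 2) {
    abort("both outcome classes must be present",
          class = "calfsid_validation_error")
  }
  r <- pROC::roc(response = y, predictor = scores, levels = c(0, 1),
                 direction = "<", quiet = TRUE)
  ci <- suppressWarnings(as.numeric(pROC::ci.auc(r, method = "delong")))
  curve <- tibble::tibble(
    threshold = r$thresholds,
    sensitivity = r$sensitivities,
    specificity = r$specificities
  )
  structure(
    list(curve = dplyr::arrange(curve, .data$threshold),
         auc = as.numeric(pROC::auc(r)),
         auc_ci = c(ci[1], ci[3]),
         n_pos = sum(y == 1), n_neg = sum(y == 0)),
    class = "calf_roc"
  )
}

#' @export
print.calf_roc <- function(x, ...) {
  cat(sprintf(
    "<calf_roc> %d events / %d non-events; AUC %.3f (95%% CI %.3f-%.3f)\n",
    x$n_pos, x$n_neg, x$auc, x$auc_ci[1], x$auc_ci[2]
  ))
  invisible(x)
}

#' @exportS3Method
tidy.calf_roc <- function(x, ...) x$curve

#' @exportS3Method
glance.calf_roc <- function(x, ...) {
  tibble::tibble(auc = x$auc, auc_ci_low = x$auc_ci[1],
                 auc_ci_high = x$auc_ci[2], n_pos = x$n_pos,
                 n_neg = x$n_neg)
}

#' Youden-optimal cutpoint of a ROC curve
#'
#' The threshold maximizing `J = sensitivity + specificity - 1`; ties go to
#' the lowest threshold.
#'
#' @param roc A [roc_curve()] result.
#' @return A one-row tibble: `threshold`, `sensitivity`, `specificity`,
#'   `youden_j`.
#' @export
youden_optimal <- function(roc) {
  stopifnot(inherits(roc, "calf_roc"))
  cv <- roc$curve
  j <- cv$sensitivity + cv$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  k <- best[which.min(cv$threshold[best])]
  tibble::tibble(threshold = cv$threshold[k],
                 sensitivity = cv$sensitivity[k],
                 specificity = cv$specificity[k],
                 youden_j = j[k])
}

#' Sensitivity and specificity of a binary rule
#'
#' Sensitivity is the fraction of non-survivors flagged by the rule,
#' specificity the fraction of survivors not flagged, with exact
#' (Clopper-Pearson) binomial 95% CIs. Rows with a missing flag are
#' excluded and counted.
#'
#' @param data Cohort data frame.
#' @param flag Name of a logical/0-1 column (e.g. from [apply_ph_rule()]).
#' @param outcome Binary outcome column.
#' @return A one-row tibble with sensitivity and specificity, their CIs,
#'   the confusion counts and `n_missing`.
#' @export
binary_rule_performance <- function(data, flag,
                                    outcome = "outcome_observed") {
  y <- as_event(data[[outcome]])
  fl <- as.logical(data[[flag]])
  ok <- !is.na(fl) & !is.na(y)
  n_missing <- sum(!ok)
  y <- y[ok]
  fl <- fl[ok]
  if (sum(y == 1) == 0) {
    abort("no events among rows with an observed rule flag",
          class = "calfsid_validation_error")
  }
  tp <- sum(fl & y == 1)
  fn <- sum(!fl & y == 1)
  tn <- sum(!fl & y == 0)
  fp <- sum(fl & y == 0)
  sens_ci <- as.numeric(binom.test(tp, tp + fn)$conf.int)
  spec_ci <- as.numeric(binom.test(tn, tn + fp)$conf.int)
  tibble::tibble(
    sensitivity = tp / (tp + fn), sens_low = sens_ci[1],
    sens_high = sens_ci[2],
    specificity = tn / (tn + fp), spec_low = spec_ci[1],
    spec_high = spec_ci[2],
    tp = tp, fn = fn, tn = tn, fp = fp, n_missing = n_missing
  )
}

#' Reference intervals used to anchor decile comparisons
#'
#' The configuration table of per-analyte reference intervals used to pick
#' the reference decile. The leukocyte, rectal temperature and GGT entries
#' are the intervals quoted with the clinical definitions (GGT uses the
#' 50 U/L failure-of-passive-transfer cut-point as its lower limit); the
#' remainder are standard bovine neonatal intervals shipped as editable
#' defaults.
#'
#' @return A tibble with `variable`, `lower`, `upper`.
#' @export
reference_intervals <- function() {
  tibble::tribble(
    ~variable, ~lower, ~upper,
    "leukocytes", 5, 12,
    "rectal_temp", 38.5, 39.5,
    "ggt", 50, Inf,
    "ph", 7.35, 7.45,
    "pco2", 35, 45,
    "hco3", 24, 30,
    "base_excess", -2, 2,
    "na", 135, 148,
    "k", 3.9, 5.2,
    "cl", 95, 105,
    "glucose", 3.9, 5.6,
    "d_lactate", 0, 3.96,
    "l_lactate", 0, 2.2,
    "urea", 2, 6.6,
    "creatinine", 50, 130,
    "total_protein", 55, 75,
    "pcv", 25, 40,
    "anion_gap", 14, 26,
    "sid_m", 38, 44,
    "sig", -5, 5,
    "usi", -5, 5
  )
}

#' Decile survival analysis for one laboratory variable
#'
#' Ranks the non-missing values into ten equal-frequency bins (ties stay
#' together, so bins sharing a boundary merge and are reported), picks the
#' reference decile as the bin whose value interval has the greatest
#' overlap fraction with the analyte's reference interval (ties resolved by
#' the bin median closest to the interval midpoint), and compares every
#' other decile's survival rate with the reference decile by a Pearson
#' chi-square test (df = 1, no continuity correction). Significance is
#' flagged at the Bonferroni-adjusted level 0.05/9, displayed to two
#' figures as P <= 0.006.
#'
#' @param data Cohort data frame.
#' @param variable Column to decile.
#' @param outcome Binary outcome column.
#' @param reference_interval Length-2 numeric; defaults to the
#'   [reference_intervals()] entry for `variable`.
#' @return A `calf_decile_table`: a tibble with one row per bin (`decile`,
#'   `lower`, `upper`, `n`, `survivors`, `survival`, `p.value`,
#'   `significant`, `reference`), with the adjusted alpha and reference
#'   decile in attributes.
#' @export
decile_survival <- function(data, variable, outcome = "outcome_observed",
                            reference_interval = NULL) {
  if (is.null(reference_interval)) {
    ri <- reference_intervals()
    row <- ri[ri$variable == variable, ]
    if (nrow(row) == 0) {
      abort(sprintf(
        "no default reference interval for '%s'; supply `reference_interval`",
        variable
      ))
    }
    reference_interval <- c(row$lower, row$upper)
  }
  x <- data[[variable]]
  y <- as_event(data[[outcome]])
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]
  y <- y[ok]
  if (length(x) < 10) {
    abort("need at least 10 non-missing values",
          class = "calfsid_validation_error")
  }
  breaks <- unique(quantile(x, probs = seq(0, 1, 0.1), type = 7))
  bin <- cut(x, breaks = breaks, include.lowest = TRUE)
  tab <- tibble::tibble(bin = bin, x = x, y = y) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      lower = min(.data$x), upper = max(.data$x), n = dplyr::n(),
      survivors = sum(.data$y == 0), median_x = median(.data$x),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$lower) |>
    dplyr::mutate(decile = dplyr::row_number(),
                  survival = .data$survivors / .data$n)
  if (any(tab$n > length(x) / 10 + 1)) {
    warn("tied values forced unequal decile sizes")
  }
  lo <- reference_interval[1]
  hi <- reference_interval[2]
  width <- pmax(tab$upper - tab$lower, .Machine$double.eps)
  overlap <- pmax(0, pmin(tab$upper, hi) - pmax(tab$lower, lo)) / width
  # degenerate single-value bins: count as inside if the value is inside
  point_in <- tab$upper == tab$lower & tab$lower >= lo & tab$lower <= hi
  overlap[point_in] <- 1
  if (all(overlap == 0)) {
    abort(paste0(
      "the reference interval [", lo, ", ", hi, "] is disjoint from every ",
      "decile; check units or supply `reference_interval` explicitly"
    ), class = "calfsid_validation_error")
  }
  best <- which(overlap >= max(overlap) - 1e-12)
  mid <- if (is.finite(hi)) (lo + hi) / 2 else lo
  ref_idx <- best[which.min(abs(tab$median_x[best] - mid))]
  adj_alpha <- 0.05 / 9
  ref_s <- tab$survivors[ref_idx]
  ref_d <- tab$n[ref_idx] - ref_s
  pvals <- purrr::map_dbl(seq_len(nrow(tab)), function(i) {
    if (i == ref_idx) return(NA_real_)
    m <- matrix(c(tab$survivors[i], tab$n[i] - tab$survivors[i],
                  ref_s, ref_d), nrow = 2, byrow = TRUE)
    suppressWarnings(chisq.test(m, correct = FALSE)$p.value)
  })
  out <- dplyr::mutate(
    tab,
    p.value = pvals,
    significant = !is.na(pvals) & pvals <= adj_alpha,
    reference = dplyr::row_number() == ref_idx
  )[, c("decile", "lower", "upper", "n", "survivors", "survival",
        "p.value", "significant", "reference")]
  attr(out, "variable") <- variable
  attr(out, "reference_decile") <- tab$decile[ref_idx]
  attr(out, "adjusted_alpha") <- adj_alpha
  attr(out, "displayed_alpha") <- 0.006
  attr(out, "reference_interval") <- reference_interval
  class(out) <- c("calf_decile_table", class(out))
  out
}
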