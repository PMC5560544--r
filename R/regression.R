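#' Univariate odds ratio from a 2x2 table
#'
#' `OR = (a d) / (b c)` with the Wald interval
#' `exp(log OR +/- 1.96 * sqrt(1/a + 1/b + 1/c + 1/d))` and a Wald p-value,
#' the arithmetic behind a univariate logistic regression on one binary
#' exposure. If any cell is zero the Haldane-Anscombe correction (0.5 added
#' to every cell) is applied with a warning.
#'
#' @param a,b Events and non-events among the exposed.
#' @param c,d Events and non-events among the unexposed (reference).
#' @return A one-row tibble: `or`, `conf.low`, `conf.high`, `p.value`,
#'   `log_or`, `se`.
#' @export
#' @examples
#' odds_ratio(171, 401, 142, 686) # hypothermic vs normothermic mortality
odds_ratio <- function(a, b, c, d) {
  counts <- c(a = a, b = b, c = c, d = d)
  if (any(counts < 0)) abort("counts must be >= 0",
                             class = "calfsid_validation_error")
  if (a + b == 0 || c + d == 0) {
    abort("a contingency row has zero total",
          class = "calfsid_validation_error")
  }
  if (any(counts == 0)) {
    warn("zero cell: applying the Haldane-Anscombe 0.5 correction")
    counts <- counts + 0.5
  }
  log_or <- log(counts[["a"]]) - log(counts[["b"]]) -
    log(counts[["c"]]) + log(counts[["d"]])
  se <- sqrt(sum(1 / counts))
  tibble::tibble(
    or = exp(log_or),
    conf.low = exp(log_or - 1.96 * se),
    conf.high = exp(log_or + 1.96 * se),
    p.value = 2 * pnorm(-abs(log_or / se)),
    log_or = log_or,
    se = se
  )
}

#' Fit a logistic regression mortality model
#'
#' Maximum-likelihood logistic regression via iteratively reweighted least
#' squares ([stats::glm()] with a tight convergence tolerance), on the
#' complete cases of the model's own columns (rows missing any term are
#' dropped and the analyzed `n` reported). Standard errors come from the
#' observed information. A coefficient diverging beyond 15 on the logit
#' scale triggers a perfect-separation error naming the term.
#'
#' @param data Cohort data frame.
#' @param outcome Binary outcome column (event = death).
#' @param terms Character vector of covariate columns (binary 0/1 features
#'   or continuous covariates).
#' @return An object of class `calf_logit` wrapping the glm fit.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 500, seed = 3))
#' cohort$acidemic <- as.integer(cohort$ph < 7.0)
#' fit <- fit_logistic(cohort, terms = "acidemic")
#' tidy(fit)
fit_logistic <- function(data, outcome = "outcome_observed", terms) {
  data <- tibble::as_tibble(data)
  if (length(terms) == 0) {
    model_df <- tibble::tibble(..y.. = as_event(data[[outcome]]))
  } else {
    missing_cols <- setdiff(terms, names(data))
    if (length(missing_cols) > 0) {
      abort(paste0("missing model column(s): ",
                   paste(missing_cols, collapse = ", ")),
            class = "calfsid_missing_columns")
    }
    model_df <- data[terms]
    model_df$..y.. <- as_event(data[[outcome]])
  }
  cc <- complete.cases(model_df)
  model_df <- model_df[cc, , drop = FALSE]
  n <- nrow(model_df)
  if (length(terms) > 0 && n < 10 * length(terms)) {
    warn(sprintf("only %d complete cases for %d terms (< 10 per term)",
                 n, length(terms)))
  }
  fml <- if (length(terms) == 0) {
    ..y.. ~ 1
  } else {
    stats::reformulate(sprintf("`%s`", terms), response = "..y..")
  }
  fit <- glm(fml, family = binomial(), data = model_df,
             control = list(epsilon = 1e-10, maxit = 100))
  est <- coef(fit)
  if (length(est) > 1 && any(abs(est[-1]) > 15)) {
    bad <- names(est[-1])[abs(est[-1]) > 15]
    abort(paste0("perfect separation suspected for term(s): ",
                 paste(gsub("`", "", bad), collapse = ", ")),
          class = "calfsid_separation_error")
  }
  structure(
    list(fit = fit, outcome = outcome, terms = terms, n = n,
         log_likelihood = as.numeric(stats::logLik(fit)),
         converged = fit$converged),
    class = "calf_logit"
  )
}

#' @export
print.calf_logit <- function(x, ...) {
  cat(sprintf("<calf_logit> n = %d, logLik = %.2f, %s\n", x$n,
              x$log_likelihood,
              if (x$converged) "converged" else "NOT converged"))
  print(tidy(x))
  invisible(x)
}

#' @exportS3Method
tidy.calf_logit <- function(x, ...) {
  sm <- summary(x$fit)$coefficients
  term <- gsub("`", "", rownames(sm))
  est <- sm[, "Estimate"]
  se <- sm[, "Std. Error"]
  is_int <- term == "(Intercept)"
  tibble::tibble(
    term = term,
    estimate = unname(est),
    std.error = unname(se),
    statistic = unname(est / se),
    p.value = unname(2 * pnorm(-abs(est / se))),
    odds.ratio = ifelse(is_int, NA_real_, exp(est)),
    conf.low = ifelse(is_int, NA_real_, exp(est - 1.96 * se)),
    conf.high = ifelse(is_int, NA_real_, exp(est + 1.96 * se))
  )
}

#' @exportS3Method
glance.calf_logit <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    n_terms = length(x$terms),
    log_likelihood = x$log_likelihood,
    aic = stats::AIC(x$fit),
    converged = x$converged
  )
}

#' Convert a fitted logistic regression to a scoring model
#'
#' The resulting [calf_model()] treats every term as a raw covariate
#' (`op = "identity"`), so scoring a cohort reproduces the glm's fitted
#' probabilities exactly and the model serializes to JSON.
#'
#' @param fit A `calf_logit`.
#' @param metadata Extra metadata stored on the model.
#' @return A `calf_model`.
#' @export
as_calf_model <- function(fit, metadata = list()) {
  stopifnot(inherits(fit, "calf_logit"))
  td <- tidy(fit)
  int <- td[td$term == "(Intercept)", ]
  tt <- td[td$term != "(Intercept)", ]
  calf_model(
    intercept = int$estimate,
    intercept_se = int$std.error,
    terms = tibble::tibble(term = tt$term, variable = tt$term,
                           op = "identity", threshold = NA_real_,
                           estimate = tt$estimate, se = tt$std.error),
    metadata = c(list(n = fit$n, log_likelihood = fit$log_likelihood,
                      converged = fit$converged), metadata)
  )
}

#' Backward Wald elimination
#'
#' Starting from the fitted full model, repeatedly removes the term with
#' the largest Wald p-value while that p-value exceeds `alpha`, refitting
#' after each removal. The intercept is always retained; a term whose
#' p-value is at or below `alpha` at its evaluation step is never removed.
#'
#' @param fit A `calf_logit` full model.
#' @param data The cohort the model was fitted on.
#' @param alpha Wald retention threshold (default 0.01).
#' @return The final `calf_logit`, with the elimination order in
#'   `attr(, "eliminated")` (a tibble of term, p-value at removal, step).
#' @export
backward_eliminate <- function(fit, data, alpha = 0.01) {
  stopifnot(inherits(fit, "calf_logit"))
  terms <- fit$terms
  log <- tibble::tibble(term = character(), p.value = numeric(),
                        step = integer())
  step <- 0L
  current <- fit
  repeat {
    td <- tidy(current)
    td <- td[td$term != "(Intercept)", ]
    if (nrow(td) == 0) break
    worst <- td[which.max(td$p.value), ]
    if (worst$p.value <= alpha) break
    step <- step + 1L
    log <- dplyr::bind_rows(log, tibble::tibble(
      term = worst$term, p.value = worst$p.value, step = step
    ))
    terms <- setdiff(terms, worst$term)
    current <- fit_logistic(data, outcome = fit$outcome, terms = terms)
  }
  attr(current, "eliminated") <- log
  current
}

#' Hosmer-Lemeshow goodness of fit
#'
#' Cases are sorted by predicted risk and cut into `groups` equal-frequency
#' bins with tie-aware collapsing: all cases sharing a predicted value stay
#' in one group, and groups with identical quantile boundaries merge. The
#' statistic is `sum((O - E)^2 / E)` over the event and non-event cells of
#' the resulting g groups, referred to chi-square with `g - 2` degrees of
#' freedom.
#'
#' @param fit A `calf_logit`, or a numeric vector of predicted
#'   probabilities (then `y` must be given).
#' @param y Event indicator, only when `fit` is a probability vector.
#' @param groups Target number of groups (default 10); `g` after collapsing
#'   must be at least 3 so that df >= 1.
#' @return A one-row tibble: `chi_square`, `df`, `p.value`, `groups`.
#' @export
hosmer_lemeshow <- function(fit, y = NULL, groups = 10) {
  if (inherits(fit, "calf_logit")) {
    p <- unname(fit$fit$fitted.values)
    y <- fit$fit$y
  } else {
    p <- fit
    if (is.null(y)) abort("`y` is required when `fit` is a vector")
    y <- as_event(y)
  }
  if (groups < 3) {
    abort("`groups` must be >= 3 (df would be < 1)",
          class = "calfsid_validation_error")
  }
  # rank-based deciles; tied predicted values share a rank and therefore a
  # group, so groups collapse rather than split a tie
  distinct <- sort(unique(p))
  if (length(distinct) <= groups) {
    bin <- match(p, distinct)
  } else {
    r <- rank(p, ties.method = "min")
    bin <- ceiling(r * groups / length(p))
    # identical boundary ranks can empty a bin; relabel to consecutive
    bin <- match(bin, sort(unique(bin)))
  }
  g <- length(unique(bin))
  if (g < 3) {
    abort(sprintf(
      "only %d distinct risk group(s) after tie collapsing (need >= 3)", g
    ), class = "calfsid_validation_error")
  }
  obs1 <- tapply(y, bin, sum)
  n_g <- tapply(y, bin, length)
  exp1 <- tapply(p, bin, sum)
  keep <- !is.na(n_g)
  obs1 <- obs1[keep]; n_g <- n_g[keep]; exp1 <- exp1[keep]
  chi2 <- sum((obs1 - exp1)^2 / exp1 +
                ((n_g - obs1) - (n_g - exp1))^2 / (n_g - exp1))
  df <- g - 2
  tibble::tibble(chi_square = chi2, df = df,
                 p.value = pchisq(chi2, df, lower.tail = FALSE),
                 groups = g)
}

#' Mann-Whitney U test
#'
#' Rank-sum U statistic with midrank tie handling. The p-value is computed
#' by exact enumeration when both groups have at most 20 observations and
#' no ties are present, and by the tie-corrected normal approximation
#' otherwise. Two identical constant groups give `U = n1 n2 / 2` and
#' `p = 1`.
#'
#' @param x,y Numeric samples for the two groups.
#' @return A one-row tibble: `u`, `p.value`, `method`.
#' @export
#' @examples
#' mann_whitney(c(1, 2, 3), c(4, 5, 6))
mann_whitney <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) {
    abort("both groups must be non-empty",
          class = "calfsid_validation_error")
  }
  n1 <- length(x)
  n2 <- length(y)
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(x, y)))
  if (!ties && n1 <= 20 && n2 <= 20) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
    method <- "exact"
  } else {
    mu <- n1 * n2 / 2
    tie_tab <- table(c(x, y))
    n <- n1 + n2
    sigma2 <- n1 * n2 / 12 *
      ((n + 1) - sum(tie_tab^3 - tie_tab) / (n * (n - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      p <- 2 * pnorm(-abs(u - mu) / sqrt(sigma2))
      p <- min(1, p)
    }
    method <- "normal"
  }
  tibble::tibble(u = u, p.value = p, method = method)
}

#' Univariate odds-ratio table for clinical categories
#'
#' Reproduces the layout of a univariate risk-factor table: for every
#' categorized clinical variable, each non-reference category is compared
#' with the reference category (score 1 for 3-point scales, 0 for flags) by
#' the 2x2 odds ratio with Wald CI and p-value.
#'
#' @param data Cohort data frame (needs the clinical columns and the
#'   outcome).
#' @param outcome Binary outcome column.
#' @param variables Named list mapping variable name to its reference
#'   level; defaults to the standard clinical set present in `data`.
#' @return A tibble with variable, category, n tested, deaths, OR, CI, p.
#' @export
univariate_odds <- function(data, outcome = "outcome_observed",
                            variables = NULL) {
  y <- as_event(data[[outcome]])
  if (is.null(variables)) {
    std <- c("suckling_reflex", "behavior", "posture", "enophthalmos",
             "body_condition", "navel_infection", "abdominal_emergency",
             "cns_involvement", "orthopedic_problems", "bronchopneumonia",
             "sirs", "hypothermia", "clinical_septicemia",
             "predicted_septicemia")
    variables <- intersect(std, names(data))
  }
  purrr::map_dfr(variables, function(v) {
    x <- data[[v]]
    if (is.logical(x)) x <- as.integer(x)
    lev <- sort(unique(x[!is.na(x)]))
    ref <- lev[1]
    ok <- !is.na(x)
    c_ref <- sum(y[ok] == 1 & x[ok] == ref)
    d_ref <- sum(y[ok] == 0 & x[ok] == ref)
    purrr::map_dfr(lev, function(l) {
      n_l <- sum(x[ok] == l)
      a <- sum(y[ok] == 1 & x[ok] == l)
      if (l == ref) {
        tibble::tibble(variable = v, category = l, n = n_l, died = a,
                       or = NA_real_, conf.low = NA_real_,
                       conf.high = NA_real_, p.value = NA_real_,
                       reference = TRUE)
      } else {
        est <- odds_ratio(a, n_l - a, c_ref, d_ref)
        tibble::tibble(variable = v, category = l, n = n_l, died = a,
                       or = est$or, conf.low = est$conf.low,
                       conf.high = est$conf.high, p.value = est$p.value,
                       reference = FALSE)
      }
    })
  })
}
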