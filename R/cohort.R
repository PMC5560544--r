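#' Marginal distribution targets for the laboratory panel
#'
#' One row per analyte: the target median and quartiles (the admission
#' values of surviving calves of the reference hospital population, which
#' dominate the cohort), plausibility bounds used to winsorize sampled
#' values, and the quantile-matching family. Strongly right-skewed analytes
#' (lactates, urea, creatinine, enzyme activities, leukocyte and
#' thrombocyte counts, age) use a shifted log-normal matched exactly to the
#' three quartiles; electrolytes, blood gases, proteins and the remaining
#' hematology use a normal matched to the median and half-IQR.
#'
#' @return A tibble with columns `name`, `median`, `q25`, `q75`, `lower`,
#'   `upper`, `family`, `unit`.
#' @export
analyte_reference <- function() {
  tibble::tribble(
    ~name, ~median, ~q25, ~q75, ~lower, ~upper, ~family, ~unit,
    "ph",            7.181, 7.030, 7.314,  6.2,   7.8,  "normal",    "pH",
    "pco2",          47.4,  37.8,  55.7,   10,    150,  "normal",    "mmHg",
    "po2",           35.7,  29.9,  42.6,   5,     150,  "normal",    "mmHg",
    "na",            134.7, 129.9, 140.4,  100,   200,  "normal",    "mmol/L",
    "k",             4.8,   4.3,   6.0,    2.0,   10,   "lognormal", "mmol/L",
    "cl",            101,   96,    107,    70,    140,  "normal",    "mmol/L",
    "d_lactate",     3.9,   0.7,   9.9,    0,     25,   "lognormal", "mmol/L",
    "l_lactate",     1.6,   0.9,   3.0,    0.2,   20,   "lognormal", "mmol/L",
    "glucose",       4.4,   3.8,   5.2,    0.5,   15,   "normal",    "mmol/L",
    "total_protein", 57.7,  50.9,  65.4,   25,    100,  "normal",    "g/L",
    "albumin",       29.2,  26.7,  32.1,   12,    50,   "normal",    "g/L",
    "globulin",      28.1,  22.8,  34.8,   5,     70,   "normal",    "g/L",
    "phosphorus",    2.9,   2.4,   3.9,    0.5,   10,   "lognormal", "mmol/L",
    "urea",          12.1,  7.2,   21.0,   1,     60,   "lognormal", "mmol/L",
    "creatinine",    140,   99,    262,    40,    3000, "lognormal", "umol/L",
    "ck",            340,   173,   831,    30,    20000,"lognormal", "U/L",
    "ast",           54.8,  41.4,  77.5,   10,    2000, "lognormal", "U/L",
    "ggt",           110,   57.5,  224.5,  5,     3000, "lognormal", "U/L",
    "gldh",          7.1,   4.3,   13.2,   0.5,   500,  "lognormal", "U/L",
    "pcv",           40.9,  34.9,  46.7,   15,    70,   "normal",    "%",
    "hb",            12.8,  11.0,  14.6,   4,     25,   "normal",    "g/dL",
    "mcv",           39.8,  37.6,  41.8,   25,    60,   "normal",    "fL",
    "mch",           12.5,  11.7,  13.3,   8,     20,   "normal",    "pg",
    "mchc",          31.7,  29.6,  33.3,   22,    42,   "normal",    "g/dL",
    "rdw_cv",        21.0,  19.6,  23.0,   12,    35,   "normal",    "%",
    "leukocytes",    13.4,  9.6,   18.6,   0.5,   80,   "lognormal", "G/L",
    "thrombocytes",  920,   701,   1171,   20,    3000, "lognormal", "G/L",
    "rectal_temp",   38.707,38.100,39.314, 33,    42,   "normal",    "degC",
    "heart_rate",    110,   93.1,  126.9,  40,    260,  "normal",    "beats/min",
    "resp_rate",     32,    25.3,  38.7,   8,     120,  "normal",    "breaths/min",
    "age",           9.0,   7.0,   12.0,   1,     21,   "lognormal", "days"
  )
}

#' Category prevalences for clinical findings
#'
#' Default sampling probabilities for the 3-point clinical scores,
#' concurrent-problem flags and septicemia-suspicion signs, taken from the
#' per-category counts among tested calves of the reference population
#' (e.g. suckling reflex 187/629/512 of 1,328). Suspicion-sign rates are
#' package choices tuned to a plausible joint clinical picture.
#'
#' @return A named list: each 3-point score maps to a length-3 probability
#'   vector, each flag to a single probability.
#' @export
clinical_prevalences <- function() {
  list(
    suckling_reflex = c(187, 629, 512) / 1328,
    behavior = c(517, 450, 425) / 1392,
    posture = c(592, 383, 412) / 1387,
    enophthalmos = c(436, 664, 294) / 1394,
    body_condition = c(685, 503, 198) / 1386,
    navel_infection = c(1192, 108, 95) / 1395,
    abdominal_emergency = 32 / 1398,
    cns_involvement = 61 / 1398,
    orthopedic_problems = 70 / 1398,
    bronchopneumonia = 208 / 1392,
    hyperemia_mucosae = 0.15,
    injected_scleral_vessels = 0.12,
    mucosal_bleeding = 0.02,
    hypopyon = 0.015,
    focal_infection = 0.25
  )
}

default_missingness <- function() {
  c(
    suckling_reflex = 72 / 1400, behavior = 8 / 1400, posture = 13 / 1400,
    enophthalmos = 6 / 1400, body_condition = 14 / 1400,
    navel_infection = 5 / 1400, bronchopneumonia = 8 / 1400,
    abdominal_emergency = 2 / 1400, cns_involvement = 2 / 1400,
    orthopedic_problems = 2 / 1400,
    po2 = 5 / 1400, ast = 2 / 1400, gldh = 2 / 1400,
    pcv = 20 / 1400, hb = 20 / 1400, mcv = 20 / 1400, mch = 20 / 1400,
    mchc = 20 / 1400, rdw_cv = 36 / 1400, leukocytes = 20 / 1400,
    thrombocytes = 20 / 1400
  )
}

#' Fit a quantile-matched sampling family
#'
#' Fits the distribution used to sample one analyte from its target
#' quartiles. The shifted log-normal (`family = "lognormal"`) has three
#' parameters and matches the 25th/50th/75th percentiles exactly:
#' `shift = (q25*q75 - median^2) / (q25 + q75 - 2*median)`, then the
#' log-normal parameters from the shifted median and upper quartile. It
#' requires right-skewed targets (`q75 - median > median - q25`); for
#' symmetric or left-skewed targets it falls back to the normal family with
#' a warning. The normal family uses `mean = median` and
#' `sd = (q75 - q25) / (2 * qnorm(0.75))`, warning when the quartile gaps
#' are markedly asymmetric.
#'
#' @param median,q25,q75 Target quartiles, `q25 < median < q75`.
#' @param family `"normal"` or `"lognormal"`.
#' @return A list with the family, its parameters, and a quantile function
#'   `qfun(p)`.
#' @export
#' @examples
#' fam <- fit_quantile_family(3.9, 0.7, 9.9, family = "lognormal")
#' fam$qfun(c(0.25, 0.5, 0.75))
fit_quantile_family <- function(median, q25, q75,
                                family = c("normal", "lognormal")) {
  family <- match.arg(family)
  if (!(q25 < median && median < q75)) {
    abort("quantile targets must satisfy q25 < median < q75",
          class = "calfsid_validation_error")
  }
  z75 <- qnorm(0.75)
  if (family == "lognormal") {
    denom <- q25 + q75 - 2 * median
    if (denom <= 0) {
      warn("targets are not right-skewed; falling back to normal family")
      family <- "normal"
    } else {
      shift <- (q25 * q75 - median^2) / denom
      mu <- log(median - shift)
      sigma <- log((q75 - shift) / (median - shift)) / z75
      return(list(
        family = "lognormal", shift = shift, meanlog = mu, sdlog = sigma,
        qfun = function(p) shift + exp(mu + sigma * qnorm(p))
      ))
    }
  }
  gap_lo <- median - q25
  gap_hi <- q75 - median
  if (abs(gap_hi - gap_lo) / (q75 - q25) > 0.2) {
    warn(sprintf(
      "asymmetric quartile targets (%.3g vs %.3g) fitted with a symmetric normal",
      gap_lo, gap_hi
    ))
  }
  sd <- (q75 - q25) / (2 * z75)
  list(
    family = "normal", mean = median, sd = sd,
    qfun = function(p) qnorm(p, mean = median, sd = sd)
  )
}

#' Specify a synthetic cohort
#'
#' Bundles everything [simulate_cohort()] needs: the cohort size, analyte
#' margins, clinical prevalences, the outcome-generating logistic model,
#' per-column missingness rates, rank-copula links, the fraction of
#' non-survivor labels flipped to form the expert-review `outcome_predicted`
#' column, and the seed. The defaults are the study conditions of the
#' 1,400-calf reference population.
#'
#' @param n Number of calves.
#' @param analytes See [analyte_reference()].
#' @param prevalences See [clinical_prevalences()].
#' @param outcome_model A [calf_model()] generating the observed outcome;
#'   default is the published clinical + laboratory model.
#' @param missingness Named vector of per-column blanking probabilities.
#' @param copula A list of `list(vars = c(a, b), rho = r)` rank-correlation
#'   links introduced through a Gaussian copula. Defaults to weak (0.3)
#'   pH--pCO2 and L-lactate--creatinine links; true inter-analyte
#'   correlations are unreported and these are recorded in the sidecar.
#' @param predicted_flip_fraction Fraction of non-survivors re-labelled as
#'   survivors in `outcome_predicted` (default 57/313, the re-review rate).
#' @param seed Integer seed; the generated cohort is a pure function of the
#'   spec including this seed.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n = 1400,
                        analytes = analyte_reference(),
                        prevalences = clinical_prevalences(),
                        outcome_model = published_models()$clinical_laboratory_observed,
                        missingness = default_missingness(),
                        copula = list(
                          list(vars = c("ph", "pco2"), rho = 0.3),
                          list(vars = c("l_lactate", "creatinine"), rho = 0.3)
                        ),
                        predicted_flip_fraction = 57 / 313,
                        seed = 1L) {
  if (n < 1) abort("`n` must be >= 1", class = "calfsid_validation_error")
  stopifnot(inherits(outcome_model, "calf_model"))
  if (any(missingness < 0 | missingness > 1)) {
    abort("missingness rates must lie in [0, 1]",
          class = "calfsid_validation_error")
  }
  probs <- unlist(prevalences)
  if (any(probs < 0 | probs > 1)) {
    abort("prevalences must lie in [0, 1]",
          class = "calfsid_validation_error")
  }
  structure(
    list(n = as.integer(n), analytes = tibble::as_tibble(analytes),
         prevalences = prevalences, outcome_model = outcome_model,
         missingness = missingness, copula = copula,
         predicted_flip_fraction = predicted_flip_fraction,
         seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

# correlated uniforms: independent everywhere except the configured
# Gaussian-copula pairs
copula_uniforms <- function(n, names, copula) {
  u <- matrix(runif(n * length(names)), nrow = n,
              dimnames = list(NULL, names))
  for (link in copula) {
    a <- link$vars[1]
    b <- link$vars[2]
    if (!all(c(a, b) %in% names)) next
    z1 <- qnorm(u[, a])
    z2 <- link$rho * z1 + sqrt(1 - link$rho^2) * qnorm(u[, b])
    u[, b] <- pnorm(z2)
  }
  u
}

#' Generate a synthetic calf cohort
#'
#' Samples `spec$n` calves: laboratory analytes from their quantile-matched
#' families (winsorized to the plausibility bounds, which preserves all
#' quantiles strictly inside the bounds), clinical scores and flags from
#' their category prevalences, the derived acid-base columns computed (never
#' sampled) via [derive_acid_base()], the observed outcome drawn Bernoulli
#' from the outcome model's probability, the expert-review
#' `outcome_predicted` label formed by flipping a fraction of non-survivor
#' labels, and missingness injected last so outcome generation always sees
#' complete data. Binary model features (e.g. glucose < 3.2 mmol/L) are
#' never sampled directly; their prevalence emerges from the continuous
#' margins.
#'
#' @param spec A [cohort_spec()].
#' @return A tibble, one row per calf, with an `id` column,
#'   `outcome_observed` / `outcome_predicted` in `{"survived", "died"}`, and
#'   all measured and derived columns.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 200, seed = 42))
#' dplyr::count(cohort, outcome_observed)
simulate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n
  an <- spec$analytes

  u <- copula_uniforms(n, an$name, spec$copula)
  cols <- purrr::map(seq_len(nrow(an)), function(i) {
    fam <- fit_quantile_family(an$median[i], an$q25[i], an$q75[i],
                               family = an$family[i])
    pmin(pmax(fam$qfun(u[, an$name[i]]), an$lower[i]), an$upper[i])
  })
  names(cols) <- an$name
  data <- tibble::as_tibble(cols)
  data$age <- round(data$age)

  pv <- spec$prevalences
  sample_score <- function(p) sample.int(length(p), n, replace = TRUE, prob = p)
  data <- dplyr::mutate(
    data,
    suckling_reflex = sample_score(pv$suckling_reflex),
    behavior = sample_score(pv$behavior),
    posture = sample_score(pv$posture),
    enophthalmos = sample_score(pv$enophthalmos),
    body_condition = sample_score(pv$body_condition),
    navel_infection = sample_score(pv$navel_infection) - 1L,
    abdominal_emergency = rbinom(n, 1, pv$abdominal_emergency),
    cns_involvement = rbinom(n, 1, pv$cns_involvement),
    orthopedic_problems = rbinom(n, 1, pv$orthopedic_problems),
    bronchopneumonia = rbinom(n, 1, pv$bronchopneumonia),
    hyperemia_mucosae = rbinom(n, 1, pv$hyperemia_mucosae),
    injected_scleral_vessels = rbinom(n, 1, pv$injected_scleral_vessels),
    mucosal_bleeding = rbinom(n, 1, pv$mucosal_bleeding),
    hypopyon = rbinom(n, 1, pv$hypopyon),
    focal_infection = rbinom(n, 1, pv$focal_infection)
  )

  # rare na <= cl draws are expected under independent electrolyte margins;
  # the plausibility warning is for measured cohorts, not the generator
  data <- withCallingHandlers(
    derive_acid_base(data),
    warning = function(w) {
      if (grepl("na <= cl", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )

  p_die <- score_cohort(data, spec$outcome_model, on_missing = "error")$probability
  died <- rbinom(n, 1, p_die) == 1
  data$outcome_observed <- ifelse(died, "died", "survived")

  predicted <- data$outcome_observed
  idx_died <- which(died)
  n_flip <- round(spec$predicted_flip_fraction * length(idx_died))
  if (n_flip > 0) {
    flip <- sample(idx_died, n_flip)
    predicted[flip] <- "survived"
  }
  data$outcome_predicted <- predicted

  data <- tibble::add_column(data, id = sprintf("calf_%05d", seq_len(n)),
                             .before = 1)
  inject_missingness(data, spec$missingness)
}

#' Blank cells at per-column missingness rates
#'
#' Each eligible cell is independently set to `NA` with its column's rate.
#' The `id` and outcome columns are protected; supplying a rate for them is
#' an error. Uses the current RNG state, so calling it inside a seeded
#' pipeline is reproducible.
#'
#' @param data Cohort data frame.
#' @param rates Named vector of probabilities in `[0, 1]`; names must be
#'   columns of `data` (absent columns are ignored with a warning).
#' @return The tibble with missingness applied.
#' @export
inject_missingness <- function(data, rates) {
  protected <- c("id", "outcome_observed", "outcome_predicted")
  if (length(rates) == 0) return(tibble::as_tibble(data))
  if (any(names(rates) %in% protected)) {
    abort(paste0("missingness rates may not target protected column(s): ",
                 paste(intersect(names(rates), protected), collapse = ", ")),
          class = "calfsid_validation_error")
  }
  if (any(rates < 0 | rates > 1)) {
    abort("missingness rates must lie in [0, 1]",
          class = "calfsid_validation_error")
  }
  absent <- setdiff(names(rates), names(data))
  if (length(absent) > 0) {
    warn(paste0("missingness rates for absent column(s) ignored: ",
                paste(absent, collapse = ", ")))
  }
  data <- tibble::as_tibble(data)
  for (col in intersect(names(rates), names(data))) {
    hit <- runif(nrow(data)) < rates[[col]]
    data[[col]][hit] <- NA
  }
  data
}

cohort_units <- function(cols) {
  an <- analyte_reference()
  units <- setNames(an$unit, an$name)
  extra <- c(
    id = "", outcome_observed = "", outcome_predicted = "",
    suckling_reflex = "score", behavior = "score", posture = "score",
    enophthalmos = "score", body_condition = "score",
    navel_infection = "score", abdominal_emergency = "0/1",
    cns_involvement = "0/1", orthopedic_problems = "0/1",
    bronchopneumonia = "0/1", hyperemia_mucosae = "0/1",
    injected_scleral_vessels = "0/1", mucosal_bleeding = "0/1",
    hypopyon = "0/1", focal_infection = "0/1",
    hco3 = "mmol/L", base_excess = "mmol/L", anion_gap = "mEq/L",
    atot = "mmol/L", a_minus = "mEq/L", sid_m = "mEq/L", sig = "mEq/L",
    usi = "mEq/L", ph_temp = "pH", pco2_temp = "mmHg", po2_temp = "mmHg"
  )
  units <- c(units, extra)
  out <- units[cols]
  out[is.na(out)] <- ""
  setNames(out, cols)
}

#' Read and write cohort CSV files
#'
#' The cohort file format is a UTF-8 CSV with a header row, a units row
#' (second line), one row per calf and empty cells for missing values.
#' `write_cohort()` can also record the generating seed and spec summary in
#' a sidecar JSON. `read_cohort()` checks the units row against the
#' package's column dictionary and rejects mismatches, so files with
#' incompatible units (e.g. protein in g/dL) are not silently mixed in.
#'
#' @param data Cohort tibble.
#' @param path CSV path.
#' @param sidecar Optional list written as `<path>.json`.
#' @return `write_cohort()`: `path`, invisibly. `read_cohort()`: a tibble.
#' @export
write_cohort <- function(data, path, sidecar = NULL) {
  units <- cohort_units(names(data))
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(names(data), collapse = ","), con)
  writeLines(paste(units, collapse = ","), con)
  write.table(data, con, sep = ",", row.names = FALSE, col.names = FALSE,
              qmethod = "double", na = "")
  if (!is.null(sidecar)) {
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  header <- strsplit(readLines(path, n = 2), ",")
  cols <- header[[1]]
  units <- header[[2]]
  # trailing unit-less columns produce trailing empty fields that strsplit drops
  length(units) <- length(cols)
  units[is.na(units)] <- ""
  expected <- cohort_units(cols)
  mismatch <- which(units != expected & expected != "")
  if (length(mismatch) > 0) {
    abort(paste0(
      "units row disagrees with the column dictionary for: ",
      paste(sprintf("%s (got '%s', expected '%s')", cols[mismatch],
                    units[mismatch], expected[mismatch]), collapse = "; ")
    ), class = "calfsid_validation_error")
  }
  body <- read.csv(path, skip = 2, header = FALSE, col.names = cols,
                   na.strings = "", stringsAsFactors = FALSE)
  tibble::as_tibble(body)
}
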