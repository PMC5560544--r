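test_that("quantile families match their targets exactly", {
  # symmetric targets, normal family
  fam <- fit_quantile_family(20, 10, 30, family = "normal")
  expect_equal(fam$mean, 20)
  expect_equal(fam$qfun(0.5), 20)
  expect_equal(fam$qfun(0.75) - 20, 20 - fam$qfun(0.25), tolerance = 1e-12)
  # shifted log-normal matches all three quartiles analytically
  fam2 <- fit_quantile_family(3.9, 0.7, 9.9, family = "lognormal")
  expect_equal(fam2$qfun(c(0.25, 0.5, 0.75)), c(0.7, 3.9, 9.9),
               tolerance = 1e-9)
  # infeasible targets
  expect_error(fit_quantile_family(3.9, 3.9, 9.9),
               class = "calfsid_validation_error")
  # left-skewed targets fall back to normal (and then warn about asymmetry)
  expect_warning(
    expect_warning(f3 <- fit_quantile_family(10, 2, 11,
                                             family = "lognormal"),
                   regexp = "falling back"),
    regexp = "asymmetric"
  )
  expect_equal(f3$family, "normal")
})

test_that("sampled quartiles of the D-lactate family hit the targets within 2%", {
  fam <- fit_quantile_family(3.9, 0.7, 9.9, family = "lognormal")
  set.seed(7)
  x <- fam$qfun(runif(1e5))
  q <- unname(quantile(x, c(0.25, 0.5, 0.75)))
  expect_equal(q, c(0.7, 3.9, 9.9), tolerance = 0.02)
})

test_that("cohort generation is deterministic and byte-identical from its seed", {
  spec <- cohort_spec(n = 300, seed = 2026)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  expect_equal(nrow(a), 300)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort(a, f1)
  write_cohort(b, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("hypothermia prevalence matches the 572/1400 target within 1%", {
  co <- simulate_cohort(cohort_spec(n = 1e5, seed = 31))
  expect_equal(mean(co$rectal_temp < 38.5, na.rm = TRUE), 572 / 1400,
               tolerance = 0.025) # +/- 1 percentage point on 40.9%
})

test_that("an intercept-only outcome model yields the closed-form mortality", {
  m <- calf_model(-2.082, tibble::tibble(
    term = "cns_involvement", variable = "cns_involvement", op = ">=",
    threshold = 1, estimate = 0
  ))
  co <- simulate_cohort(cohort_spec(n = 4e4, seed = 5, outcome_model = m))
  expect_equal(mean(co$outcome_observed == "died"), plogis(-2.082),
               tolerance = 0.04)
})

test_that("derived columns always satisfy the acid-base identities", {
  co <- simulate_cohort(cohort_spec(n = 2000, seed = 8))
  expect_lt(max(abs(co$usi - co$sig - co$d_lactate - co$l_lactate)), 1e-9)
  expect_lt(max(abs(co$usi + co$sid_m - co$a_minus - co$hco3)), 1e-9)
})

test_that("the expert-review outcome flips the configured fraction of deaths", {
  co <- simulate_cohort(cohort_spec(n = 2e4, seed = 13))
  died <- co$outcome_observed == "died"
  flipped <- died & co$outcome_predicted == "survived"
  expect_equal(sum(flipped) / sum(died), 57 / 313, tolerance = 0.01)
  # never in the other direction
  expect_false(any(co$outcome_observed == "survived" &
                     co$outcome_predicted == "died"))
})

test_that("missingness injection blanks cells at the configured rates", {
  co <- simulate_cohort(cohort_spec(n = 1e4, seed = 17, missingness = NULL))
  expect_false(anyNA(co$glucose))
  out0 <- inject_missingness(co, c(glucose = 0))
  expect_identical(out0$glucose, co$glucose)
  out1 <- inject_missingness(co, c(glucose = 1))
  expect_true(all(is.na(out1$glucose)))
  set.seed(3)
  out <- inject_missingness(co, c(glucose = 0.05))
  expect_equal(mean(is.na(out$glucose)), 0.05, tolerance = 0.2)
  expect_lt(abs(mean(is.na(out$glucose)) - 0.05), 0.01)
  expect_error(inject_missingness(co, c(outcome_observed = 0.1)),
               class = "calfsid_validation_error")
  expect_error(inject_missingness(co, c(glucose = 1.2)),
               class = "calfsid_validation_error")
})

test_that("copula links induce the configured rank correlation only where set", {
  co <- simulate_cohort(cohort_spec(n = 2e4, seed = 23))
  r_linked <- cor(co$ph, co$pco2, method = "spearman")
  expect_gt(r_linked, 0.2)
  expect_lt(r_linked, 0.4)
  r_free <- cor(co$na, co$glucose, method = "spearman")
  expect_lt(abs(r_free), 0.05)
})

test_that("cohort CSV round-trips through the units-row format", {
  co <- simulate_cohort(cohort_spec(n = 50, seed = 4))
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort(co, f, sidecar = list(seed = 4, n = 50))
  back <- read_cohort(f)
  expect_equal(back$ph, co$ph, tolerance = 1e-9)
  expect_identical(back$outcome_observed, co$outcome_observed)
  expect_true(file.exists(paste0(f, ".json")))
  # corrupt the units row: the reader must refuse
  lines <- readLines(f)
  lines[2] <- gsub("g/L", "g/dL", lines[2], fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_cohort(f), regexp = "units",
               class = "calfsid_validation_error")
})

test_that("refitting the outcome model on a generated cohort recovers the coefficients", {
  truth <- published_models()$clinical_laboratory_observed
  feats <- tibble::tibble(
    feature = c("cachectic", "acidemic"),
    variable = c("body_condition", "ph"),
    op = c(">=", "<"), threshold = c(3, 6.85), label = feature
  )
  terms <- c("abdominal_emergency", "cns_involvement",
             "orthopedic_problems", "cachectic", "acidemic")
  true_beta <- c(-2.082, truth$terms$estimate)
  ok <- 0L
  for (s in 1:3) {
    co <- simulate_cohort(cohort_spec(n = 2e4, seed = 100 + s,
                                      missingness = NULL))
    co <- materialize_predictors(co, feats)
    fit <- fit_logistic(co, terms = terms)
    td <- tidy(fit)
    ok <- ok + as.integer(all(abs(td$estimate - true_beta) <
                                3 * td$std.error))
  }
  expect_gte(ok, 2L)
})
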