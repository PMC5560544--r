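test_that("odds ratios reproduce the 2x2 arithmetic with Wald intervals", {
  est <- odds_ratio(171, 401, 142, 686)
  expect_equal(round(est$or, 2), 2.06)
  expect_equal(round(est$conf.low, 2), 1.60)
  expect_equal(round(est$conf.high, 2), 2.66)
  expect_lt(est$p.value, 0.001)
  expect_equal(odds_ratio(10, 90, 10, 90)$or, 1)
  expect_equal(odds_ratio(10, 90, 10, 90)$p.value, 1)
})

test_that("odds_ratio is label-antisymmetric and guards degenerate tables", {
  a <- odds_ratio(98, 100, 103, 582)
  b <- odds_ratio(103, 582, 98, 100)
  expect_equal(b$or, 1 / a$or, tolerance = 1e-12)
  expect_equal(b$conf.low, 1 / a$conf.high, tolerance = 1e-12)
  expect_equal(b$conf.high, 1 / a$conf.low, tolerance = 1e-12)
  expect_warning(z <- odds_ratio(0, 50, 10, 40), regexp = "Haldane")
  expect_true(z$or > 0)
  expect_error(odds_ratio(0, 0, 10, 40), class = "calfsid_validation_error")
})

test_that("fit_logistic matches closed forms on saturated designs", {
  set.seed(6)
  d <- tibble::tibble(x = rbinom(400, 1, 0.4))
  d$outcome_observed <- rbinom(400, 1, plogis(-1 + 1.2 * d$x))
  fit <- fit_logistic(d, terms = "x")
  tab <- table(d$x, d$outcome_observed)
  ln_or <- log(tab["1", "1"] * tab["0", "0"] /
                 (tab["1", "0"] * tab["0", "1"]))
  td <- tidy(fit)
  expect_equal(td$estimate[td$term == "x"], ln_or, tolerance = 1e-6)
  # intercept-only model: ln(events / nonevents)
  fit0 <- fit_logistic(d, terms = character(0))
  expect_equal(coef(fit0$fit)[[1]],
               log(sum(d$outcome_observed) / sum(!d$outcome_observed)),
               tolerance = 1e-8)
  # ML property: mean fitted probability equals the event rate
  expect_equal(mean(fit$fit$fitted.values), mean(d$outcome_observed),
               tolerance = 1e-8)
})

test_that("perfect separation raises a structured error naming the term", {
  d <- tibble::tibble(x = c(rep(0, 30), rep(1, 30)),
                      outcome_observed = c(rep(0, 30), rep(1, 30)))
  expect_error(suppressWarnings(fit_logistic(d, terms = "x")),
               regexp = "x", class = "calfsid_separation_error")
})

test_that("backward elimination retains strong effects and stops at alpha", {
  set.seed(9)
  n <- 5000
  d <- tibble::tibble(strong = rbinom(n, 1, 0.3), n1 = rbinom(n, 1, 0.5),
                      n2 = rnorm(n), n3 = rbinom(n, 1, 0.2))
  d$outcome_observed <- rbinom(n, 1, plogis(-1.5 + 2 * d$strong))
  full <- fit_logistic(d, terms = c("strong", "n1", "n2", "n3"))
  final <- backward_eliminate(full, d, alpha = 0.01)
  expect_true("strong" %in% final$terms)
  elim <- attr(final, "eliminated")
  expect_true(all(elim$p.value > 0.01))
  expect_false("strong" %in% elim$term)
  # an already all-significant model returns unchanged
  refit <- fit_logistic(d, terms = "strong")
  expect_equal(backward_eliminate(refit, d, alpha = 0.01)$terms, "strong")
})

test_that("Hosmer-Lemeshow collapses tied risk groups and sets df = g - 2", {
  set.seed(12)
  n <- 900
  d <- tibble::tibble(x1 = rbinom(n, 1, 0.4), x2 = rbinom(n, 1, 0.3))
  d$outcome_observed <- rbinom(n, 1, plogis(-1 + 0.8 * d$x1 + 0.5 * d$x2))
  fit <- fit_logistic(d, terms = c("x1", "x2"))
  hl <- hosmer_lemeshow(fit)
  expect_equal(hl$groups, 4) # 2 binary predictors: 4 distinct risks
  expect_equal(hl$df, 2)
  expect_gte(hl$chi_square, 0)
  # 3 distinct predicted values: g = 3, df = 1
  p3 <- rep(c(0.1, 0.3, 0.5), each = 100)
  y3 <- rbinom(300, 1, p3)
  hl3 <- hosmer_lemeshow(p3, y = y3)
  expect_equal(hl3$groups, 3)
  expect_equal(hl3$df, 1)
  expect_error(hosmer_lemeshow(p3, y = y3, groups = 2),
               class = "calfsid_validation_error")
})

test_that("Hosmer-Lemeshow p-values are roughly uniform under a calibrated model", {
  set.seed(15)
  reject <- 0
  runs <- 60
  for (i in seq_len(runs)) {
    p <- runif(800, 0.05, 0.6)
    yy <- rbinom(800, 1, p)
    reject <- reject + (hosmer_lemeshow(p, y = yy)$p.value < 0.05)
  }
  expect_lt(reject / runs, 0.15)
  expect_gt(reject / runs, 0.0 - 1e-9)
})

test_that("Mann-Whitney matches exact enumeration and handles ties", {
  mw <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(mw$u, 0)
  expect_equal(mw$p.value, 0.1)
  # exhaustive permutation oracle for n1 = n2 = 3
  vals <- c(1.3, 2.1, 3.9, 0.4, 5.5, 2.8)
  u_stat <- function(x, y) {
    r <- rank(c(x, y))
    sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
  }
  obs <- u_stat(vals[1:3], vals[4:6])
  combs <- utils::combn(6, 3)
  us <- apply(combs, 2, function(ix) u_stat(vals[ix], vals[-ix]))
  p_exact <- mean(abs(us - 4.5) >= abs(obs - 4.5))
  expect_equal(mann_whitney(vals[1:3], vals[4:6])$p.value, p_exact,
               tolerance = 1e-9)
  # identical constant groups: U = n1 n2 / 2, p = 1
  tied <- mann_whitney(rep(2, 25), rep(2, 30))
  expect_equal(tied$u, 25 * 30 / 2)
  expect_equal(tied$p.value, 1)
  expect_error(mann_whitney(numeric(0), 1:3),
               class = "calfsid_validation_error")
})

test_that("univariate_odds reproduces per-category 2x2 comparisons", {
  set.seed(20)
  n <- 1200
  d <- tibble::tibble(
    body_condition = sample(1:3, n, replace = TRUE, prob = c(0.5, 0.35, 0.15)),
    cns_involvement = rbinom(n, 1, 0.05)
  )
  d$outcome_observed <- rbinom(
    n, 1, plogis(-1.6 + 0.6 * (d$body_condition == 3) + 2 * d$cns_involvement)
  )
  tab <- univariate_odds(d)
  row <- tab[tab$variable == "cns_involvement" & tab$category == 1, ]
  a <- sum(d$cns_involvement == 1 & d$outcome_observed == 1)
  b <- sum(d$cns_involvement == 1 & d$outcome_observed == 0)
  cc <- sum(d$cns_involvement == 0 & d$outcome_observed == 1)
  dd <- sum(d$cns_involvement == 0 & d$outcome_observed == 0)
  expect_equal(row$or, (a * dd) / (b * cc), tolerance = 1e-12)
  expect_true(tab$reference[tab$variable == "body_condition" &
                              tab$category == 1])
})
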