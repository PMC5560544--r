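# Shared fixtures, all generated in code.

# a complete single-calf record at the survivor medians of the reference
# laboratory table
survivor_median_calf <- function() {
  tibble::tibble(
    ph = 7.181, pco2 = 47.4, po2 = 35.7, na = 134.7, k = 4.8, cl = 101,
    d_lactate = 3.9, l_lactate = 1.6, glucose = 4.4, total_protein = 57.7,
    hb = 12.8, rectal_temp = 38.8
  )
}

# random valid blood-gas + chemistry panels for property tests
random_panels <- function(n, seed = 421) {
  set.seed(seed)
  tibble::tibble(
    ph = runif(n, 6.5, 7.8),
    pco2 = runif(n, 15, 90),
    na = runif(n, 120, 165),
    k = runif(n, 3, 8),
    cl = runif(n, 85, 120),
    d_lactate = runif(n, 0, 15),
    l_lactate = runif(n, 0, 10),
    total_protein = runif(n, 30, 90),
    hb = runif(n, 5, 20)
  )
}

# noiseless planted two-rule mortality data: die iff ph < 6.85 or CNS flag
planted_two_rule_data <- function(n = 2000, seed = 99) {
  set.seed(seed)
  d <- tibble::tibble(
    ph = rnorm(n, 7.15, 0.21),
    cns_involvement = rbinom(n, 1, 0.05),
    glucose = rnorm(n, 4.4, 1.0),
    urea = exp(rnorm(n, 2.5, 0.7))
  )
  d$outcome_observed <- ifelse(d$ph < 6.85 | d$cns_involvement == 1,
                               "died", "survived")
  d
}

# naive quadratic-time AUC: pairwise concordance with ties counted 1/2
pair_count_auc <- function(scores, y) {
  pos <- scores[y == 1]
  neg <- scores[y == 0]
  tot <- 0
  for (p in pos) for (q in neg) {
    tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}

# naive exhaustive best Gini split: double loop over variables and all
# candidate midpoints, first strictly-better candidate wins
naive_best_split <- function(data, y, vars, min_bucket = 7) {
  n <- length(y)
  gini <- function(e, m) if (m == 0) 0 else 2 * (e / m) * (1 - e / m)
  best <- NULL
  for (v in vars) {
    x <- data[[v]]
    xs <- sort(unique(x))
    if (length(xs) < 2) next
    for (i in seq_len(length(xs) - 1)) {
      cut <- (xs[i] + xs[i + 1]) / 2
      l <- x < cut
      nl <- sum(l)
      if (nl < min_bucket || n - nl < min_bucket) next
      dec <- gini(sum(y), n) -
        (nl * gini(sum(y[l]), nl) + (n - nl) * gini(sum(y[!l]), n - nl)) / n
      if (is.null(best) || dec > best$decrease + 1e-12) {
        best <- list(variable = v, cutpoint = cut, decrease = dec)
      }
    }
  }
  best
}
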