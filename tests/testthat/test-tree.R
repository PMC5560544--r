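test_that("gini impurity follows 2p(1-p) for binary counts", {
  expect_equal(gini_impurity(c(50, 50)), 0.5)
  expect_equal(gini_impurity(c(100, 0)), 0)
  expect_equal(round(gini_impurity(c(313, 1087)), 3), 0.347)
  expect_error(gini_impurity(c(0, 0)), class = "calfsid_validation_error")
})

test_that("best_split finds the exhaustive-search optimum on a toy set", {
  d <- tibble::tibble(x = 1:6,
                      outcome_observed = c("died", "died", rep("survived", 4)))
  bs <- best_split(d, predictors = "x", min_bucket = 1)
  expect_equal(bs$variable, "x")
  expect_equal(bs$cutpoint, 2.5)
  # perfectly separating variable yields pure children (full decrease)
  expect_equal(bs$decrease, gini_impurity(c(2, 4)), tolerance = 1e-12)
  # constant variables are never chosen
  d$z <- 1
  bs2 <- best_split(d, predictors = c("z", "x"), min_bucket = 1)
  expect_equal(bs2$variable, "x")
  # no admissible split: terminal marker
  expect_null(best_split(d, predictors = "x", min_bucket = 4))
})

test_that("best_split equals the brute-force oracle on random small datasets", {
  for (s in 1:12) {
    set.seed(1000 + s)
    n <- sample(30:200, 1)
    nv <- sample(2:4, 1)
    d <- tibble::as_tibble(setNames(
      purrr::map(seq_len(nv), ~ round(rnorm(n), sample(0:1, 1))),
      paste0("v", seq_len(nv))
    ))
    y <- rbinom(n, 1, 0.3)
    d$outcome_observed <- y
    bs <- best_split(d, predictors = paste0("v", seq_len(nv)))
    oracle <- naive_best_split(d, y, paste0("v", seq_len(nv)))
    if (is.null(oracle)) {
      expect_null(bs)
    } else {
      expect_equal(bs$variable, oracle$variable)
      expect_equal(bs$cutpoint, oracle$cutpoint, tolerance = 1e-12)
      expect_equal(bs$decrease, oracle$decrease, tolerance = 1e-12)
    }
  }
})

test_that("root splits agree with rpart's Gini choice on complete data", {
  skip_if_not_installed("rpart")
  for (s in 1:5) {
    set.seed(2000 + s)
    n <- 150
    d <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
    d$outcome_observed <- rbinom(n, 1, plogis(-1 + 1.2 * d$a - 0.8 * d$c))
    bs <- best_split(d, predictors = c("a", "b", "c"))
    rp <- rpart::rpart(
      factor(outcome_observed) ~ a + b + c, data = d, method = "class",
      parms = list(split = "gini"),
      control = rpart::rpart.control(minsplit = 20, minbucket = 7,
                                     cp = 0, maxdepth = 1, xval = 0)
    )
    expect_equal(bs$variable, rownames(rp$splits)[1])
    expect_equal(bs$cutpoint, unname(rp$splits[1, "index"]),
                 tolerance = 1e-9)
  }
})

test_that("surrogates rank by agreement above the majority baseline", {
  # a duplicate of the primary variable agrees perfectly and ranks first
  set.seed(2)
  d <- tibble::tibble(a = rnorm(100))
  d$b <- d$a
  d$c <- rnorm(100)
  s <- find_surrogates(d, "a", 0, predictors = c("b", "c"))
  expect_equal(s$variable[1], "b")
  expect_equal(s$agreement[1], 1)
  # all-missing other variables: empty surrogate list
  d2 <- tibble::tibble(a = rnorm(50), w = NA_real_)
  expect_equal(nrow(find_surrogates(d2, "a", 0, predictors = "w")), 0)
  # hand-built 8/10 agreement against a 6/10 majority baseline
  d3 <- tibble::tibble(
    a = c(1, 1, 1, 1, 2, 2, 2, 2, 2, 2),  # primary: a < 1.5, 4 left / 6 right
    b = c(1, 1, 1, 2, 1, 2, 2, 2, 2, 2)   # matches primary on 8/10
  )
  s3 <- find_surrogates(d3, "a", 1.5, predictors = "b")
  expect_equal(s3$agreement, 0.8)
  expect_equal(s3$direction, "same")
})

test_that("grow_tree recovers planted rules and respects stopping controls", {
  d <- planted_two_rule_data(n = 2000, seed = 99)
  tr <- grow_tree(d, predictors = c("ph", "cns_involvement", "glucose",
                                    "urea"))
  internal <- tr$nodes[!tr$nodes$is_leaf, ]
  expect_equal(sort(internal$variable), c("cns_involvement", "ph"))
  ph_cut <- internal$cutpoint[internal$variable == "ph"]
  obs <- sort(d$ph)
  below <- max(obs[obs < 6.85])
  above <- min(obs[obs >= 6.85])
  expect_gte(ph_cut, below)
  expect_lte(ph_cut, above)
  # pure dataset: single terminal root
  pure <- tibble::tibble(x = rnorm(100), outcome_observed = "survived")
  expect_error(grow_tree(pure, predictors = "x"), regexp = NA)
  expect_true(all(grow_tree(pure, predictors = "x")$nodes$is_leaf))
  # below min_split: terminal root
  small <- d[1:15, ]
  tr_small <- grow_tree(small, predictors = "ph")
  expect_equal(nrow(tr_small$nodes), 1)
  expect_error(grow_tree(dplyr::mutate(d, outcome_observed = "maybe"),
                         predictors = "ph"),
               class = "calfsid_validation_error")
})

test_that("every accepted split strictly decreases weighted Gini impurity", {
  co <- simulate_cohort(cohort_spec(n = 1500, seed = 77))
  tr <- grow_tree(co, predictors = c("ph", "glucose", "na", "urea",
                                     "body_condition"))
  internal <- tr$nodes[!tr$nodes$is_leaf, ]
  expect_true(all(internal$decrease > 0))
  for (i in seq_len(nrow(internal))) {
    nd <- internal[i, ]
    l <- tr$nodes[tr$nodes$id == nd$left, ]
    r <- tr$nodes[tr$nodes$id == nd$right, ]
    g_p <- gini_impurity(c(nd$n_died, nd$n_survived))
    g_c <- (l$n * gini_impurity(c(l$n_died, l$n_survived)) +
              r$n * gini_impurity(c(r$n_died, r$n_survived))) / nd$n
    expect_lt(g_c, g_p)
    expect_equal(l$n + r$n, nd$n)
  }
})

test_that("with complete data predictions are identical with or without surrogates", {
  d <- planted_two_rule_data(n = 800, seed = 5)
  tr1 <- grow_tree(d, predictors = c("ph", "cns_involvement", "glucose"))
  tr2 <- grow_tree(d, predictors = c("ph", "cns_involvement", "glucose"),
                   control = tree_control(max_surrogates = 0))
  expect_equal(predict(tr1, d), predict(tr2, d))
})

test_that("cost-complexity path is monotone and CV pruning keeps planted structure", {
  d <- planted_two_rule_data(n = 2000, seed = 42)
  tr <- grow_tree(d, predictors = c("ph", "cns_involvement", "glucose",
                                    "urea"))
  pr <- prune_by_cv(tr, d, seed = 11)
  path <- pr$path
  expect_true(all(diff(path$alpha) > 0))
  expect_true(all(diff(path$size) <= 0))
  expect_true(all(pr$tree$nodes$id %in% tr$nodes$id))
  internal <- pr$tree$nodes[!pr$tree$nodes$is_leaf, ]
  expect_equal(sort(internal$variable), c("cns_involvement", "ph"))
  # single-node tree passes through unchanged with a length-1 path
  root_only <- grow_tree(d[1:15, ], predictors = "ph")
  pr0 <- prune_by_cv(root_only, d[1:15, ], folds = 5, seed = 1)
  expect_equal(nrow(pr0$path), 1)
  expect_error(prune_by_cv(tr, d[1:5, ], folds = 10, seed = 1),
               class = "calfsid_validation_error")
})

test_that("binary predictors extract oriented to the higher-risk side", {
  d <- planted_two_rule_data(n = 2000, seed = 42)
  tr <- grow_tree(d, predictors = c("ph", "cns_involvement", "glucose",
                                    "urea"))
  pr <- prune_by_cv(tr, d, seed = 11)
  feats <- extract_binary_predictors(pr$tree)
  expect_setequal(feats$variable, c("ph", "cns_involvement"))
  expect_equal(feats$op[feats$variable == "ph"], "<")
  expect_equal(feats$op[feats$variable == "cns_involvement"], ">=")
  mat <- materialize_predictors(d, feats)
  ph_feat <- feats$feature[feats$variable == "ph"]
  expect_true(all(mat[[ph_feat]] %in% 0:1))
  # root-only tree: empty feature list
  root_only <- grow_tree(d[1:15, ], predictors = "ph")
  expect_equal(nrow(extract_binary_predictors(root_only)), 0)
})
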