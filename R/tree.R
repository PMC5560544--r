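#' Gini impurity of a node
#'
#' `1 - sum(p_k^2)` over the class proportions; for a binary node this is
#' `2 p (1 - p)`, maximal (0.5) at a 50/50 split and zero for a pure node.
#'
#' @param counts Non-negative class counts with a positive total.
#' @return The impurity.
#' @export
#' @examples
#' gini_impurity(c(313, 1087))
gini_impurity <- function(counts) {
  if (any(counts < 0) || sum(counts) <= 0) {
    abort("`counts` must be non-negative with a positive total",
          class = "calfsid_validation_error")
  }
  p <- counts / sum(counts)
  1 - sum(p^2)
}

# 1 = event (death). Accepts 0/1, logical, factor, or died/survived strings.
as_event <- function(y) {
  if (is.factor(y)) y <- as.character(y)
  if (is.character(y)) {
    ok <- y %in% c("died", "survived") | is.na(y)
    if (!all(ok)) {
      abort("outcome strings must be 'died' or 'survived'",
            class = "calfsid_validation_error")
    }
    return(as.integer(y == "died"))
  }
  y <- as.integer(as.logical(y) | y == 1)
  if (!all(y %in% c(0L, 1L) | is.na(y))) {
    abort("outcome must be binary", class = "calfsid_validation_error")
  }
  y
}

#' Growth controls for classification trees
#'
#' Defaults follow common recursive-partitioning practice: grow generously
#' (small `cp`) and let cross-validated pruning cut the tree back.
#'
#' @param min_split Minimum node size eligible for splitting.
#' @param min_bucket Minimum child size.
#' @param cp Complexity threshold on the root-scaled Gini decrease a split
#'   must achieve during growing.
#' @param max_depth Maximum depth (root = 0).
#' @param max_surrogates Surrogate splits retained per node.
#' @return A list of controls.
#' @export
tree_control <- function(min_split = 20, min_bucket = 7, cp = 0.001,
                         max_depth = 30, max_surrogates = 5) {
  list(min_split = min_split, min_bucket = min_bucket, cp = cp,
       max_depth = max_depth, max_surrogates = max_surrogates)
}

# Exhaustive Gini search over one variable. Returns NULL or
# list(cutpoint, decrease) where decrease is scaled to the full node
# (missing-value cases contribute no decrease).
scan_variable <- function(x, y, n_node, min_bucket) {
  obs <- !is.na(x)
  x <- x[obs]
  y <- y[obs]
  n <- length(x)
  if (n < 2 * min_bucket) return(NULL)
  ord <- order(x)
  x <- x[ord]
  y <- y[ord]
  cum_e <- cumsum(y)
  tot_e <- cum_e[n]
  i <- seq_len(n - 1)
  valid <- x[i] < x[i + 1] & i >= min_bucket & (n - i) >= min_bucket
  if (!any(valid)) return(NULL)
  i <- i[valid]
  nl <- i
  nr <- n - i
  el <- cum_e[i]
  er <- tot_e - el
  g_parent <- 2 * (tot_e / n) * (1 - tot_e / n)
  g_l <- 2 * (el / nl) * (1 - el / nl)
  g_r <- 2 * (er / nr) * (1 - er / nr)
  dec <- (n / n_node) * (g_parent - (nl * g_l + nr * g_r) / n)
  best <- which.max(dec)
  list(cutpoint = (x[i[best]] + x[i[best] + 1]) / 2, decrease = dec[best])
}

#' Best single Gini split of a node
#'
#' Exhaustively evaluates every midpoint between consecutive distinct
#' observed values of each candidate variable (ordinal scores are treated
#' as ordered numeric, binary flags as 0/1) and returns the split with the
#' largest weighted Gini decrease. Ties are broken deterministically:
#' earlier variable in `predictors`, then smaller cutpoint. Cases missing
#' the variable under evaluation contribute no decrease, so splits on
#' near-complete variables are favored the way surrogate-capable
#' partitioners do it.
#'
#' @param data Data frame containing the predictors and outcome.
#' @param outcome Name of the binary outcome column (event = death).
#' @param predictors Character vector of candidate numeric columns.
#' @param min_bucket Minimum child size.
#' @return A list with `variable`, `cutpoint`, `decrease`, or `NULL` when
#'   no admissible split exists (terminal marker).
#' @export
best_split <- function(data, outcome = "outcome_observed",
                       predictors = setdiff(names(data), outcome),
                       min_bucket = 7) {
  y <- as_event(data[[outcome]])
  keep <- !is.na(y)
  y <- y[keep]
  n_node <- length(y)
  best <- NULL
  for (v in predictors) {
    x <- as.numeric(data[[v]][keep])
    cand <- scan_variable(x, y, n_node, min_bucket)
    if (is.null(cand)) next
    if (is.null(best) || cand$decrease > best$decrease + 1e-12) {
      best <- list(variable = v, cutpoint = cand$cutpoint,
                   decrease = cand$decrease)
    }
  }
  best
}

# Best agreeing split of `w` with the primary left/right assignment.
# Returns NULL or list(cutpoint, direction, agreement) where direction
# "same" sends w < cutpoint left.
scan_surrogate <- function(w, primary_left) {
  obs <- !is.na(w) & !is.na(primary_left)
  w <- w[obs]
  pl <- primary_left[obs]
  n <- length(w)
  if (n < 2) return(NULL)
  ord <- order(w)
  w <- w[ord]
  pl <- pl[ord]
  cum_l <- cumsum(pl)
  tot_l <- cum_l[n]
  i <- seq_len(n - 1)
  valid <- w[i] < w[i + 1]
  if (!any(valid)) return(NULL)
  i <- i[valid]
  same <- cum_l[i] + ((n - i) - (tot_l - cum_l[i]))
  agree_same <- same / n
  agree_opp <- 1 - agree_same
  k_same <- which.max(agree_same)
  k_opp <- which.max(agree_opp)
  if (agree_same[k_same] >= agree_opp[k_opp]) {
    list(cutpoint = (w[i[k_same]] + w[i[k_same] + 1]) / 2,
         direction = "same", agreement = agree_same[k_same], n_both = n)
  } else {
    list(cutpoint = (w[i[k_opp]] + w[i[k_opp] + 1]) / 2,
         direction = "opposite", agreement = agree_opp[k_opp], n_both = n)
  }
}

#' Surrogate splits for a primary split
#'
#' For each other candidate variable, finds the split that best agrees with
#' the primary split's left/right assignment (either orientation), keeps it
#' only if its agreement exceeds the majority-direction baseline (the
#' fraction achieved by sending every case the way most cases go), and
#' orders surrogates by decreasing agreement. Cases missing the primary
#' variable are routed by the first applicable surrogate, otherwise by the
#' majority direction.
#'
#' @param data Node data.
#' @param variable,cutpoint The primary split (`variable < cutpoint` goes
#'   left).
#' @param predictors Candidate surrogate variables.
#' @param max_surrogates Maximum number retained.
#' @return A tibble with columns `variable`, `cutpoint`, `direction`,
#'   `agreement`, `n_both` (possibly zero rows).
#' @export
find_surrogates <- function(data, variable, cutpoint,
                            predictors = setdiff(names(data), variable),
                            max_surrogates = 5) {
  primary_left <- data[[variable]] < cutpoint
  obs <- !is.na(primary_left)
  empty <- tibble::tibble(variable = character(), cutpoint = numeric(),
                          direction = character(), agreement = numeric(),
                          n_both = integer())
  if (sum(obs) == 0) return(empty)
  rows <- purrr::compact(purrr::map(setdiff(predictors, variable), function(v) {
    s <- scan_surrogate(as.numeric(data[[v]]), primary_left)
    if (is.null(s)) return(NULL)
    baseline <- max(mean(primary_left[obs & !is.na(data[[v]])]),
                    1 - mean(primary_left[obs & !is.na(data[[v]])]))
    if (s$agreement <= baseline + 1e-12) return(NULL)
    tibble::tibble(variable = v, cutpoint = s$cutpoint,
                   direction = s$direction, agreement = s$agreement,
                   n_both = as.integer(s$n_both))
  }))
  if (length(rows) == 0) return(empty)
  out <- dplyr::arrange(dplyr::bind_rows(rows), dplyr::desc(.data$agreement))
  head(out, max_surrogates)
}

# TRUE = left for each row of node data, with surrogate then
# majority-direction routing for cases missing the primary variable
route_left <- function(data, variable, cutpoint, surrogates, majority_left) {
  left <- data[[variable]] < cutpoint
  miss <- is.na(left)
  if (any(miss) && nrow(surrogates) > 0) {
    for (k in seq_len(nrow(surrogates))) {
      if (!any(miss)) break
      s <- surrogates[k, ]
      w <- data[[s$variable]]
      usable <- miss & !is.na(w)
      if (!any(usable)) next
      go_left <- (w[usable] < s$cutpoint)
      if (s$direction == "opposite") go_left <- !go_left
      left[usable] <- go_left
      miss <- is.na(left)
    }
  }
  left[miss] <- majority_left
  left
}

#' Grow a classification tree for binary mortality
#'
#' Recursive Gini partitioning with surrogate-split handling of missing
#' values. Growth stops at a node when it is pure, smaller than
#' `min_split`, at `max_depth`, or when the best split's root-scaled Gini
#' decrease falls below `cp`. Every node stores its class counts, death
#' risk, and surrogate list.
#'
#' @param data Cohort data frame.
#' @param outcome Binary outcome column (event = death).
#' @param predictors Candidate split variables (numeric; ordinal scores as
#'   ordered numeric, flags as 0/1).
#' @param control See [tree_control()].
#' @return An object of class `calf_tree`.
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n = 400, seed = 7))
#' fit <- grow_tree(cohort, predictors = c("ph", "glucose", "na"))
#' fit
grow_tree <- function(data, outcome = "outcome_observed",
                      predictors = setdiff(names(data), outcome),
                      control = tree_control()) {
  y <- as_event(data[[outcome]])
  keep <- !is.na(y)
  data <- tibble::as_tibble(data)[keep, , drop = FALSE]
  y <- y[keep]
  n_root <- length(y)
  if (n_root == 0) abort("no usable outcome values")
  gini_root <- gini_impurity(c(sum(y), n_root - sum(y)))

  nodes <- list()
  surrogates <- list()
  next_id <- 1L

  build <- function(idx, depth, parent) {
    id <- next_id
    next_id <<- next_id + 1L
    yy <- y[idx]
    n <- length(idx)
    n_died <- sum(yy)
    node <- list(id = id, parent = parent, depth = depth, n = n,
                 n_died = n_died, n_survived = n - n_died,
                 predicted_risk = n_died / n, is_leaf = TRUE,
                 variable = NA_character_, cutpoint = NA_real_,
                 decrease = NA_real_, majority_left = NA,
                 left = NA_integer_, right = NA_integer_)
    surrogates[[id]] <<- NULL
    can_split <- n >= control$min_split && n_died > 0 && n_died < n &&
      depth < control$max_depth
    if (can_split) {
      nd <- data[idx, , drop = FALSE]
      nd$..y.. <- yy
      bs <- best_split(nd, outcome = "..y..", predictors = predictors,
                       min_bucket = control$min_bucket)
      ok <- !is.null(bs) &&
        (length(idx) * bs$decrease) / (n_root * gini_root) >= control$cp
      if (ok) {
        surr <- find_surrogates(nd, bs$variable, bs$cutpoint,
                                predictors = predictors,
                                max_surrogates = control$max_surrogates)
        prim_left <- nd[[bs$variable]] < bs$cutpoint
        majority_left <- mean(prim_left, na.rm = TRUE) >= 0.5
        left_mask <- route_left(nd, bs$variable, bs$cutpoint, surr,
                                majority_left)
        if (sum(left_mask) > 0 && sum(!left_mask) > 0) {
          node$is_leaf <- FALSE
          node$variable <- bs$variable
          node$cutpoint <- bs$cutpoint
          node$decrease <- bs$decrease
          node$majority_left <- majority_left
          surrogates[[id]] <<- surr
          nodes[[id]] <<- node  # placeholder before recursion
          node$left <- build(idx[left_mask], depth + 1L, id)
          node$right <- build(idx[!left_mask], depth + 1L, id)
        }
      }
    }
    nodes[[id]] <<- node
    id
  }
  build(seq_len(n_root), 0L, NA_integer_)

  node_tbl <- dplyr::bind_rows(purrr::map(nodes, tibble::as_tibble))
  structure(
    list(nodes = node_tbl, surrogates = surrogates, outcome = outcome,
         predictors = predictors, control = control, n = n_root,
         gini_root = gini_root),
    class = "calf_tree"
  )
}

#' @export
print.calf_tree <- function(x, ...) {
  cat(sprintf("<calf_tree> %d cases, %d terminal node(s)\n",
              x$n, sum(x$nodes$is_leaf)))
  show <- function(id, indent) {
    nd <- x$nodes[x$nodes$id == id, ]
    lab <- if (nd$is_leaf) "leaf" else
      sprintf("%s < %s", nd$variable, format(nd$cutpoint, digits = 4))
    cat(sprintf("%s[%d] n=%d died=%d risk=%.3f %s\n",
                strrep("  ", indent), nd$id, nd$n, nd$n_died,
                nd$predicted_risk, lab))
    if (!nd$is_leaf) {
      show(nd$left, indent + 1)
      show(nd$right, indent + 1)
    }
  }
  show(1L, 0)
  invisible(x)
}

#' @exportS3Method
tidy.calf_tree <- function(x, ...) x$nodes

# leaf id for every row
tree_leaf_ids <- function(tree, newdata) {
  nodes <- tree$nodes
  out <- integer(nrow(newdata))
  assign_node <- function(id, idx) {
    nd <- nodes[nodes$id == id, ]
    if (nd$is_leaf || is.na(nd$left) || !(nd$left %in% nodes$id)) {
      out[idx] <<- id
      return(invisible())
    }
    surr <- tree$surrogates[[id]]
    if (is.null(surr)) surr <- tibble::tibble()
    left <- route_left(newdata[idx, , drop = FALSE], nd$variable,
                       nd$cutpoint, surr, nd$majority_left)
    if (any(left)) assign_node(nd$left, idx[left])
    if (any(!left)) assign_node(nd$right, idx[!left])
  }
  assign_node(1L, seq_len(nrow(newdata)))
  out
}

#' @export
predict.calf_tree <- function(object, newdata,
                              type = c("risk", "class", "node"), ...) {
  type <- match.arg(type)
  leaf <- tree_leaf_ids(object, newdata)
  if (type == "node") return(leaf)
  nd <- object$nodes
  risk <- nd$predicted_risk[match(leaf, nd$id)]
  if (type == "risk") return(risk)
  n_died <- nd$n_died[match(leaf, nd$id)]
  n_surv <- nd$n_survived[match(leaf, nd$id)]
  ifelse(n_died > n_surv, "died", "survived")
}

# --- cost-complexity pruning ------------------------------------------------

# Weakest-link cost-complexity sequence on misclassification risk.
# Node ids are assigned sequentially from 1, so plain vectors indexed by id
# suffice. Returns list(path = tibble, keep_sets = list of node-id vectors)
# with alpha strictly increasing and sizes non-increasing; keep_sets[[k]] is
# the optimal subtree for penalties in [alpha_k, alpha_{k+1}).
cc_sequence <- function(tree) {
  nd <- tree$nodes
  m <- max(nd$id)
  risk <- rep(NA_real_, m)
  left <- right <- rep(NA_integer_, m)
  orig_leaf <- rep(TRUE, m)
  risk[nd$id] <- pmin(nd$n_died, nd$n_survived) / tree$n
  left[nd$id] <- nd$left
  right[nd$id] <- nd$right
  orig_leaf[nd$id] <- nd$is_leaf
  pruned <- rep(FALSE, m)

  cur_leaf <- function(id) orig_leaf[id] || pruned[id]
  stats <- function(id) {  # c(subtree risk, n leaves)
    if (cur_leaf(id)) return(c(risk[id], 1))
    stats(left[id]) + stats(right[id])
  }
  walk_ids <- function(internal_only) {
    out <- integer(0)
    walk <- function(id) {
      if (!internal_only) out <<- c(out, id)
      if (cur_leaf(id)) return(invisible())
      if (internal_only) out <<- c(out, id)
      walk(left[id])
      walk(right[id])
    }
    walk(1L)
    out
  }
  link_strength <- function(ids) {
    vapply(ids, function(id) {
      st <- stats(id)
      (risk[id] - st[1]) / (st[2] - 1)
    }, numeric(1))
  }

  path_alpha <- path_risk <- numeric(0)
  path_size <- integer(0)
  keep_sets <- list()
  alpha <- 0
  repeat {
    repeat {  # collapse every link no stronger than the current penalty
      ints <- walk_ids(TRUE)
      if (length(ints) == 0) break
      hit <- ints[link_strength(ints) <= alpha + 1e-12]
      if (length(hit) == 0) break
      pruned[hit] <- TRUE
    }
    st <- stats(1L)
    path_alpha <- c(path_alpha, alpha)
    path_size <- c(path_size, as.integer(st[2]))
    path_risk <- c(path_risk, st[1])
    keep_sets[[length(keep_sets) + 1]] <- walk_ids(FALSE)
    ints <- walk_ids(TRUE)
    if (length(ints) == 0) break
    alpha <- min(link_strength(ints))
  }
  list(
    path = tibble::tibble(alpha = path_alpha, size = path_size,
                          resub_error = path_risk),
    keep_sets = keep_sets
  )
}

# keep set of the optimal subtree at penalty alpha, given a cc_sequence
keep_at <- function(seqs, alpha) {
  seqs$keep_sets[[max(which(seqs$path$alpha <= alpha + 1e-12))]]
}

subset_tree <- function(tree, keep_ids) {
  nodes <- tree$nodes[tree$nodes$id %in% keep_ids, , drop = FALSE]
  nodes <- dplyr::mutate(
    nodes,
    is_leaf = .data$is_leaf | !(.data$left %in% keep_ids)
  )
  nodes$variable[nodes$is_leaf] <- NA_character_
  nodes$cutpoint[nodes$is_leaf] <- NA_real_
  nodes$left[nodes$is_leaf] <- NA_integer_
  nodes$right[nodes$is_leaf] <- NA_integer_
  out <- tree
  out$nodes <- nodes
  out$surrogates <- tree$surrogates
  out
}

#' Prune a tree by 10-fold cross-validated cost-complexity
#'
#' Computes the nested weakest-link sequence of the grown tree, estimates
#' each subtree's misclassification error by stratified k-fold
#' cross-validation (each fold regrows the tree on the training part and
#' prunes it at the geometric-mean penalty of the step), and returns the
#' subtree at the penalty with the lowest cross-validated error — not the
#' 1-SE rule; ties go to the smaller tree. Fold assignment is stratified by
#' outcome and reproducible from `seed`.
#'
#' @param tree A grown [grow_tree()] tree.
#' @param data The data it was grown on.
#' @param folds Number of CV folds.
#' @param seed Integer seed for fold assignment.
#' @param one_se Use the 1-SE rule instead of the minimum (off by default).
#' @return A list with `tree` (the pruned `calf_tree`) and `path` (a
#'   `calf_pruning_path` tibble: `alpha`, `size`, `resub_error`,
#'   `cv_error`, `cv_se`).
#' @export
prune_by_cv <- function(tree, data, folds = 10, seed = 1, one_se = FALSE) {
  stopifnot(inherits(tree, "calf_tree"))
  y <- as_event(data[[tree$outcome]])
  keep <- !is.na(y)
  data <- tibble::as_tibble(data)[keep, , drop = FALSE]
  y <- y[keep]
  n <- length(y)
  if (n < folds) abort("fewer cases than folds",
                       class = "calfsid_validation_error")
  seqs <- cc_sequence(tree)
  path <- seqs$path
  K <- nrow(path)
  if (K == 1) {
    path$cv_error <- path$resub_error
    path$cv_se <- 0
    class(path) <- c("calf_pruning_path", class(path))
    return(list(tree = subset_tree(tree, seqs$keep_sets[[1]]), path = path))
  }
  # geometric-mean evaluation penalties per step
  betas <- vapply(seq_len(K), function(k) {
    if (k == 1) return(0)
    if (k == K) return(path$alpha[K])
    sqrt(path$alpha[k] * path$alpha[k + 1])
  }, numeric(1))

  set.seed(seed)
  fold_id <- integer(n)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
  }

  wrong <- matrix(0, nrow = folds, ncol = K)
  for (f in seq_len(folds)) {
    train <- data[fold_id != f, , drop = FALSE]
    test <- data[fold_id == f, , drop = FALSE]
    ft <- grow_tree(train, outcome = tree$outcome,
                    predictors = tree$predictors, control = tree$control)
    fseq <- cc_sequence(ft)
    y_test <- y[fold_id == f]
    for (k in seq_len(K)) {
      pruned <- subset_tree(ft, keep_at(fseq, betas[k]))
      cls_pred <- predict(pruned, test, type = "class")
      wrong[f, k] <- sum((cls_pred == "died") != (y_test == 1))
    }
  }
  cv_err <- colSums(wrong) / n
  path$cv_error <- cv_err
  path$cv_se <- sqrt(cv_err * (1 - cv_err) / n)
  if (one_se) {
    thresh <- min(cv_err) + path$cv_se[which.min(cv_err)]
    best_k <- max(which(cv_err <= thresh))
  } else {
    best_k <- max(which(cv_err <= min(cv_err) + 1e-12))
  }
  class(path) <- c("calf_pruning_path", class(path))
  list(tree = subset_tree(tree, seqs$keep_sets[[best_k]]), path = path)
}

#' Binary risk features from a pruned tree
#'
#' One binary feature per distinct split, oriented so that `TRUE` is the
#' higher-risk side (e.g. `ph < 6.85`, `na >= 151`). These are the features
#' entered into subsequent logistic regression.
#'
#' @param tree A (pruned) `calf_tree`.
#' @return A tibble with `feature` (syntactic column name), `variable`,
#'   `op`, `threshold`, `label`; zero rows for a root-only tree.
#' @export
extract_binary_predictors <- function(tree) {
  nodes <- tree$nodes
  internal <- nodes[!nodes$is_leaf, , drop = FALSE]
  if (nrow(internal) == 0) {
    return(tibble::tibble(feature = character(), variable = character(),
                          op = character(), threshold = numeric(),
                          label = character()))
  }
  rows <- purrr::map(seq_len(nrow(internal)), function(i) {
    nd <- internal[i, ]
    risk_l <- nodes$predicted_risk[nodes$id == nd$left]
    risk_r <- nodes$predicted_risk[nodes$id == nd$right]
    op <- if (risk_l > risk_r) "<" else ">="
    tibble::tibble(variable = nd$variable, op = op, threshold = nd$cutpoint)
  })
  out <- dplyr::distinct(dplyr::bind_rows(rows))
  dplyr::mutate(
    out,
    label = sprintf("%s %s %s", .data$variable, .data$op,
                    format(.data$threshold, digits = 4, trim = TRUE)),
    feature = sprintf("%s_%s_%s", .data$variable,
                      ifelse(.data$op == "<", "lt", "ge"),
                      gsub("[^0-9a-zA-Z]+", "_",
                           format(.data$threshold, digits = 4, trim = TRUE))),
    .before = 1
  )[, c("feature", "variable", "op", "threshold", "label")]
}

#' Materialize tree features as binary cohort columns
#'
#' @param data Cohort data frame.
#' @param features Output of [extract_binary_predictors()].
#' @return The tibble with one 0/1 column appended per feature.
#' @export
materialize_predictors <- function(data, features) {
  data <- tibble::as_tibble(data)
  for (i in seq_len(nrow(features))) {
    f <- features[i, ]
    x <- data[[f$variable]]
    data[[f$feature]] <- as.integer(
      if (f$op == "<") x < f$threshold else x >= f$threshold
    )
  }
  data
}
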