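# Boosting induction of alternating decision trees.
#
# Each boosting round attaches one weak rule -- a (precondition, predicate)
# pair with two new prediction values -- to the growing tree. The
# precondition is an existing prediction node; the predicate is an ordinal
# threshold on one item. Candidates are scored with the weak-rule objective
#
#   Z = 2 * ( sqrt(W+(p & c) W-(p & c)) + sqrt(W+(p & !c) W-(p & !c)) )
#       + W(outside p or unevaluable)
#
# where W+/W- are current instance-weight sums by class, and the two new
# prediction values are smoothed log-odds a = 1/2 log((W+ + eps)/(W- + eps)).
# Weights then update multiplicatively under exponential loss. Instances that
# cannot evaluate a candidate predicate (missing item) belong to neither
# branch: their weight joins the constant remainder term, mirroring the
# path-truncation rule used at scoring time.

# ---------------------------------------------------------------------------
# Candidate predicates

# Threshold candidates: midpoints between adjacent observed codes, per item.
# Finite ordinal answer domains make this exhaustive.
candidate_cuts <- function(x_mat) {
  cand <- list()
  for (j in seq_len(ncol(x_mat))) {
    v <- sort(unique(x_mat[, j]))
    v <- v[!is.na(v)]
    if (length(v) >= 2L) {
      cuts <- (v[-1L] + v[-length(v)]) / 2
      cand[[length(cand) + 1L]] <- tibble(item = j, cut = cuts)
    }
  }
  if (length(cand) == 0L) {
    abort("No candidate predicate exists: every item is constant.",
          class = "adscreen_training_error")
  }
  bind_rows(cand) |> arrange(.data$item, .data$cut)
}

# 0/1 truth and evaluability matrices for all candidates (n x n_candidates).
candidate_matrices <- function(x_mat, cand) {
  n <- nrow(x_mat)
  p_mat <- matrix(0, n, nrow(cand))
  e_mat <- matrix(0, n, nrow(cand))
  for (i in seq_len(nrow(cand))) {
    code <- x_mat[, cand$item[i]]
    ok <- !is.na(code)
    e_mat[, i] <- as.numeric(ok)
    p_mat[ok, i] <- as.numeric(code[ok] <= cand$cut[i])
  }
  list(truth = p_mat, evaluable = e_mat)
}

# ---------------------------------------------------------------------------
# Weak-rule search

# Scores every (precondition, candidate) pair and returns the minimiser of Z.
# Ties (within 1e-10) break by lowest item index, then lowest cut, then
# earliest precondition in insertion order.
select_weak_rule <- function(wpos, wneg, predmat, cmat, cand, epsilon) {
  total_w <- sum(wpos) + sum(wneg)
  n_pre <- ncol(predmat)
  best <- NULL
  for (j in seq_len(n_pre)) {
    r <- predmat[, j]
    wpos_r <- wpos * r
    wneg_r <- wneg * r
    w_pt <- as.numeric(crossprod(cmat$truth, wpos_r))
    w_nt <- as.numeric(crossprod(cmat$truth, wneg_r))
    w_pe <- as.numeric(crossprod(cmat$evaluable, wpos_r))
    w_ne <- as.numeric(crossprod(cmat$evaluable, wneg_r))
    w_pf <- pmax(w_pe - w_pt, 0)
    w_nf <- pmax(w_ne - w_nt, 0)
    rest <- total_w - (w_pe + w_ne)
    z <- 2 * (sqrt(w_pt * w_nt) + sqrt(w_pf * w_nf)) + rest
    # candidates are sorted by (item, cut): first index wins ties
    idx <- which(z <= min(z) + 1e-10)[1L]
    if (is.null(best) ||
        z[idx] < best$z - 1e-10 ||
        (z[idx] <= best$z + 1e-10 &&
         (cand$item[idx] < best$item ||
          (cand$item[idx] == best$item && cand$cut[idx] < best$cut)))) {
      best <- list(precond = j, cand_idx = idx,
                   item = cand$item[idx], cut = cand$cut[idx], z = z[idx],
                   w_pt = w_pt[idx], w_nt = w_nt[idx],
                   w_pf = w_pf[idx], w_nf = w_nf[idx])
    }
  }
  best$a_true <- 0.5 * log((best$w_pt + epsilon) / (best$w_nt + epsilon))
  best$a_false <- 0.5 * log((best$w_pf + epsilon) / (best$w_nf + epsilon))
  best
}

# ---------------------------------------------------------------------------
# Training

#' Train an alternating decision tree by boosting
#'
#' Grows an ADTree for `rounds` boosting rounds. The root value is the
#' smoothed log-odds of the training class balance; each round adds one test
#' node (one weak rule: an ordinal threshold predicate attached beneath an
#' existing prediction node) together with its two prediction values, chosen
#' to minimise the weak-rule objective over all candidates. Instance weights
#' update multiplicatively under exponential loss after every round. With the
#' default `rounds = 20` the learner reproduces the published screener shape:
#' a tree over 7 items with 20 decision nodes.
#'
#' Training is deterministic given the data and settings; no randomness is
#' involved.
#'
#' @param data Data frame with encoded item columns `item_1 ... item_k`
#'   (`NA` = missing) and a class label column.
#' @param rounds Number of boosting rounds = number of test nodes (default 20).
#' @param epsilon Laplace-style smoothing constant in the log-odds prediction
#'   values (default 1).
#' @param label Name of the label column (default `"label"`).
#' @param positive Label value of the screen-positive class (default
#'   `"ASD"`); this class is oriented to the negative score side.
#' @param weights Optional positive case weights, one per row.
#' @return An object of class `adtree_fit` with components `tree` (an
#'   [adtree()]), `history` (one row per round: chosen predicate, objective
#'   value, exponential loss after the round) and training metadata.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 120), seed = 7)
#' fit <- adtree_train(cohort, rounds = 5, label = "true_label")
#' fit$tree
#' glance(fit)
#' @export
adtree_train <- function(data, rounds = 20, epsilon = 1, label = "label",
                         positive = "ASD", weights = NULL) {
  rounds <- as.integer(rounds)
  if (length(rounds) != 1L || is.na(rounds) || rounds < 1L) {
    abort("`rounds` must be a single integer >= 1.", class = "adscreen_config_error")
  }
  if (!label %in% names(data)) {
    abort(paste0("Label column '", label, "' not found in the training data."),
          class = "adscreen_input_error")
  }
  item_cols <- grep("^item_[0-9]+$", names(data), value = TRUE)
  n_items <- length(item_cols)
  if (n_items == 0L) {
    abort("Training data has no item_<k> columns.", class = "adscreen_input_error")
  }
  x_mat <- response_matrix(data, n_items)
  lab <- as.character(data[[label]])
  # score orientation: the screen-positive class sits on the negative side,
  # so it maps to y = -1 and the other class to y = +1
  y <- ifelse(lab == positive, -1, 1)
  if (length(unique(y)) < 2L) {
    abort("Training requires both classes to be present.",
          class = "adscreen_training_error")
  }
  w <- if (is.null(weights)) rep(1, nrow(x_mat)) else as.numeric(weights)
  if (length(w) != nrow(x_mat) || any(!is.finite(w)) || any(w <= 0)) {
    abort("`weights` must be positive and one per instance.",
          class = "adscreen_input_error")
  }

  cand <- candidate_cuts(x_mat)
  cmat <- candidate_matrices(x_mat, cand)

  # root: smoothed log-odds of class balance, applied to every instance
  root_value <- 0.5 * log((sum(w[y > 0]) + epsilon) / (sum(w[y < 0]) + epsilon))
  w <- w * exp(-y * root_value)

  # flat bookkeeping of the growing tree; nested afterwards
  pred_value <- root_value
  pred_parent_test <- NA_integer_
  pred_branch <- NA_character_
  test_parent_pred <- integer(0)
  test_item <- integer(0)
  test_cut <- numeric(0)
  predmat <- matrix(TRUE, nrow(x_mat), 1L)   # reach indicator per prediction node

  history <- vector("list", rounds)
  for (r in seq_len(rounds)) {
    wpos <- w * (y > 0)
    wneg <- w * (y < 0)
    rule <- select_weak_rule(wpos, wneg, predmat, cmat, cand, epsilon)

    reach <- predmat[, rule$precond]
    hit <- cmat$truth[, rule$cand_idx] > 0
    evaluable <- cmat$evaluable[, rule$cand_idx] > 0
    r_true <- reach & evaluable & hit
    r_false <- reach & evaluable & !hit

    t_id <- length(test_item) + 1L
    test_parent_pred[t_id] <- rule$precond
    test_item[t_id] <- rule$item
    test_cut[t_id] <- rule$cut
    pred_value <- c(pred_value, rule$a_true, rule$a_false)
    pred_parent_test <- c(pred_parent_test, t_id, t_id)
    pred_branch <- c(pred_branch, "true", "false")
    predmat <- cbind(predmat, r_true, r_false)

    contrib <- rule$a_true * r_true + rule$a_false * r_false
    w <- w * exp(-y * contrib)

    history[[r]] <- tibble(
      round = r, item = rule$item, cut = rule$cut,
      precondition = rule$precond, z = rule$z,
      value_true = rule$a_true, value_false = rule$a_false,
      exp_loss = sum(w))
  }

  tree <- adtree(nest_flat_tree(pred_value, pred_parent_test, pred_branch,
                                test_parent_pred, test_item, test_cut),
                 n_items = n_items)
  structure(list(
    tree = tree,
    history = bind_rows(history),
    rounds = rounds, epsilon = epsilon,
    label = label, positive = positive,
    n = nrow(x_mat),
    class_counts = table(lab)
  ), class = "adtree_fit")
}

# Rebuild the nested node structure from the flat training bookkeeping.
nest_flat_tree <- function(pred_value, pred_parent_test, pred_branch,
                           test_parent_pred, test_item, test_cut) {
  build_pred <- function(pid) {
    kids <- which(test_parent_pred == pid)
    prediction_node(pred_value[pid], lapply(kids, build_test))
  }
  build_test <- function(tid) {
    tc <- which(pred_parent_test == tid & pred_branch == "true")
    fc <- which(pred_parent_test == tid & pred_branch == "false")
    test_node(predicate_le(test_item[tid], test_cut[tid]),
              build_pred(tc), build_pred(fc))
  }
  build_pred(1L)
}

#' @export
print.adtree_fit <- function(x, ...) {
  cat(sprintf("<adtree_fit: %d rounds on %d instances (%s)>\n",
              x$rounds, x$n,
              paste(names(x$class_counts), x$class_counts,
                    sep = "=", collapse = ", ")))
  print(x$tree)
  invisible(x)
}

#' @rdname tidy.adtree
#' @export
tidy.adtree_fit <- function(x, ...) tidy(x$tree, ...)

#' One-row summary of a trained ADTree
#'
#' @param x An `adtree_fit` from [adtree_train()].
#' @param ... Unused.
#' @return A tibble with the number of boosting rounds, decision nodes,
#'   training instances, the final exponential loss, and the training-set
#'   misclassification rate.
#' @export
glance.adtree_fit <- function(x, ...) {
  tibble(rounds = x$rounds,
         n_decision_nodes = x$tree$n_decision_nodes,
         n = x$n,
         final_exp_loss = x$history$exp_loss[nrow(x$history)])
}

#' Plot the boosting loss trajectory
#'
#' @param object An `adtree_fit`.
#' @param ... Unused.
#' @return A ggplot of the exponential loss after each boosting round.
#' @export
autoplot.adtree_fit <- function(object, ...) {
  ggplot(object$history, aes(x = .data$round, y = .data$exp_loss)) +
    geom_line() + geom_point() +
    labs(x = "Boosting round", y = "Exponential loss",
         title = "ADTree training loss") +
    theme_minimal()
}

# ---------------------------------------------------------------------------
# Cross-validation

#' Build a k-fold cross-validation plan
#'
#' Folds are a seeded uniform shuffle followed by contiguous chunking; with
#' `strata` supplied (the default in [adtree_cv()]) the shuffle happens within
#' each class and fold labels are dealt cyclically across the classes, which
#' keeps fold sizes within one of each other overall *and* per class --
#' protecting small-`n` runs from single-class training splits.
#'
#' @param n Number of instances.
#' @param k Number of folds (default 10).
#' @param seed Integer RNG seed for the shuffle.
#' @param strata Optional class vector of length `n` for stratified folds.
#' @return An object of class `cv_plan`: list with `k`, `seed` and `folds`,
#'   an integer vector assigning each instance index to a fold.
#' @export
cv_plan <- function(n, k = 10, seed = 1, strata = NULL) {
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.", class = "adscreen_config_error")
  if (n < k) abort("Need at least one instance per fold.", class = "adscreen_config_error")
  folds <- integer(n)
  withr::with_seed(seed, {
    if (is.null(strata)) {
      ord <- sample.int(n)
      sizes <- rep(n %/% k, k) + (seq_len(k) <= n %% k)
      folds[ord] <- rep.int(seq_len(k), sizes)
    } else {
      strata <- as.character(strata)
      deal <- rep_len(seq_len(k), n)
      pos <- 0L
      for (cl in unique(strata)) {
        idx <- which(strata == cl)
        idx <- idx[sample.int(length(idx))]
        folds[idx] <- deal[pos + seq_along(idx)]
        pos <- pos + length(idx)
      }
    }
  })
  structure(list(k = k, seed = seed, folds = folds), class = "cv_plan")
}

#' Cross-validated evaluation of the ADTree learner
#'
#' Runs k-fold cross-validation (default 10-fold): the data are divided
#' evenly into k folds; for each rotation the tree is trained on k-1 folds
#' and scores the held-out fold, until every fold has served as test set
#' exactly once. Out-of-fold screen results are pooled into a single
#' confusion table for honest accuracy estimation. The deliverable model is
#' a separate concern: retrain on the full data with [adtree_train()] --
#' cross-validation here estimates performance, it does not produce the
#' shipped tree.
#'
#' @inheritParams adtree_train
#' @param k Number of folds (default 10).
#' @param seed Seed for the fold shuffle (default 1).
#' @param stratify Stratify folds by class (default `TRUE`).
#' @param plan Optional pre-built [cv_plan()]; overrides `k`, `seed`,
#'   `stratify`.
#' @return An object of class `adtree_cv`: `oof` (tibble of out-of-fold
#'   scores and screen results, one row per instance), `folds` (per-fold
#'   metric tibble), `pooled` (a [confusion_table()] of all out-of-fold
#'   results), and the plan/settings used.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 150), seed = 11)
#' cv <- adtree_cv(cohort, k = 5, rounds = 4, seed = 3, label = "true_label")
#' glance(cv)
#' @export
adtree_cv <- function(data, k = 10, rounds = 20, seed = 1, stratify = TRUE,
                      epsilon = 1, label = "label", positive = "ASD",
                      plan = NULL) {
  if (!label %in% names(data)) {
    abort(paste0("Label column '", label, "' not found."),
          class = "adscreen_input_error")
  }
  lab <- as.character(data[[label]])
  n <- nrow(data)
  if (is.null(plan)) {
    plan <- cv_plan(n, k = k, seed = seed,
                    strata = if (stratify) lab else NULL)
  }
  k <- plan$k
  oof <- vector("list", k)
  fold_rows <- vector("list", k)
  for (f in seq_len(k)) {
    test_idx <- which(plan$folds == f)
    train_idx <- which(plan$folds != f)
    if (length(unique(lab[train_idx])) < 2L) {
      abort(sprintf("Fold %d leaves a single-class training split.", f),
            class = "adscreen_fold_error")
    }
    fit <- adtree_train(data[train_idx, , drop = FALSE], rounds = rounds,
                        epsilon = epsilon, label = label, positive = positive)
    sc <- adtree_score(fit$tree, data[test_idx, , drop = FALSE])
    oof[[f]] <- tibble(row = test_idx, fold = f, score = sc,
                       risk_class = classify_score(sc),
                       truth = lab[test_idx])
    ct <- confusion_table_counts(lab[test_idx] == positive,
                                 classify_score(sc) == "positive")
    fold_rows[[f]] <- tibble(fold = f, n = length(test_idx),
                             tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
                             sensitivity = safe_ratio(ct$tp, ct$tp + ct$fn),
                             specificity = safe_ratio(ct$tn, ct$tn + ct$fp))
  }
  oof <- bind_rows(oof) |> arrange(.data$row)
  pooled <- confusion_table_counts(oof$truth == positive,
                                   oof$risk_class == "positive")
  structure(list(
    oof = oof,
    folds = bind_rows(fold_rows),
    pooled = confusion_table(pooled$tp, pooled$fp, pooled$fn, pooled$tn),
    plan = plan, rounds = rounds, epsilon = epsilon,
    label = label, positive = positive
  ), class = "adtree_cv")
}

safe_ratio <- function(num, den) if (den > 0) num / den else NA_real_

#' @export
print.adtree_cv <- function(x, ...) {
  cat(sprintf("<adtree_cv: %d folds, %d rounds, seed %d>\n",
              x$plan$k, x$rounds, x$plan$seed))
  print(glance(x))
  invisible(x)
}

#' Per-fold cross-validation metrics
#'
#' @param x An `adtree_cv` from [adtree_cv()].
#' @param ... Unused.
#' @return A tibble with one row per fold: confusion counts, sensitivity and
#'   specificity on the held-out fold.
#' @export
tidy.adtree_cv <- function(x, ...) x$folds

#' Pooled out-of-fold summary
#'
#' @inheritParams tidy.adtree_cv
#' @return One-row tibble with pooled out-of-fold confusion counts,
#'   sensitivity, specificity and accuracy.
#' @export
glance.adtree_cv <- function(x, ...) {
  ct <- x$pooled
  tibble(k = x$plan$k, rounds = x$rounds,
         tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
         sensitivity = sensitivity(ct),
         specificity = specificity(ct),
         accuracy = (ct$tp + ct$tn) / (ct$tp + ct$fp + ct$fn + ct$tn))
}

#' Plot per-fold cross-validation metrics
#'
#' @param object An `adtree_cv`.
#' @param ... Unused.
#' @return A ggplot showing per-fold sensitivity and specificity with the
#'   pooled values as horizontal reference lines.
#' @export
autoplot.adtree_cv <- function(object, ...) {
  long <- object$folds |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  pooled <- glance(object) |>
    tidyr::pivot_longer(c("sensitivity", "specificity"),
                        names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data$fold, y = .data$value)) +
    geom_point() +
    geom_hline(data = pooled, aes(yintercept = .data$value), linetype = 2) +
    facet_wrap(~metric) +
    scale_x_continuous(breaks = unique(long$fold)) +
    labs(x = "Fold", y = NULL, title = "Out-of-fold performance") +
    theme_minimal()
}
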