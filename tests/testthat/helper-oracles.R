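# Independent oracles used across the suite. These deliberately use a
# different algorithm from the package implementation: the scoring oracle
# enumerates every prediction node with its full ancestor-predicate list and
# filters, rather than walking paths; the weak-rule oracle scores every
# candidate with plain loops and sums.

# Flatten a tree into a list of (value, ancestors) where ancestors is a list
# of (predicate, branch) pairs that must all hold for the node to count.
enumerate_prediction_nodes <- function(tree) {
  out <- list()
  walk_pred <- function(node, ancestors) {
    out[[length(out) + 1L]] <<- list(value = node$value, ancestors = ancestors)
    for (tn in node$children) {
      walk_pred(tn$true_child, c(ancestors, list(list(p = tn$predicate, want = TRUE))))
      walk_pred(tn$false_child, c(ancestors, list(list(p = tn$predicate, want = FALSE))))
    }
  }
  walk_pred(tree$root, list())
  out
}

# TRUE/FALSE/NA evaluation of one predicate on a response vector.
oracle_eval <- function(p, x) {
  code <- x[[p$item]]
  if (is.na(code)) return(NA)
  switch(p$op,
    le = code <= p$cut,
    ge = code >= p$cut,
    `in` = code %in% p$choices)
}

# Which prediction nodes (indices into enumerate_prediction_nodes) a single
# instance collects; an unevaluable ancestor predicate excludes the node.
oracle_included <- function(nodes, x) {
  keep <- vapply(nodes, function(nd) {
    for (a in nd$ancestors) {
      hit <- oracle_eval(a$p, x)
      if (is.na(hit) || hit != a$want) return(FALSE)
    }
    TRUE
  }, logical(1))
  which(keep)
}

oracle_score <- function(tree, x) {
  nodes <- enumerate_prediction_nodes(tree)
  sum(vapply(nodes[oracle_included(nodes, x)], function(nd) nd$value,
             numeric(1)))
}

# Exhaustive min/max of the oracle score over all complete response
# combinations (n_opts[i] codes for item i).
oracle_range <- function(tree, n_opts) {
  combos <- as.matrix(expand.grid(lapply(n_opts, function(k) 0:(k - 1L)),
                                  KEEP.OUT.ATTRS = FALSE))
  scores <- apply(combos, 1L, function(x) oracle_score(tree, x))
  c(min = min(scores), max = max(scores))
}

# Random tree generator: each prediction node sprouts a test node with
# probability p_child, up to max_depth levels of test nodes.
random_tree <- function(n_items, n_opts, max_depth = 4, p_child = 0.7) {
  rand_pred_node <- function(depth) {
    children <- list()
    while (depth < max_depth && runif(1) < p_child && length(children) < 2) {
      item <- sample.int(n_items, 1L)
      cut <- sample.int(n_opts[item] - 1L, 1L) - 0.5
      children[[length(children) + 1L]] <- test_node(
        if (runif(1) < 0.8) predicate_le(item, cut)
        else predicate_in(item, sample.int(n_opts[item], 2L) - 1L),
        rand_pred_node(depth + 1L), rand_pred_node(depth + 1L))
    }
    prediction_node(runif(1, -2, 2), children)
  }
  adtree(rand_pred_node(0L), n_items = n_items)
}

random_instance <- function(n_opts, p_na = 0.15) {
  x <- vapply(n_opts, function(k) sample.int(k, 1L) - 1L, integer(1))
  x[runif(length(x)) < p_na] <- NA
  x
}

# Exhaustive weak-rule oracle: scores every (precondition, item, cut)
# candidate with plain sums and returns the minimal objective value.
oracle_weak_rule <- function(x_mat, y, w, reach_list, epsilon) {
  total_w <- sum(w)
  best <- NULL
  for (j in seq_along(reach_list)) {
    r <- reach_list[[j]]
    for (item in seq_len(ncol(x_mat))) {
      v <- sort(unique(x_mat[, item]))
      v <- v[!is.na(v)]
      if (length(v) < 2L) next
      for (cut in (v[-1L] + v[-length(v)]) / 2) {
        code <- x_mat[, item]
        t_set <- r & !is.na(code) & code <= cut
        f_set <- r & !is.na(code) & code > cut
        wpt <- sum(w[t_set & y > 0]); wnt <- sum(w[t_set & y < 0])
        wpf <- sum(w[f_set & y > 0]); wnf <- sum(w[f_set & y < 0])
        z <- 2 * (sqrt(wpt * wnt) + sqrt(wpf * wnf)) +
          (total_w - sum(w[t_set | f_set]))
        if (is.null(best) || z < best$z - 1e-10) {
          best <- list(precond = j, item = item, cut = cut, z = z)
        }
      }
    }
  }
  best
}

# Exponential loss of a tree on labelled data, computed from final scores.
oracle_exp_loss <- function(tree, data, label = "true_label",
                            positive = "ASD") {
  y <- ifelse(data[[label]] == positive, -1, 1)
  sum(exp(-y * adtree_score(tree, data)))
}

# Small labelled fixture with both classes and clean structure.
toy_training_set <- function(n = 10, n_items = 2, seed = 1, p_na = 0) {
  withr::with_seed(seed, {
    d <- tibble::tibble(.rows = n)
    for (i in seq_len(n_items)) {
      v <- sample(0:4, n, replace = TRUE)
      v[runif(n) < p_na] <- NA
      d[[paste0("item_", i)]] <- v
    }
    d$label <- sample(c("ASD", "nonASD"), n, replace = TRUE)
    # guarantee both classes
    d$label[1] <- "ASD"; d$label[2] <- "nonASD"
    d
  })
}
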