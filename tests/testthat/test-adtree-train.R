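test_that("weak-rule selection equals exhaustive candidate minimization", {
  for (seed in 1:12) {
    d <- toy_training_set(n = 10, n_items = 2, seed = seed, p_na = 0.1)
    x_mat <- as.matrix(d[paste0("item_", 1:2)])
    y <- ifelse(d$label == "ASD", -1, 1)
    w <- rep(1, 10)
    cand <- adscreen:::candidate_cuts(x_mat)
    cmat <- adscreen:::candidate_matrices(x_mat, cand)
    got <- adscreen:::select_weak_rule(w * (y > 0), w * (y < 0),
                                       matrix(TRUE, 10, 1), cmat, cand,
                                       epsilon = 1)
    want <- oracle_weak_rule(x_mat, y, w, list(rep(TRUE, 10)), epsilon = 1)
    expect_equal(got$z, want$z, tolerance = 1e-9)
  }
})

test_that("a perfectly separating feature is split at the separating cut", {
  d <- tibble::tibble(item_1 = c(0, 0, 1, 1, 3, 3, 4, 4),
                      item_2 = c(2, 3, 1, 4, 0, 2, 3, 1),
                      label = rep(c("ASD", "nonASD"), each = 4))
  fit <- adtree_train(d, rounds = 1)
  nodes <- tidy(fit)
  split <- nodes[nodes$kind == "test", ]
  expect_equal(split$item, 1L)
  expect_equal(split$cut, 2)  # midpoint between codes 1 and 3
})

test_that("ties break toward the lowest item index", {
  # item_2 duplicates item_1, so every candidate on item_2 ties one on item_1
  d <- tibble::tibble(item_1 = c(0, 0, 1, 1, 3, 3, 4, 4),
                      item_2 = c(0, 0, 1, 1, 3, 3, 4, 4),
                      label = rep(c("ASD", "nonASD"), each = 4))
  fit <- adtree_train(d, rounds = 1)
  split <- tidy(fit) |> dplyr::filter(kind == "test")
  expect_equal(split$item, 1L)
})

test_that("boosting reaches zero training error on separable data", {
  d <- tibble::tibble(item_1 = c(0, 1, 0, 1, 3, 4, 3, 4),
                      item_2 = c(1, 0, 0, 1, 4, 3, 4, 3),
                      label = rep(c("ASD", "nonASD"), each = 4))
  fit <- adtree_train(d, rounds = 3)
  sc <- adtree_score(fit$tree, d)
  expect_true(all(classify_score(sc)[d$label == "ASD"] == "positive"))
  expect_true(all(classify_score(sc)[d$label == "nonASD"] == "negative"))
})

test_that("rounds=20 produces the published tree shape: 20 decision nodes", {
  cohort <- simulate_cohort(cohort_params(n = 500), seed = 17)
  fit <- adtree_train(cohort, rounds = 20, label = "true_label")
  expect_equal(fit$tree$n_decision_nodes, 20L)
  expect_equal(fit$tree$n_items, 7L)
  # 2 new prediction values per round plus the root
  expect_equal(sum(tidy(fit)$kind == "prediction"), 41L)
})

test_that("training exponential loss is non-increasing over rounds", {
  cohort <- simulate_cohort(cohort_params(n = 300), seed = 23)
  fit <- adtree_train(cohort, rounds = 15, label = "true_label")
  expect_true(all(diff(fit$history$exp_loss) <= 1e-9))
  # bookkeeping weights equal the loss recomputed from final tree scores
  expect_equal(fit$history$exp_loss[15],
               oracle_exp_loss(fit$tree, cohort), tolerance = 1e-8)
})

test_that("the minimal one-instance-per-class problem is solved in one round", {
  d <- tibble::tibble(item_1 = c(0, 4), label = c("ASD", "nonASD"))
  fit <- adtree_train(d, rounds = 1)
  sc <- adtree_score(fit$tree, d)
  expect_lt(sc[1], 0)
  expect_gt(sc[2], 0)
})

test_that("training is deterministic: identical data gives identical trees", {
  cohort <- simulate_cohort(cohort_params(n = 250), seed = 31)
  j1 <- adtree_to_json(adtree_train(cohort, rounds = 6, label = "true_label")$tree)
  j2 <- adtree_to_json(adtree_train(cohort, rounds = 6, label = "true_label")$tree)
  expect_identical(j1, j2)
})

test_that("instances with missing items contribute to neither branch", {
  # with item_1 missing for two ASD rows, their weight must sit in the
  # remainder term; the oracle applies the same convention
  d <- toy_training_set(n = 12, n_items = 2, seed = 99, p_na = 0.3)
  x_mat <- as.matrix(d[paste0("item_", 1:2)])
  y <- ifelse(d$label == "ASD", -1, 1)
  cand <- adscreen:::candidate_cuts(x_mat)
  cmat <- adscreen:::candidate_matrices(x_mat, cand)
  got <- adscreen:::select_weak_rule(as.numeric(y > 0), as.numeric(y < 0),
                                     matrix(TRUE, 12, 1), cmat, cand, 1)
  want <- oracle_weak_rule(x_mat, y, rep(1, 12), list(rep(TRUE, 12)), 1)
  expect_equal(got$z, want$z, tolerance = 1e-9)
})

test_that("degenerate training inputs are rejected", {
  d <- tibble::tibble(item_1 = 0:3, label = rep("ASD", 4))
  expect_error(adtree_train(d), class = "adscreen_training_error")
  d2 <- tibble::tibble(item_1 = c(2, 2, 2, 2),
                       label = c("ASD", "ASD", "nonASD", "nonASD"))
  expect_error(adtree_train(d2), class = "adscreen_training_error")
  d3 <- toy_training_set()
  expect_error(adtree_train(d3, rounds = 0), class = "adscreen_config_error")
})
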