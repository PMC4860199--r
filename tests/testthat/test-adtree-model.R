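test_that("degenerate trees score by their explicit paths", {
  lone <- adtree(prediction_node(1.75), n_items = 3)
  expect_equal(adtree_score(lone, c(0, 0, 0)), 1.75)
  expect_equal(lone$n_decision_nodes, 0L)

  one_split <- adtree(prediction_node(0, list(
    test_node(predicate_le(2, 0.5),
              prediction_node(0.9), prediction_node(-0.9)))), n_items = 3)
  expect_equal(adtree_score(one_split, c(0, 2, 0)), -0.9)  # predicate fails
  expect_equal(adtree_score(one_split, c(0, 0, 0)), 0.9)
  expect_equal(adtree_score(one_split, c(0, NA, 0)), 0)    # path truncated
})

test_that("path-sum scoring matches the brute-force enumeration oracle", {
  n_opts <- c(5, 5, 5, 5, 5, 5, 4)
  withr::with_seed(101, {
    for (rep in 1:25) {
      tree <- random_tree(7, n_opts)
      for (k in 1:5) {
        x <- random_instance(n_opts)
        expect_equal(adtree_score(tree, x), oracle_score(tree, x),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("vectorised batch scoring agrees with single-instance scoring", {
  n_opts <- c(5, 5, 5, 5, 5, 5, 4)
  withr::with_seed(202, {
    tree <- random_tree(7, n_opts, max_depth = 5)
    x <- do.call(rbind, lapply(1:40, function(i) random_instance(n_opts)))
    batch <- adtree_score(tree, x)
    single <- vapply(seq_len(nrow(x)),
                     function(i) adtree_score(tree, x[i, ]), numeric(1))
    expect_equal(batch, single, tolerance = 1e-12)
  })
})

test_that("negating every prediction value negates scores and flips classes", {
  negate_tree <- function(node) {
    node$value <- -node$value
    node$children <- lapply(node$children, function(tn) {
      tn$true_child <- negate_tree(tn$true_child)
      tn$false_child <- negate_tree(tn$false_child)
      tn
    })
    node
  }
  n_opts <- rep(4, 5)
  withr::with_seed(33, {
    tree <- random_tree(5, n_opts)
    flipped <- adtree(negate_tree(tree$root), n_items = 5)
    for (k in 1:20) {
      x <- random_instance(n_opts)
      s <- adtree_score(tree, x)
      expect_equal(adtree_score(flipped, x), -s, tolerance = 1e-12)
      if (s != 0) {
        expect_true(classify_score(s) != classify_score(-s))
      }
    }
  })
})

test_that("masking an item only ever removes prediction-node contributions", {
  n_opts <- rep(5, 6)
  withr::with_seed(77, {
    for (rep in 1:10) {
      tree <- random_tree(6, n_opts)
      nodes <- enumerate_prediction_nodes(tree)
      x <- random_instance(n_opts, p_na = 0)
      inc_full <- oracle_included(nodes, x)
      for (item in 1:6) {
        x_masked <- x
        x_masked[item] <- NA
        inc_masked <- oracle_included(nodes, x_masked)
        expect_true(all(inc_masked %in% inc_full))
        expect_equal(adtree_score(tree, x_masked),
                     sum(vapply(nodes[inc_masked], function(nd) nd$value,
                                numeric(1))),
                     tolerance = 1e-9)
      }
    }
  })
})

test_that("classification is sign-based with a documented zero tie rule", {
  expect_equal(as.character(classify_score(-9.28)), "positive")
  expect_equal(as.character(classify_score(6.43)), "negative")
  expect_equal(as.character(classify_score(0)), "positive")
  expect_equal(as.character(classify_score(0, tie = "negative")), "negative")
  expect_error(classify_score(NaN), class = "adscreen_input_error")
  expect_error(classify_score(Inf), class = "adscreen_input_error")
})

test_that("confidence is the score magnitude, symmetric about the cutoff", {
  expect_equal(score_confidence(-9.28), 9.28)
  expect_equal(score_confidence(0), 0)
  s <- c(-3.2, -0.01, 0.5, 7)
  expect_equal(score_confidence(s), score_confidence(-s))
  expect_error(score_confidence(NA_real_), class = "adscreen_input_error")
})

test_that("score_range enumerates the exact attainable extremes", {
  lone <- adtree(prediction_node(2.5), n_items = 2)
  expect_equal(score_range(lone, c(3, 3)), tibble::tibble(min = 2.5, max = 2.5))

  # independent enumeration oracle on 7-item trees (3^7 combinations)
  n_opts <- rep(3, 7)
  withr::with_seed(55, {
    for (rep in 1:5) {
      tree <- random_tree(7, n_opts, max_depth = 3)
      got <- score_range(tree, n_opts)
      want <- oracle_range(tree, n_opts)
      expect_equal(got$min, unname(want["min"]), tolerance = 1e-9)
      expect_equal(got$max, unname(want["max"]), tolerance = 1e-9)
      # both endpoints are attained by an actual complete response
      combos <- as.matrix(expand.grid(lapply(n_opts, function(k) 0:(k - 1))))
      scores <- adtree_score(tree, unname(combos))
      expect_true(any(abs(scores - got$min) < 1e-12))
      expect_true(any(abs(scores - got$max) < 1e-12))
    }
  })
})

test_that("a learner-produced tree spans both score signs", {
  cohort <- simulate_cohort(cohort_params(n = 400), seed = 5)
  fit <- adtree_train(cohort, rounds = 8, label = "true_label")
  rng <- score_range(fit$tree, mara_instrument())
  expect_lt(rng$min, 0)
  expect_gt(rng$max, 0)
})

test_that("JSON serialization round-trips bit-identically", {
  n_opts <- c(5, 5, 5, 5, 5, 5, 4)
  withr::with_seed(909, {
    tree <- random_tree(7, n_opts, max_depth = 4)
    doc <- adtree_to_json(tree)
    back <- adtree_from_json(doc)
    expect_identical(adtree_to_json(back), doc)
    for (k in 1:100) {
      x <- random_instance(n_opts)
      expect_identical(adtree_score(back, x), adtree_score(tree, x))
    }
  })
  # via file
  tf <- withr::local_tempfile(fileext = ".json")
  adtree_to_json(tree, tf, provenance = list(seed = 1))
  expect_identical(adtree_to_json(adtree_from_json(tf)), adtree_to_json(tree))
})

test_that("malformed tree documents are rejected with the offending path", {
  expect_error(adtree_from_json(""), class = "adscreen_parse_error")
  expect_error(adtree_from_json("{}"), class = "adscreen_parse_error")
  missing_false <- '
  {"n_items": 2, "root": {"kind": "prediction", "value": 0, "children": [
    {"kind": "test", "predicate": {"item": 1, "op": "le", "cut": 0.5},
     "children": [{"kind": "prediction", "value": 1, "children": []}]}]}}'
  err <- expect_error(adtree_from_json(missing_false),
                      class = "adscreen_parse_error")
  expect_match(conditionMessage(err), "root/children\\[1\\]")
  expect_match(conditionMessage(err), "exactly 2 children")
})

test_that("scoring validates dimensions and tree structure", {
  tree <- adtree(prediction_node(1), n_items = 7)
  expect_error(adtree_score(tree, c(1, 2, 3)), class = "adscreen_input_error")
  expect_error(adtree(prediction_node(0, list(
    test_node(predicate_le(9, 0.5), prediction_node(1), prediction_node(-1)))),
    n_items = 7), class = "adscreen_model_error")
  expect_error(prediction_node(Inf), class = "adscreen_model_error")
})
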