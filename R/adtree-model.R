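# Alternating decision tree: data model and scoring semantics.
#
# An ADTree interleaves prediction nodes (signed score contributions) and test
# nodes (predicates on one questionnaire item). An instance's score is the sum
# of the values of every prediction node it reaches: the root is always
# reached, and a prediction node below a test node is reached when the
# instance reaches the test node's parent and the predicate evaluates to the
# corresponding branch. A predicate that cannot be evaluated (the item is
# missing / "not applicable") truncates that path: nothing below the test
# node contributes, while contributions already collected above it stand.

#' Predicate on a single questionnaire item
#'
#' Predicates are the conditions carried by ADTree test nodes. Two kinds are
#' supported: ordinal threshold predicates (`predicate_le()`, `predicate_ge()`)
#' that compare the encoded answer code against a cut value, and membership
#' predicates (`predicate_in()`) that test whether the code falls in a set of
#' answer codes (useful when several answer choices are collapsed together).
#'
#' @param item 1-based index of the instrument item the predicate reads.
#' @param cut Numeric cut value; `predicate_le()` is true when
#'   `code <= cut`, `predicate_ge()` when `code >= cut`.
#' @param choices Non-empty integer vector of answer codes;
#'   `predicate_in()` is true when the code is one of them.
#' @return A `predicate` object (a named list with fields `item`, `op` and
#'   `cut` or `choices`).
#' @examples
#' predicate_le(3, 1.5)
#' predicate_in(7, c(0L, 1L))
#' @export
predicate_le <- function(item, cut) new_predicate(item, "le", cut = cut)

#' @rdname predicate_le
#' @export
predicate_ge <- function(item, cut) new_predicate(item, "ge", cut = cut)

#' @rdname predicate_le
#' @export
predicate_in <- function(item, choices) new_predicate(item, "in", choices = choices)

new_predicate <- function(item, op, cut = NULL, choices = NULL) {
  item <- as.integer(item)
  if (length(item) != 1L || is.na(item) || item < 1L) {
    abort("`item` must be a single positive integer.", class = "adscreen_input_error")
  }
  if (op == "in") {
    choices <- as.integer(choices)
    if (length(choices) == 0L || anyNA(choices)) {
      abort("`choices` must be a non-empty integer vector.", class = "adscreen_input_error")
    }
    choices <- sort(unique(choices))
  } else {
    cut <- as.numeric(cut)
    if (length(cut) != 1L || !is.finite(cut)) {
      abort("`cut` must be a single finite number.", class = "adscreen_input_error")
    }
  }
  structure(list(item = item, op = op, cut = cut, choices = choices),
            class = "adscreen_predicate")
}

# Evaluate a predicate on one encoded answer code; NA code gives NA
# (unevaluable), which callers translate into path truncation.
eval_predicate <- function(pred, code) {
  if (is.na(code)) return(NA)
  switch(pred$op,
    le = code <= pred$cut,
    ge = code >= pred$cut,
    `in` = code %in% pred$choices,
    abort(paste0("Unknown predicate op '", pred$op, "'."), class = "adscreen_model_error")
  )
}

#' @export
format.adscreen_predicate <- function(x, ...) {
  switch(x$op,
    le = sprintf("item_%d <= %g", x$item, x$cut),
    ge = sprintf("item_%d >= %g", x$item, x$cut),
    `in` = sprintf("item_%d in {%s}", x$item, paste(x$choices, collapse = ",")),
    "<predicate>"
  )
}

#' @export
print.adscreen_predicate <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' ADTree node constructors
#'
#' `prediction_node()` carries a signed contribution to the total score and
#' zero or more test-node children. `test_node()` carries a predicate and
#' exactly two prediction-node children, one per branch.
#'
#' @param value Finite signed contribution of the prediction node.
#' @param children List of `test_node` objects attached below a prediction
#'   node (possibly empty).
#' @param predicate A predicate built with [predicate_le()] and friends.
#' @param true_child,false_child Prediction nodes entered when the predicate
#'   evaluates true / false.
#' @return A node object (nested named list).
#' @seealso [adtree()]
#' @export
prediction_node <- function(value, children = list()) {
  value <- as.numeric(value)
  if (length(value) != 1L || !is.finite(value)) {
    abort("Prediction node `value` must be a single finite number.",
          class = "adscreen_model_error")
  }
  structure(list(value = value, children = children), class = "adscreen_prediction")
}

#' @rdname prediction_node
#' @export
test_node <- function(predicate, true_child, false_child) {
  if (!inherits(predicate, "adscreen_predicate")) {
    abort("`predicate` must be a predicate object.", class = "adscreen_model_error")
  }
  if (!inherits(true_child, "adscreen_prediction") ||
      !inherits(false_child, "adscreen_prediction")) {
    abort("Both children of a test node must be prediction nodes.",
          class = "adscreen_model_error")
  }
  structure(list(predicate = predicate, true_child = true_child,
                 false_child = false_child), class = "adscreen_test")
}

#' Construct an alternating decision tree
#'
#' Bundles a root prediction node with the instrument dimension and the score
#' orientation convention. In the convention used throughout this package
#' (and by the screening instrument the package models) a *negative* total
#' score indicates the high-risk, screen-positive class.
#'
#' @param root A `prediction_node()`; the root contribution received by every
#'   instance.
#' @param n_items Number of instrument items the tree's predicates may read.
#' @param orientation Score-sign convention; `"negative"` (default) means a
#'   negative score is screen-positive for ASD.
#' @return An object of class `adtree` with fields `root`, `n_items`,
#'   `n_decision_nodes` and `orientation`.
#' @examples
#' tr <- adtree(
#'   prediction_node(0.5, list(
#'     test_node(predicate_le(1, 1.5),
#'               prediction_node(-1.2), prediction_node(0.8)))),
#'   n_items = 7)
#' adtree_score(tr, c(1, 0, 0, 0, 0, 0, 0))
#' @export
adtree <- function(root, n_items, orientation = "negative") {
  if (!inherits(root, "adscreen_prediction")) {
    abort("`root` must be a prediction node.", class = "adscreen_model_error")
  }
  n_items <- as.integer(n_items)
  if (length(n_items) != 1L || is.na(n_items) || n_items < 1L) {
    abort("`n_items` must be a single positive integer.", class = "adscreen_input_error")
  }
  orientation <- match.arg(orientation, c("negative", "positive"))
  tree <- structure(list(root = root, n_items = n_items,
                         n_decision_nodes = 0L, orientation = orientation),
                    class = "adtree")
  tree$n_decision_nodes <- count_test_nodes(root, n_items)
  tree
}

# Walks the tree once: counts test nodes, checks item indices and structure.
count_test_nodes <- function(node, n_items, depth = 0L) {
  if (depth > 1000L) {
    abort("Tree nesting exceeds 1000 levels; refusing (cycle or runaway tree).",
          class = "adscreen_model_error")
  }
  total <- 0L
  for (tn in node$children) {
    if (!inherits(tn, "adscreen_test")) {
      abort("Children of a prediction node must be test nodes.",
            class = "adscreen_model_error")
    }
    if (tn$predicate$item > n_items) {
      abort(sprintf("Predicate reads item %d but the tree declares %d items.",
                    tn$predicate$item, n_items), class = "adscreen_model_error")
    }
    total <- total + 1L +
      count_test_nodes(tn$true_child, n_items, depth + 1L) +
      count_test_nodes(tn$false_child, n_items, depth + 1L)
  }
  total
}

#' @export
print.adtree <- function(x, ...) {
  cat(sprintf("<adtree: %d items, %d decision nodes, root %+.4f, %s-is-ASD>\n",
              x$n_items, x$n_decision_nodes, x$root$value, x$orientation))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Response-matrix coercion shared by scoring entry points.

# Accepts a data frame with item_1..item_n columns, a numeric matrix, or a
# single numeric vector; returns an n x n_items numeric matrix (NA = missing).
response_matrix <- function(responses, n_items) {
  if (is.numeric(responses) && is.null(dim(responses))) {
    responses <- matrix(responses, nrow = 1L)
  }
  if (is.data.frame(responses)) {
    cols <- paste0("item_", seq_len(n_items))
    missing_cols <- setdiff(cols, names(responses))
    if (length(missing_cols) > 0L) {
      abort(paste0("Response table is missing column(s): ",
                   paste(missing_cols, collapse = ", "), "."),
            class = "adscreen_input_error")
    }
    responses <- as.matrix(as.data.frame(lapply(responses[cols], as.numeric)))
  }
  if (!is.matrix(responses) || !is.numeric(responses)) {
    abort("Responses must be a data frame, numeric matrix or numeric vector.",
          class = "adscreen_input_error")
  }
  if (ncol(responses) != n_items) {
    abort(sprintf("Responses have %d columns but the tree expects %d items.",
                  ncol(responses), n_items), class = "adscreen_input_error")
  }
  responses
}

# ---------------------------------------------------------------------------
# Scoring

#' Score instances with an alternating decision tree
#'
#' The score of an instance is the sum of the root value and of every
#' prediction node reached along paths whose test-node predicates all evaluate
#' true for that instance. A test node whose predicate cannot be evaluated
#' because the item is missing terminates that path: nothing below it
#' contributes, while contributions above it remain.
#'
#' @param tree An [adtree()].
#' @param responses Encoded answers: a data frame with columns
#'   `item_1 ... item_n` (extra columns ignored), a numeric matrix with one
#'   column per item, or a single numeric vector. `NA` marks a missing /
#'   "not applicable" answer.
#' @return Numeric vector of signed scores, one per row of `responses`.
#' @export
adtree_score <- function(tree, responses) {
  stopifnot(inherits(tree, "adtree"))
  x <- response_matrix(responses, tree$n_items)
  if (nrow(x) == 1L) {
    score_one(tree$root, x[1L, ])
  } else {
    adtree_score_matrix(tree, x)
  }
}

# Recursive per-path accumulation for a single instance.
score_one <- function(node, x) {
  total <- node$value
  for (tn in node$children) {
    hit <- eval_predicate(tn$predicate, x[[tn$predicate$item]])
    if (is.na(hit)) next                    # unevaluable: truncate this path
    child <- if (hit) tn$true_child else tn$false_child
    total <- total + score_one(child, x)
  }
  total
}

# Vectorised scorer: propagates per-instance reach indicators through the
# flattened node table. Used for batch scoring and by score_range().
adtree_score_matrix <- function(tree, x) {
  flat <- adtree_flatten(tree)
  n <- nrow(x)
  scores <- rep(tree$root$value, n)
  reach <- vector("list", nrow(flat$pred))
  reach[[1L]] <- rep(TRUE, n)
  if (nrow(flat$test) == 0L) return(scores)
  for (i in seq_len(nrow(flat$test))) {
    tinfo <- flat$test[i, ]
    parent_reach <- reach[[tinfo$parent_pred]]
    pred <- flat$predicates[[i]]
    code <- x[, pred$item]
    hit <- switch(pred$op,
      le = code <= pred$cut,
      ge = code >= pred$cut,
      `in` = !is.na(code) & code %in% pred$choices)
    if (pred$op == "in") hit[is.na(code)] <- NA
    r_true <- parent_reach & !is.na(hit) & hit
    r_false <- parent_reach & !is.na(hit) & !hit
    reach[[tinfo$true_pred]] <- r_true
    reach[[tinfo$false_pred]] <- r_false
    scores <- scores + r_true * flat$pred$value[tinfo$true_pred] +
      r_false * flat$pred$value[tinfo$false_pred]
  }
  scores
}

# Flatten the nested tree into parallel node tables (parents before children).
# pred: one row per prediction node (id, value, parent_test, branch);
# test: one row per test node (id, parent_pred, true_pred, false_pred);
# predicates: list of predicate objects parallel to test rows.
adtree_flatten <- function(tree) {
  pred_value <- numeric(0); pred_parent <- integer(0); pred_branch <- character(0)
  test_parent <- integer(0); test_true <- integer(0); test_false <- integer(0)
  predicates <- list()

  add_pred <- function(node, parent_test, branch) {
    pred_value[[length(pred_value) + 1L]] <<- node$value
    pred_parent[[length(pred_parent) + 1L]] <<- parent_test
    pred_branch[[length(pred_branch) + 1L]] <<- branch
    length(pred_value)
  }
  # breadth-first so that a test node's parent prediction is already placed
  queue <- list(list(node = tree$root, parent = NA_integer_, branch = NA_character_))
  pred_nodes <- list()
  while (length(queue) > 0L) {
    entry <- queue[[1L]]; queue <- queue[-1L]
    id <- add_pred(entry$node, entry$parent, entry$branch)
    pred_nodes[[id]] <- entry$node
    for (tn in entry$node$children) {
      tid <- length(predicates) + 1L
      predicates[[tid]] <- tn$predicate
      test_parent[[tid]] <- id
      test_true[[tid]] <- NA_integer_
      test_false[[tid]] <- NA_integer_
      queue <- c(queue, list(
        list(node = tn$true_child, parent = tid, branch = "true"),
        list(node = tn$false_child, parent = tid, branch = "false")))
    }
  }
  # resolve test -> child prediction ids
  for (pid in seq_along(pred_parent)) {
    tp <- pred_parent[[pid]]
    if (!is.na(tp)) {
      if (pred_branch[[pid]] == "true") test_true[[tp]] <- pid else test_false[[tp]] <- pid
    }
  }
  list(
    pred = tibble(id = seq_along(pred_value), value = pred_value,
                  parent_test = pred_parent, branch = pred_branch),
    test = tibble(id = seq_along(test_parent), parent_pred = test_parent,
                  true_pred = test_true, false_pred = test_false),
    predicates = predicates
  )
}

#' Tidy an ADTree into a node table
#'
#' Returns one row per node (prediction and test), parents before children,
#' with the fields needed to reconstruct or inspect the tree: node kind,
#' prediction value, and the predicate (item, operator, cut / choice set) for
#' test nodes.
#'
#' @param x An [adtree()].
#' @param ... Unused.
#' @return A tibble with columns `node`, `kind`, `value`, `item`, `op`,
#'   `cut`, `choices`, `parent`, `branch`.
#' @export
tidy.adtree <- function(x, ...) {
  flat <- adtree_flatten(x)
  pred_rows <- flat$pred |>
    mutate(node = paste0("p", .data$id), kind = "prediction",
           item = NA_integer_, op = NA_character_, cut = NA_real_,
           choices = list(NULL),
           parent = ifelse(is.na(.data$parent_test), NA_character_,
                           paste0("t", .data$parent_test)),
           branch = .data$branch) |>
    select("node", "kind", "value", "item", "op", "cut", "choices",
           "parent", "branch")
  if (nrow(flat$test) > 0L) {
    test_rows <- flat$test |>
      mutate(node = paste0("t", .data$id), kind = "test",
             value = NA_real_,
             item = map_int(flat$predicates, "item"),
             op = map_chr(flat$predicates, "op"),
             cut = map_dbl(flat$predicates, function(p) p$cut %||% NA_real_),
             choices = map(flat$predicates, "choices"),
             parent = paste0("p", .data$parent_pred),
             branch = NA_character_) |>
      select("node", "kind", "value", "item", "op", "cut", "choices",
             "parent", "branch")
    pred_rows <- bind_rows(pred_rows, test_rows)
  }
  as_tibble(pred_rows)
}

# ---------------------------------------------------------------------------
# Classification and confidence

#' Dichotomise ADTree scores into screen results
#'
#' A negative total score is classified screen-positive (high risk for ASD),
#' a positive score screen-negative. A score of exactly zero is classified
#' screen-positive by default: the published cutoff defines only the strict
#' signs, and a screening instrument should err toward sensitivity at the
#' boundary; the tie rule is exposed so the choice is auditable.
#'
#' @param score Numeric vector of finite ADTree scores.
#' @param tie Class assigned to a score of exactly zero; `"positive"`
#'   (default) or `"negative"`.
#' @return Factor with levels `c("positive", "negative")`, where `"positive"`
#'   means screen-positive for ASD.
#' @examples
#' classify_score(c(-9.28, 6.43, 0))
#' @export
classify_score <- function(score, tie = c("positive", "negative")) {
  tie <- match.arg(tie)
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score))) {
    abort("`score` must be finite and non-missing.", class = "adscreen_input_error")
  }
  pos <- score < 0 | (score == 0 & tie == "positive")
  factor(ifelse(pos, "positive", "negative"), levels = c("positive", "negative"))
}

#' Confidence of an ADTree classification
#'
#' The magnitude of the score measures confidence in the classification:
#' scores near the zero cutoff carry low confidence, scores near the extremes
#' of the range carry high confidence.
#'
#' @inheritParams classify_score
#' @return Non-negative numeric vector, `abs(score)`.
#' @export
score_confidence <- function(score) {
  if (!is.numeric(score) || anyNA(score) || any(!is.finite(score))) {
    abort("`score` must be finite and non-missing.", class = "adscreen_input_error")
  }
  abs(score)
}

# ---------------------------------------------------------------------------
# Score range

#' Exact attainable score range of a tree over an instrument
#'
#' Enumerates every complete response combination over the instrument's
#' finite answer domains (at most `prod(n_options)` combinations; 5^7 =
#' 78,125 for the seven-item instrument) and returns the exact minimum and
#' maximum attainable scores.
#'
#' @param tree An [adtree()].
#' @param instrument An instrument from [mara_instrument()], or an integer
#'   vector giving the number of answer options per item (codes are assumed
#'   consecutive from 0).
#' @return A tibble with columns `min` and `max`.
#' @export
score_range <- function(tree, instrument) {
  n_opts <- instrument_n_options(instrument)
  if (length(n_opts) != tree$n_items) {
    abort(sprintf("Instrument has %d items but the tree expects %d.",
                  length(n_opts), tree$n_items), class = "adscreen_input_error")
  }
  if (anyNA(n_opts) || any(n_opts < 1L) || any(!is.finite(n_opts))) {
    abort("Every item needs a finite, declared answer domain.",
          class = "adscreen_input_error")
  }
  grids <- lapply(n_opts, function(k) seq.int(0L, k - 1L))
  combos <- as.matrix(expand.grid(grids, KEEP.OUT.ATTRS = FALSE))
  colnames(combos) <- NULL
  scores <- adtree_score_matrix(tree, combos)
  tibble(min = min(scores), max = max(scores))
}

# Number of answer options per item; accepts an instrument or a bare vector.
instrument_n_options <- function(instrument) {
  if (inherits(instrument, "adscreen_instrument")) {
    map_int(instrument$options, nrow)
  } else {
    as.integer(instrument)
  }
}

# ---------------------------------------------------------------------------
# Serialization

# %.17g round-trips IEEE doubles exactly; jsonlite would re-round them.
fmt_num <- function(x) sprintf("%.17g", x)

json_str <- function(x) paste0('"', gsub('"', '\\\\"', x), '"')

emit_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (inherits(node, "adscreen_prediction")) {
    kids <- vapply(node$children, emit_node, character(1), indent = indent + 1L)
    children <- if (length(kids) == 0L) "[]" else
      paste0("[\n", paste(kids, collapse = ",\n"), "\n", pad, "]")
    paste0(pad, '{"kind": "prediction", "value": ', fmt_num(node$value),
           ', "children": ', children, "}")
  } else {
    p <- node$predicate
    pred_json <- if (p$op == "in") {
      paste0('{"item": ', p$item, ', "op": "in", "choices": [',
             paste(p$choices, collapse = ", "), "]}")
    } else {
      paste0('{"item": ', p$item, ', "op": ', json_str(p$op),
             ', "cut": ', fmt_num(p$cut), "}")
    }
    kids <- vapply(list(node$true_child, node$false_child), emit_node,
                   character(1), indent = indent + 1L)
    paste0(pad, '{"kind": "test", "predicate": ', pred_json,
           ', "children": [\n', paste(kids, collapse = ",\n"), "\n", pad, "]}")
  }
}

#' Serialize / deserialize an ADTree as JSON
#'
#' The canonical tree document is nested JSON with explicit node kinds:
#' prediction nodes carry `value` and a list of test-node `children`; test
#' nodes carry a `predicate` (`item`, `op`, `cut` or `choices`) and exactly
#' two children, the true branch first. Numeric values are written with 17
#' significant digits so that `adtree_from_json(adtree_to_json(t))`
#' reproduces the tree bit-identically; printed renderings of a tree are
#' approximations and must never be re-read as model values.
#'
#' @param tree An [adtree()].
#' @param path Optional file path; if supplied the document is written there
#'   and the path returned invisibly, otherwise the JSON string is returned.
#' @param provenance Optional named list (seed, configuration hash, tool
#'   version, ...) embedded in the document header.
#' @return `adtree_to_json()`: a JSON string (or the path, invisibly).
#'   `adtree_from_json()`: an [adtree()].
#' @export
adtree_to_json <- function(tree, path = NULL, provenance = NULL) {
  stopifnot(inherits(tree, "adtree"))
  prov <- if (is.null(provenance) || length(provenance) == 0L) "{}" else {
    fields <- imap(provenance, function(v, k) {
      val <- if (is.numeric(v)) fmt_num(v) else json_str(as.character(v))
      paste0(json_str(k), ": ", val)
    })
    paste0("{", paste(unlist(fields), collapse = ", "), "}")
  }
  doc <- paste0(
    '{\n"format": "adscreen-adtree",\n"version": 1,\n',
    '"n_items": ', tree$n_items, ',\n',
    '"orientation": ', json_str(tree$orientation), ',\n',
    '"provenance": ', prov, ',\n',
    '"root":\n', emit_node(tree$root, 1L), "\n}\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(path)
}

#' @param x For `adtree_from_json()`: a JSON string or a path to a JSON file.
#' @rdname adtree_to_json
#' @export
adtree_from_json <- function(x) {
  doc <- tryCatch(
    jsonlite::fromJSON(x, simplifyVector = FALSE),
    error = function(e) abort(paste0("Tree document is not valid JSON: ",
                                     conditionMessage(e)),
                              class = "adscreen_parse_error"))
  if (!is.list(doc) || is.null(doc$root)) {
    abort("Tree document lacks a 'root' node.", class = "adscreen_parse_error")
  }
  n_items <- doc$n_items
  if (is.null(n_items)) {
    abort("Tree document lacks 'n_items'.", class = "adscreen_parse_error")
  }
  root <- parse_node(doc$root, "root", expect = "prediction")
  adtree(root, n_items = n_items,
         orientation = doc$orientation %||% "negative")
}

parse_node <- function(node, path, expect) {
  if (!is.list(node) || is.null(node$kind)) {
    abort(paste0("Node at ", path, " lacks a 'kind' field."),
          class = "adscreen_parse_error")
  }
  if (node$kind != expect) {
    abort(sprintf("Node at %s has kind '%s' but a %s node is required here.",
                  path, node$kind, expect), class = "adscreen_parse_error")
  }
  if (expect == "prediction") {
    if (is.null(node$value) || !is.numeric(node$value)) {
      abort(paste0("Prediction node at ", path, " lacks a numeric 'value'."),
            class = "adscreen_parse_error")
    }
    kids <- node$children %||% list()
    children <- imap(kids, function(k, i)
      parse_node(k, paste0(path, "/children[", i, "]"), expect = "test"))
    prediction_node(node$value, children)
  } else {
    p <- node$predicate
    if (is.null(p) || is.null(p$item) || is.null(p$op)) {
      abort(paste0("Test node at ", path, " lacks a well-formed 'predicate'."),
            class = "adscreen_parse_error")
    }
    pred <- switch(p$op,
      le = predicate_le(p$item, p$cut),
      ge = predicate_ge(p$item, p$cut),
      `in` = predicate_in(p$item, unlist(p$choices)),
      abort(paste0("Test node at ", path, " has unknown predicate op '",
                   p$op, "'."), class = "adscreen_parse_error"))
    kids <- node$children %||% list()
    if (length(kids) != 2L) {
      abort(sprintf(
        "Test node at %s must have exactly 2 children (true, false); found %d.",
        path, length(kids)), class = "adscreen_parse_error")
    }
    test_node(pred,
              parse_node(kids[[1L]], paste0(path, "/children[1]"), "prediction"),
              parse_node(kids[[2L]], paste0(path, "/children[2]"), "prediction"))
  }
}
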