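# The 7-item parent questionnaire instrument: item definitions, ordinal
# answer encoding, response validation, and end-to-end screening reports.

mara_items <- c(
  paste0("How well does your child understand spoken language, based on ",
         "speech alone? (Not including using clues from the surrounding ",
         "environment)"),
  "Can your child have a back-and-forth conversation with you?",
  "Does your child engage in imaginative or pretend play?",
  paste0("Does your child play pretend games when with a peer? Do they ",
         "understand each other when playing?"),
  paste0("Does your child maintain normal eye contact for his or her age in ",
         "different situations and with a variety of different people?"),
  paste0("Does your child play with his or her peers when in a group of at ",
         "least two others?"),
  "When were your child's behavioral abnormalities first obvious?")

#' The seven-item mobile autism risk assessment instrument
#'
#' Returns the instrument definition: the seven questions about a child's
#' communication, social skills and behaviors, each with 4-5 ordered answer
#' choices plus the option of "not applicable". Answer codes are consecutive
#' integers from 0, with 0 the most atypical choice and the highest code the
#' most typical; the ordinal codes are what the scoring model consumes, so
#' the option *labels* are configurable display text, not model inputs
#' (the published source does not print them; generic labels are shipped).
#'
#' @param option_labels Optional list of character vectors (one per item)
#'   replacing the generic answer-choice labels; lengths must match the
#'   per-item option counts.
#' @return An object of class `adscreen_instrument`: a tibble with one row
#'   per item (`index`, `text`, `allows_na` and an `options` list-column of
#'   `code`/`label` tibbles), with version and administration metadata
#'   attached as attributes (reading level 7.9, about 5 minutes to
#'   complete).
#' @examples
#' inst <- mara_instrument()
#' nrow(inst)                 # 7 items
#' inst$text[7]
#' @export
mara_instrument <- function(option_labels = NULL) {
  n_opts <- c(5L, 5L, 5L, 5L, 5L, 5L, 4L)
  options <- map(seq_along(n_opts), function(i) {
    k <- n_opts[i]
    labels <- if (!is.null(option_labels)) {
      if (length(option_labels[[i]]) != k) {
        abort(sprintf("Item %d needs %d option labels.", i, k),
              class = "adscreen_input_error")
      }
      option_labels[[i]]
    } else {
      paste0("choice_", seq_len(k) - 1L)
    }
    tibble(code = seq_len(k) - 1L, label = labels)
  })
  inst <- tibble(index = seq_along(mara_items), text = mara_items,
                 options = options, allows_na = TRUE)
  structure(inst,
            class = c("adscreen_instrument", class(inst)),
            version = "1.0",
            metadata = list(reading_grade_level = 7.9,
                            completion_minutes = 5))
}

#' Write / read an instrument definition as JSON
#'
#' @param instrument An instrument from [mara_instrument()].
#' @param path File path for the JSON document.
#' @return `instrument_to_json()` returns `path` invisibly;
#'   `instrument_from_json()` returns the instrument.
#' @export
instrument_to_json <- function(instrument, path) {
  doc <- list(
    version = attr(instrument, "version"),
    metadata = attr(instrument, "metadata"),
    items = map(seq_len(nrow(instrument)), function(i) {
      list(index = instrument$index[i], text = instrument$text[i],
           allows_na = instrument$allows_na[i],
           options = instrument$options[[i]])
    }))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname instrument_to_json
#' @export
instrument_from_json <- function(path) {
  doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  inst <- tibble(
    index = map_int(doc$items, "index"),
    text = map_chr(doc$items, "text"),
    options = map(doc$items, function(it)
      tibble(code = map_int(it$options, "code"),
             label = map_chr(it$options, "label"))),
    allows_na = map_lgl(doc$items, "allows_na"))
  structure(inst, class = c("adscreen_instrument", class(inst)),
            version = doc$version, metadata = doc$metadata)
}

# ---------------------------------------------------------------------------
# Encoding and validation

#' Encode and validate questionnaire responses
#'
#' `encode_responses()` validates a table of answered codes against the
#' instrument: every `item_<k>` entry must be one of the item's declared
#' codes or `NA` ("not applicable"). Invalid entries are rejected with an
#' error naming the item and the offending value; no partially validated
#' table is returned. `decode_responses()` maps codes back to the option
#' labels.
#'
#' @param data Data frame with columns `item_1 ... item_k` (integer answer
#'   codes or `NA`) and optionally `subject_id`; other columns pass through
#'   untouched.
#' @param instrument An instrument from [mara_instrument()].
#' @return `encode_responses()`: the input as a tibble with item columns
#'   coerced to integer. `decode_responses()`: a tibble with item columns
#'   replaced by option labels.
#' @examples
#' inst <- mara_instrument()
#' r <- tibble::tibble(item_1 = 0L, item_2 = 4L, item_3 = NA, item_4 = 2L,
#'                     item_5 = 1L, item_6 = 3L, item_7 = 0L)
#' encode_responses(r, inst)
#' @export
encode_responses <- function(data, instrument = mara_instrument()) {
  n_items <- nrow(instrument)
  cols <- paste0("item_", seq_len(n_items))
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Response table is missing column(s): ",
                 paste(missing_cols, collapse = ", "), "."),
          class = "adscreen_validation_error")
  }
  out <- as_tibble(data)
  n_opts <- instrument_n_options(instrument)
  for (i in seq_len(n_items)) {
    v <- out[[cols[i]]]
    vn <- suppressWarnings(as.numeric(v))
    bad_type <- !is.na(v) & is.na(vn)
    bad_range <- !is.na(vn) & (vn != round(vn) | vn < 0 | vn > n_opts[i] - 1L)
    bad <- which(bad_type | bad_range)
    if (length(bad) > 0L) {
      abort(sprintf(
        "Invalid answer for item_%d (codes 0..%d or NA): value '%s' in row %d.",
        i, n_opts[i] - 1L, as.character(v[bad[1L]]), bad[1L]),
        class = "adscreen_validation_error")
    }
    out[[cols[i]]] <- as.integer(vn)
  }
  out
}

#' @rdname encode_responses
#' @export
decode_responses <- function(data, instrument = mara_instrument()) {
  encoded <- encode_responses(data, instrument)
  cols <- paste0("item_", seq_len(nrow(instrument)))
  for (i in seq_along(cols)) {
    opts <- instrument$options[[i]]
    encoded[[cols[i]]] <- opts$label[match(encoded[[cols[i]]], opts$code)]
  }
  encoded
}

# ---------------------------------------------------------------------------
# Screening

#' Screen subjects with a scoring tree
#'
#' Runs validated responses through an alternating decision tree and reports,
#' per subject: the signed total score, the dichotomized risk class (negative
#' scores are screen-positive for ASD), the confidence (score magnitude) and
#' the number of unanswered items. Input order is preserved.
#'
#' @param data Data frame with `item_1 ... item_7` answer-code columns and
#'   optionally `subject_id` (generated from row numbers when absent).
#' @param tree An [adtree()] over the instrument's items.
#' @param instrument The instrument the responses answer
#'   (default [mara_instrument()]).
#' @param tie Tie rule for a score of exactly zero, see [classify_score()].
#' @return A tibble with columns `subject_id`, `score`, `risk_class`,
#'   `confidence`, `items_missing`.
#' @export
screen <- function(data, tree, instrument = mara_instrument(),
                   tie = "positive") {
  stopifnot(inherits(tree, "adtree"))
  if (tree$n_items != nrow(instrument)) {
    abort(sprintf("Tree expects %d items but the instrument defines %d.",
                  tree$n_items, nrow(instrument)),
          class = "adscreen_input_error")
  }
  encoded <- encode_responses(data, instrument)
  cols <- paste0("item_", seq_len(nrow(instrument)))
  x <- response_matrix(encoded, nrow(instrument))
  sc <- if (nrow(x) == 0L) numeric(0) else adtree_score(tree, x)
  tibble(
    subject_id = if ("subject_id" %in% names(encoded)) encoded$subject_id
                 else paste0("S", seq_len(nrow(encoded))),
    score = sc,
    risk_class = classify_score(sc, tie = tie),
    confidence = score_confidence(sc),
    items_missing = as.integer(rowSums(is.na(x))))
}

#' Histogram of screening scores by diagnosis
#'
#' @param data A data frame holding at least a `score` column, e.g. the
#'   output of [screen()] joined to the clinical labels.
#' @param truth Optional column with the clinical diagnosis (tidy-eval) used
#'   to fill the histogram by group.
#' @param binwidth Histogram bin width (default 1 score unit).
#' @return A ggplot: score histogram with the zero classification cutoff
#'   marked; scores left of the line are screen-positive for ASD.
#' @export
plot_score_distribution <- function(data, truth = NULL, binwidth = 1) {
  q <- rlang::enquo(truth)
  p <- if (rlang::quo_is_null(q)) {
    ggplot(data, aes(x = .data$score))
  } else {
    ggplot(data, aes(x = .data$score, fill = {{ truth }}))
  }
  p + geom_histogram(binwidth = binwidth, position = "identity",
                     alpha = 0.6, boundary = 0) +
    geom_vline(xintercept = 0, linetype = 2) +
    labs(x = "Screening score (negative = high risk)", y = "Subjects",
         fill = NULL, title = "Screening score distribution") +
    theme_minimal()
}
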