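# Synthetic screening-cohort generator.
#
# Emulates a developmental-behavioral clinic cohort so training, screening
# and evaluation can be exercised end to end without clinical data: ~31% ASD
# prevalence, 76% male, median age 5.8 years (ASD subjects skewing younger),
# partially missing non-verbal IQ, mostly verbal subjects, and 7-item ordinal
# questionnaire responses whose distributions differ by diagnosis.
#
# Item responses follow per-class categorical base tables optionally tied to
# a latent severity scalar: each subject draws a severity s (a class-specific
# normal mixture), and the base probabilities of item i are exponentially
# tilted toward low (more atypical) codes in proportion to loading_i * s. The
# shared scalar induces the within-subject correlation across items that
# real questionnaires show; with all loadings at 0 the items are
# conditionally independent given the class.

default_item_model <- function() {
  # Mild class-specific skew in the base tables (code 0 = most atypical
  # choice); the class signal is carried by the latent severity. Each class
  # is a two-component mixture: a dominant, well-separated component plus a
  # minority crossover subpopulation -- ASD children whose presentation is
  # mild enough to be missed, and non-ASD children (think language delays)
  # whose responses resemble ASD. The decision boundary then falls in a
  # low-density valley, so the screener's operating point is governed by the
  # stable mixture weights rather than by knife-edge threshold placement.
  tilt_table <- function(k, shift) {
    w <- exp(shift * (seq_len(k) - 1L))
    w / sum(w)
  }
  n_opts <- c(5L, 5L, 5L, 5L, 5L, 5L, 4L)
  list(
    base = list(
      asd = lapply(n_opts, tilt_table, shift = -0.15),
      other = lapply(n_opts, tilt_table, shift = 0.15)),
    loading = rep(1.2, 7),
    severity = list(
      asd = list(w = c(0.94, 0.06), mean = c(4.0, -0.8), sd = c(0.6, 0.7)),
      other = list(w = c(0.80, 0.20), mean = c(-0.8, 4.0), sd = c(0.7, 0.6))),
    na_fraction = 0.02
  )
}

#' Generative settings for a synthetic screening cohort
#'
#' Defaults emulate the clinic population the screener was evaluated in:
#' 31% ASD prevalence, 76.1% male, log-normal ages with class-specific
#' medians (3.9 years for ASD, 6.6 for other diagnoses) truncated to the
#' enrolled range of 16 months to 17 years, normal non-verbal IQ with lower
#' ASD location and 105/222 missingness, and mostly verbal subjects with
#' non-verbal status concentrated in the ASD class.
#'
#' @param n Cohort size (default 222).
#' @param prevalence ASD fraction (default 0.31).
#' @param male_fraction Male fraction (default 0.761).
#' @param age List: `median` and `sdlog` (each named `asd`/`other`) of the
#'   log-normal age distribution, and `range` for truncation in years.
#' @param iq List: `mean`, `sd` (named `asd`/`other`) and `missing_fraction`
#'   of the non-verbal IQ distribution.
#' @param verbal List: `fraction` verbal by class and `missing_fraction` of
#'   the verbal-status covariate.
#' @param items Item-response model: per-class `base` probability tables
#'   (one vector per item), per-item severity `loading`, a class-specific
#'   `severity` normal mixture (fields `w`, `mean`, `sd` per class), and a
#'   per-item `na_fraction` of "not applicable"
#'   answers. See [default_item_model()] internals via `cohort_preset()`.
#' @param ... Overrides merged into the defaults.
#' @return An object of class `cohort_params`.
#' @seealso [cohort_preset()] for named presets, [simulate_cohort()]
#' @export
cohort_params <- function(n = 222, prevalence = 0.31, male_fraction = 0.761,
                          age = NULL, iq = NULL, verbal = NULL, items = NULL,
                          ...) {
  params <- list(
    n = as.integer(n),
    prevalence = prevalence,
    male_fraction = male_fraction,
    age = modifyList(list(median = c(asd = 3.9, other = 6.6),
                          sdlog = c(asd = 0.61, other = 0.43),
                          range = c(16 / 12, 17)), age %||% list()),
    iq = modifyList(list(mean = c(asd = 87.5, other = 95),
                         sd = c(asd = 15, other = 15),
                         missing_fraction = 105 / 222), iq %||% list()),
    verbal = modifyList(list(fraction = c(asd = 56 / 69, other = 149 / 153),
                             missing_fraction = 7 / 222), verbal %||% list()),
    items = merge_item_model(default_item_model(), items %||% list())
  )
  params <- modifyList(params, list(...))
  validate_cohort_params(params)
  structure(params, class = "cohort_params")
}

# modifyList drops unnamed list elements, so the per-item base tables (plain
# lists of probability vectors) are replaced wholesale when supplied.
merge_item_model <- function(default, user) {
  out <- default
  if (!is.null(user$base)) {
    for (cls in names(user$base)) out$base[[cls]] <- user$base[[cls]]
  }
  if (!is.null(user$loading)) out$loading <- user$loading
  if (!is.null(user$severity)) {
    for (cls in names(user$severity)) {
      out$severity[[cls]] <- modifyList(out$severity[[cls]],
                                        user$severity[[cls]])
    }
  }
  if (!is.null(user$na_fraction)) out$na_fraction <- user$na_fraction
  out
}

validate_cohort_params <- function(p) {
  frac_ok <- function(x) all(is.finite(x)) && all(x >= 0 & x <= 1)
  if (p$n < 1L) abort("`n` must be at least 1.", class = "adscreen_config_error")
  if (!frac_ok(p$prevalence) || !frac_ok(p$male_fraction) ||
      !frac_ok(p$iq$missing_fraction) || !frac_ok(p$verbal$fraction) ||
      !frac_ok(p$items$na_fraction)) {
    abort("All fractions must lie in [0, 1].", class = "adscreen_config_error")
  }
  if (any(p$age$median <= 0) || any(p$age$sdlog <= 0) ||
      p$age$range[1] <= 0 || diff(p$age$range) <= 0) {
    abort("Invalid age distribution parameters.", class = "adscreen_config_error")
  }
  for (cls in c("asd", "other")) {
    tabs <- p$items$base[[cls]]
    if (length(tabs) != length(p$items$loading)) {
      abort("Item base tables and loadings disagree in item count.",
            class = "adscreen_config_error")
    }
    for (t in tabs) {
      if (any(t < 0) || abs(sum(t) - 1) > 1e-6) {
        abort("Each item's base probabilities must be non-negative and sum to 1.",
              class = "adscreen_config_error")
      }
    }
    sp <- p$items$severity[[cls]]
    if (is.null(sp$w) || length(sp$w) != length(sp$mean) ||
        length(sp$w) != length(sp$sd) || any(sp$w < 0) ||
        abs(sum(sp$w) - 1) > 1e-6 || any(sp$sd <= 0)) {
      abort("Severity mixture needs matching w/mean/sd with w summing to 1.",
            class = "adscreen_config_error")
    }
  }
  invisible(p)
}

#' Named cohort presets
#'
#' * `"study_like"`: the default parameters, calibrated so that a 20-round
#'   tree trained on a large cohort operates near sensitivity 0.90 /
#'   specificity 0.80 -- an *emulation* of the published operating point for
#'   end-to-end demonstrations, not a reproduction of the clinical data.
#' * `"separable"`: ASD and other subjects answer from disjoint code ranges,
#'   so a trained tree can classify perfectly.
#' * `"uninformative"`: item responses are independent of the diagnosis;
#'   any classifier can only perform at chance level.
#'
#' @param preset Preset name.
#' @param ... Overrides passed to [cohort_params()] (e.g. `n`).
#' @return A [cohort_params()] object.
#' @export
cohort_preset <- function(preset = c("study_like", "separable", "uninformative"),
                          ...) {
  preset <- match.arg(preset)
  switch(preset,
    study_like = cohort_params(...),
    separable = cohort_params(items = list(
      base = list(
        asd = c(rep(list(c(0.6, 0.4, 0, 0, 0)), 6), list(c(0.6, 0.4, 0, 0))),
        other = c(rep(list(c(0, 0, 0, 0.4, 0.6)), 6), list(c(0, 0, 0.4, 0.6)))),
      loading = rep(0, 7),
      severity = list(asd = list(w = 1, mean = 0, sd = 1),
                      other = list(w = 1, mean = 0, sd = 1)),
      na_fraction = 0), ...),
    uninformative = {
      flat <- c(rep(list(rep(0.2, 5)), 6), list(rep(0.25, 4)))
      cohort_params(items = list(
        base = list(asd = flat, other = flat),
        loading = rep(0, 7),
        severity = list(asd = list(w = 1, mean = 0, sd = 1),
                      other = list(w = 1, mean = 0, sd = 1)),
        na_fraction = 0), ...)
    })
}

#' @export
print.cohort_params <- function(x, ...) {
  cat(sprintf(
    "<cohort_params: n=%d, prevalence=%.2f, male=%.2f, %d items>\n",
    x$n, x$prevalence, x$male_fraction, length(x$items$loading)))
  invisible(x)
}

#' Read / write cohort parameters as YAML
#'
#' @param params A [cohort_params()] object.
#' @param path File path.
#' @return `write_cohort_params()` returns `path` invisibly;
#'   `read_cohort_params()` returns a [cohort_params()].
#' @export
write_cohort_params <- function(params, path) {
  # yaml serialises named atomic vectors as plain sequences; convert them to
  # lists so the asd/other names survive the round trip
  named_to_list <- function(x) {
    if (is.list(x)) lapply(x, named_to_list)
    else if (!is.null(names(x))) as.list(x)
    else x
  }
  yaml::write_yaml(named_to_list(unclass(params)), path, precision = 17L)
  invisible(path)
}

#' @rdname write_cohort_params
#' @export
read_cohort_params <- function(path) {
  raw <- yaml::read_yaml(path)
  # yaml drops names on named numeric vectors read back as lists
  relist <- function(x) if (is.list(x)) lapply(x, relist) else x
  p <- cohort_params(
    n = raw$n %||% 222,
    prevalence = raw$prevalence %||% 0.31,
    male_fraction = raw$male_fraction %||% 0.761,
    age = restore_named(raw$age),
    iq = restore_named(raw$iq),
    verbal = restore_named(raw$verbal),
    items = restore_items(raw$items))
  p
}

restore_named <- function(x) {
  if (is.null(x)) return(NULL)
  lapply(x, function(v) if (is.list(v)) unlist(v) else v)
}

restore_items <- function(x) {
  if (is.null(x)) return(NULL)
  out <- x
  if (!is.null(x$base)) {
    out$base <- lapply(x$base, function(tabs) lapply(tabs, unlist))
  }
  if (!is.null(x$loading)) out$loading <- unlist(x$loading)
  if (!is.null(x$severity)) out$severity <- lapply(x$severity, restore_named)
  out
}

# ---------------------------------------------------------------------------
# Simulation

# Inverse-CDF sample from a log-normal truncated to [lo, hi].
rlnorm_trunc <- function(n, meanlog, sdlog, lo, hi) {
  p_lo <- stats::plnorm(lo, meanlog, sdlog)
  p_hi <- stats::plnorm(hi, meanlog, sdlog)
  stats::qlnorm(p_lo + runif(n) * (p_hi - p_lo), meanlog, sdlog)
}

# Row-wise categorical draw from an n x k probability matrix; returns codes
# 0..k-1.
sample_categorical <- function(prob) {
  cum <- t(apply(prob, 1L, cumsum))
  u <- runif(nrow(prob)) * cum[, ncol(cum)]
  codes <- rowSums(u > cum)
  as.integer(codes)
}

#' Simulate a synthetic screening cohort
#'
#' Draws class labels first, then covariates and item responses conditional
#' on class. The draw is deterministic given `seed` (the global RNG state is
#' left untouched).
#'
#' @param params A [cohort_params()] or [cohort_preset()].
#' @param seed Integer RNG seed.
#' @return A tibble with one row per subject: `subject_id`, `true_label`
#'   (`"ASD"` / `"nonASD"`), `item_1 ... item_7` answer codes (`NA` = not
#'   applicable), `age_years`, `sex`, `nonverbal_iq` (`NA` when untested),
#'   `verbal_status` and the latent `severity` used to generate the items.
#' @examples
#' cohort <- simulate_cohort(cohort_params(n = 50), seed = 1)
#' table(cohort$true_label)
#' @export
simulate_cohort <- function(params, seed = 1) {
  stopifnot(inherits(params, "cohort_params"))
  n <- params$n
  withr::with_seed(seed, {
    asd <- runif(n) < params$prevalence
    cls <- ifelse(asd, "asd", "other")
    sex <- ifelse(runif(n) < params$male_fraction, "male", "female")

    age <- numeric(n)
    for (c2 in c("asd", "other")) {
      idx <- cls == c2
      age[idx] <- rlnorm_trunc(sum(idx), log(params$age$median[[c2]]),
                               params$age$sdlog[[c2]],
                               params$age$range[1], params$age$range[2])
    }

    iq <- numeric(n)
    for (c2 in c("asd", "other")) {
      idx <- cls == c2
      iq[idx] <- round(rnorm(sum(idx), params$iq$mean[[c2]],
                             params$iq$sd[[c2]]))
    }
    iq <- pmin(pmax(iq, 40), 140)
    iq[runif(n) < params$iq$missing_fraction] <- NA

    verbal <- character(n)
    for (c2 in c("asd", "other")) {
      idx <- cls == c2
      verbal[idx] <- ifelse(runif(sum(idx)) < params$verbal$fraction[[c2]],
                            "verbal", "non-verbal")
    }
    verbal[runif(n) < params$verbal$missing_fraction] <- NA

    sev <- numeric(n)
    for (c2 in c("asd", "other")) {
      idx <- which(cls == c2)
      sp <- params$items$severity[[c2]]
      comp <- if (length(sp$w) == 1L) rep(1L, length(idx)) else
        sample.int(length(sp$w), length(idx), replace = TRUE, prob = sp$w)
      sev[idx] <- rnorm(length(idx), sp$mean[comp], sp$sd[comp])
    }

    n_items <- length(params$items$loading)
    responses <- matrix(NA_integer_, n, n_items)
    for (i in seq_len(n_items)) {
      k_asd <- length(params$items$base$asd[[i]])
      prob <- matrix(0, n, k_asd)
      for (c2 in c("asd", "other")) {
        idx <- cls == c2
        base <- params$items$base[[c2]][[i]]
        # exponential tilt toward code 0 for high-severity subjects
        tilt <- exp(outer(-params$items$loading[i] * sev[idx],
                          seq_len(k_asd) - 1L))
        w <- sweep(tilt, 2L, base, `*`)
        prob[idx, ] <- w / rowSums(w)
      }
      responses[, i] <- sample_categorical(prob)
    }
    na_mask <- matrix(runif(n * n_items) < params$items$na_fraction, n, n_items)
    responses[na_mask] <- NA_integer_

    out <- tibble(
      subject_id = sprintf("S%05d", seq_len(n)),
      true_label = ifelse(asd, "ASD", "nonASD"))
    for (i in seq_len(n_items)) out[[paste0("item_", i)]] <- responses[, i]
    out$age_years <- age
    out$sex <- sex
    out$nonverbal_iq <- iq
    out$verbal_status <- verbal
    out$severity <- sev
    out
  })
}

#' Monte-Carlo operating characteristics of a tree under a generative model
#'
#' Simulates a large fresh cohort from `params` and measures the tree's
#' population-scale sensitivity and specificity, with binomial standard
#' errors. Serves as the oracle that cross-validated estimates on small
#' cohorts are compared against.
#'
#' @param params A [cohort_params()].
#' @param tree An [adtree()] to evaluate.
#' @param n_large Monte-Carlo sample size (default 50,000; at least 10,000
#'   recommended for stable estimates).
#' @param seed Seed for the Monte-Carlo draw.
#' @return One-row tibble: `sensitivity`, `specificity`, their standard
#'   errors, and the class sizes used.
#' @export
ideal_performance <- function(params, tree, n_large = 50000, seed = 1) {
  p <- params
  p$n <- as.integer(n_large)
  cohort <- simulate_cohort(p, seed = seed)
  sc <- adtree_score(tree, cohort)
  pos <- classify_score(sc) == "positive"
  is_asd <- cohort$true_label == "ASD"
  sens <- mean(pos[is_asd])
  spec <- mean(!pos[!is_asd])
  tibble(
    sensitivity = sens,
    specificity = spec,
    se_sensitivity = sqrt(sens * (1 - sens) / sum(is_asd)),
    se_specificity = sqrt(spec * (1 - spec) / sum(!is_asd)),
    n_asd = sum(is_asd), n_other = sum(!is_asd))
}
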