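# Diagnostic test accuracy for a dichotomous screen against a clinical
# reference diagnosis: 2x2 construction, sensitivity / specificity /
# predictive values, Wald binomial confidence intervals, Yates-corrected
# chi-square, and stratified reports.

#' Build a 2x2 confusion table
#'
#' Cross-tabulates screen result against clinical diagnosis. `confusion()`
#' works on a data frame of paired columns; `confusion_table()` constructs
#' the table directly from the four counts.
#'
#' @param data Data frame with one row per subject.
#' @param truth Column holding the clinical diagnosis (tidy-eval).
#' @param screen Column holding the screen result (tidy-eval).
#' @param positive Value of `truth` denoting a clinical ASD diagnosis.
#' @param screen_positive Value of `screen` denoting a screen-positive
#'   result.
#' @return An object of class `confusion_table` with integer fields `tp`,
#'   `fp`, `fn`, `tn`.
#' @examples
#' confusion_table(tp = 62, fp = 31, fn = 7, tn = 122)
#' @export
confusion <- function(data, truth = clinical_label, screen = risk_class,
                      positive = "ASD", screen_positive = "positive") {
  truth_v <- dplyr::pull(data, {{ truth }})
  screen_v <- dplyr::pull(data, {{ screen }})
  if (length(truth_v) == 0L) {
    abort("Cannot build a confusion table from zero records.",
          class = "adscreen_input_error")
  }
  if (anyNA(truth_v) || anyNA(screen_v)) {
    abort("Labels and screen results must be non-missing.",
          class = "adscreen_input_error")
  }
  ct <- confusion_table_counts(as.character(truth_v) == positive,
                               as.character(screen_v) == screen_positive)
  confusion_table(ct$tp, ct$fp, ct$fn, ct$tn)
}

confusion_table_counts <- function(truth_pos, screen_pos) {
  if (length(truth_pos) != length(screen_pos)) {
    abort("Labels and screen results differ in length.",
          class = "adscreen_input_error")
  }
  list(tp = sum(truth_pos & screen_pos),
       fp = sum(!truth_pos & screen_pos),
       fn = sum(truth_pos & !screen_pos),
       tn = sum(!truth_pos & !screen_pos))
}

#' @param tp,fp,fn,tn Non-negative integer counts (screen positive/negative
#'   crossed with clinical ASD / non-ASD).
#' @rdname confusion
#' @export
confusion_table <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    abort("Confusion counts must be non-negative integers.",
          class = "adscreen_input_error")
  }
  if (sum(counts) == 0) {
    abort("Confusion table is empty (N = 0).", class = "adscreen_input_error")
  }
  structure(as.list(as.integer(counts)) |> setNames(names(counts)),
            class = "confusion_table")
}

#' @export
print.confusion_table <- function(x, ...) {
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(screen = c("positive", "negative"),
                              diagnosis = c("ASD", "non-ASD")))
  print(m)
  invisible(x)
}

#' @export
as_tibble.confusion_table <- function(x, ...) {
  tibble(tp = x$tp, fp = x$fp, fn = x$fn, tn = x$tn)
}

# ---------------------------------------------------------------------------
# Point metrics

check_ct <- function(t) {
  if (!inherits(t, "confusion_table")) {
    abort("Expected a `confusion_table`.", class = "adscreen_input_error")
  }
}

metric_ratio <- function(num, den, what) {
  if (den == 0) {
    abort(paste0(what, " is undefined: its denominator is zero."),
          class = "adscreen_undefined_metric")
  }
  num / den
}

#' Sensitivity, specificity and predictive values of a 2x2 table
#'
#' Sensitivity is the proportion of clinically diagnosed subjects who
#' screened positive, `TP / (TP + FN)`; specificity the proportion of
#' non-diagnosed subjects who screened negative, `TN / (TN + FP)`. The
#' positive (negative) predictive value is the probability that a positive
#' (negative) screen matches the clinical diagnosis: `TP / (TP + FP)` and
#' `TN / (TN + FN)`. All are returned as raw proportions; a zero denominator
#' raises an undefined-metric error rather than returning 0.
#'
#' @param t A [confusion_table()].
#' @return A proportion in `[0, 1]`.
#' @examples
#' t <- confusion_table(tp = 62, fp = 31, fn = 7, tn = 122)
#' sensitivity(t)   # 0.8986
#' specificity(t)   # 0.7974
#' ppv(t)           # 0.667
#' npv(t)           # 0.946
#' @export
sensitivity <- function(t) {
  check_ct(t); metric_ratio(t$tp, t$tp + t$fn, "Sensitivity")
}

#' @rdname sensitivity
#' @export
specificity <- function(t) {
  check_ct(t); metric_ratio(t$tn, t$tn + t$fp, "Specificity")
}

#' @rdname sensitivity
#' @export
ppv <- function(t) {
  check_ct(t); metric_ratio(t$tp, t$tp + t$fp, "Positive predictive value")
}

#' @rdname sensitivity
#' @export
npv <- function(t) {
  check_ct(t); metric_ratio(t$tn, t$tn + t$fn, "Negative predictive value")
}

# ---------------------------------------------------------------------------
# Confidence intervals

#' Wald binomial confidence interval for a proportion
#'
#' The normal-approximation (Wald) interval `p +/- z * sqrt(p (1 - p) / n)`,
#' truncated to `[0, 1]`. This is the interval construction whose bounds
#' match the published accuracy intervals for this screener; note its
#' well-known degenerate behaviour at `p = 0` or `1`, where the interval has
#' zero width. Wilson and Clopper-Pearson intervals are available behind the
#' `method` flag for users who prefer better small-sample coverage.
#'
#' @param p_hat Observed proportion(s) in `[0, 1]`.
#' @param n Denominator(s), at least 1.
#' @param z Critical value (default 1.96 for a 95% interval).
#' @param method `"wald"` (default), `"wilson"` or `"clopper-pearson"`.
#' @return A tibble with columns `estimate`, `lower`, `upper`, `n`, `z`.
#' @examples
#' wald_ci(62 / 69, 69)    # [0.827, 0.970]
#' wald_ci(122 / 153, 153) # [0.734, 0.861]
#' @export
wald_ci <- function(p_hat, n, z = 1.96,
                    method = c("wald", "wilson", "clopper-pearson")) {
  method <- match.arg(method)
  if (any(n < 1)) abort("`n` must be at least 1.", class = "adscreen_input_error")
  if (any(p_hat < 0 | p_hat > 1)) {
    abort("`p_hat` must lie in [0, 1].", class = "adscreen_input_error")
  }
  bounds <- switch(method,
    wald = {
      half <- z * sqrt(p_hat * (1 - p_hat) / n)
      list(lower = p_hat - half, upper = p_hat + half)
    },
    wilson = {
      centre <- (p_hat + z^2 / (2 * n)) / (1 + z^2 / n)
      half <- z * sqrt(p_hat * (1 - p_hat) / n + z^2 / (4 * n^2)) / (1 + z^2 / n)
      list(lower = centre - half, upper = centre + half)
    },
    `clopper-pearson` = {
      alpha <- 2 * stats::pnorm(-z)
      x <- round(p_hat * n)
      list(lower = ifelse(x == 0, 0, stats::qbeta(alpha / 2, x, n - x + 1)),
           upper = ifelse(x == n, 1, stats::qbeta(1 - alpha / 2, x + 1, n - x)))
    })
  tibble(estimate = p_hat,
         lower = pmax(bounds$lower, 0),
         upper = pmin(bounds$upper, 1),
         n = as.integer(n), z = z)
}

# percent with 1 decimal, the precision used for headline estimates
fmt_pct <- function(p, digits = 1) sprintf(paste0("%.", digits, "f"), 100 * p)

# ---------------------------------------------------------------------------
# Chi-square tests

#' Chi-square tests of screen result against diagnosis
#'
#' `yates_chi2()` applies the continuity-corrected statistic
#' `N (max(|TP*TN - FP*FN| - N/2, 0))^2 / ((TP+FP)(FN+TN)(TP+FN)(FP+TN))`
#' with a chi-square reference distribution on 1 degree of freedom;
#' `pearson_chi2()` is the uncorrected version (no `N/2` term).
#'
#' @param t A [confusion_table()] with all four marginals positive.
#' @return A tibble with columns `statistic`, `df`, `p_value`, `method`.
#' @examples
#' yates_chi2(confusion_table(62, 31, 7, 122))
#' @export
yates_chi2 <- function(t) chi2_impl(t, correct = TRUE)

#' @rdname yates_chi2
#' @export
pearson_chi2 <- function(t) chi2_impl(t, correct = FALSE)

chi2_impl <- function(t, correct) {
  check_ct(t)
  n <- t$tp + t$fp + t$fn + t$tn
  marg <- c(t$tp + t$fp, t$fn + t$tn, t$tp + t$fn, t$fp + t$tn)
  if (any(marg == 0)) {
    abort("Chi-square test undefined: a table marginal is zero.",
          class = "adscreen_undefined_test")
  }
  num <- abs(t$tp * t$tn - t$fp * t$fn)
  if (correct) num <- max(num - n / 2, 0)
  stat <- n * num^2 / prod(marg)
  tibble(statistic = stat, df = 1L,
         p_value = pchisq(stat, df = 1L, lower.tail = FALSE),
         method = if (correct) "yates" else "pearson")
}

# ---------------------------------------------------------------------------
# Whole-sample report

#' Whole-sample diagnostic accuracy report
#'
#' Computes the full set of published-style accuracy statistics from paired
#' clinical diagnoses and screen results: the 2x2 table, sensitivity and
#' specificity with Wald 95% confidence intervals, predictive values, and
#' the Yates-corrected chi-square test of screen against diagnosis.
#'
#' @inheritParams confusion
#' @param z Critical value for the confidence intervals (default 1.96).
#' @param ci_method Interval construction, see [wald_ci()].
#' @return An object of class `screen_accuracy`: list with `confusion`
#'   (a [confusion_table()]), `metrics` (tibble: metric, estimate, lower,
#'   upper, n) and `chi2` (tibble from [yates_chi2()], `NULL` when a marginal
#'   is zero).
#' @export
accuracy_report <- function(data, truth = clinical_label, screen = risk_class,
                            positive = "ASD", screen_positive = "positive",
                            z = 1.96, ci_method = "wald") {
  ct <- confusion(data, {{ truth }}, {{ screen }},
                  positive = positive, screen_positive = screen_positive)
  metric_row <- function(name, num, den) {
    if (den == 0) {
      return(tibble(metric = name, estimate = NA_real_, lower = NA_real_,
                    upper = NA_real_, n = 0L))
    }
    ci <- wald_ci(num / den, den, z = z, method = ci_method)
    tibble(metric = name, estimate = ci$estimate, lower = ci$lower,
           upper = ci$upper, n = as.integer(den))
  }
  metrics <- bind_rows(
    metric_row("sensitivity", ct$tp, ct$tp + ct$fn),
    metric_row("specificity", ct$tn, ct$tn + ct$fp),
    metric_row("ppv", ct$tp, ct$tp + ct$fp),
    metric_row("npv", ct$tn, ct$tn + ct$fn))
  chi2 <- tryCatch(yates_chi2(ct),
                   adscreen_undefined_test = function(e) NULL)
  structure(list(confusion = ct, metrics = metrics, chi2 = chi2,
                 z = z, ci_method = ci_method),
            class = "screen_accuracy")
}

#' @export
print.screen_accuracy <- function(x, ...) {
  cat("Screen accuracy (N =",
      x$confusion$tp + x$confusion$fp + x$confusion$fn + x$confusion$tn, ")\n")
  print(x$confusion)
  m <- x$metrics
  for (i in seq_len(nrow(m))) {
    if (is.na(m$estimate[i])) {
      cat(sprintf("  %-12s undefined (empty denominator)\n", m$metric[i]))
    } else if (m$metric[i] %in% c("sensitivity", "specificity")) {
      cat(sprintf("  %-12s %s%% [%s, %s]  (n = %d)\n", m$metric[i],
                  fmt_pct(m$estimate[i]), fmt_pct(m$lower[i]),
                  fmt_pct(m$upper[i]), m$n[i]))
    } else {
      cat(sprintf("  %-12s %.2f  (n = %d)\n", m$metric[i], m$estimate[i], m$n[i]))
    }
  }
  if (!is.null(x$chi2)) {
    cat(sprintf("  chi-square (Yates) = %.2f, p %s\n", x$chi2$statistic,
                if (x$chi2$p_value < 1e-4) "< 0.0001"
                else sprintf("= %.4f", x$chi2$p_value)))
  }
  invisible(x)
}

#' @rdname accuracy_report
#' @param x A `screen_accuracy` object.
#' @param ... Unused.
#' @export
tidy.screen_accuracy <- function(x, ...) x$metrics

#' @rdname accuracy_report
#' @export
glance.screen_accuracy <- function(x, ...) {
  wide <- x$metrics |>
    select("metric", "estimate") |>
    tidyr::pivot_wider(names_from = "metric", values_from = "estimate")
  bind_cols(as_tibble(x$confusion), wide,
            tibble(chi2_yates = x$chi2$statistic %||% NA_real_,
                   chi2_p = x$chi2$p_value %||% NA_real_))
}

# ---------------------------------------------------------------------------
# Stratified reports

#' Define a stratification stratum
#'
#' A stratum is a named membership predicate over subject covariates.
#' `predicate` receives the data frame and returns one logical per row;
#' `NA` marks a record whose covariate is missing, which is excluded from
#' the scheme (and counted) rather than silently dropped.
#'
#' @param name Display name of the stratum.
#' @param predicate Function `data -> logical`.
#' @return A `stratum_spec` object.
#' @seealso [age_strata()], [iq_strata()], [verbal_strata()]
#' @export
stratum_spec <- function(name, predicate) {
  stopifnot(is.character(name), is.function(predicate))
  structure(list(name = name, predicate = predicate), class = "stratum_spec")
}

#' Built-in stratification schemes
#'
#' The age bands (`< 3`, `3-6`, `> 6` years), non-verbal IQ bands (`< 70`,
#' `70-84`, `85-100`, `> 100`) and verbal-status split used in clinical
#' accuracy tables for this screener.
#'
#' @param var Name of the covariate column.
#' @return A list of [stratum_spec()] objects.
#' @export
age_strata <- function(var = "age_years") {
  list(
    stratum_spec("age < 3", function(d) d[[var]] < 3),
    stratum_spec("age 3-6", function(d) d[[var]] >= 3 & d[[var]] <= 6),
    stratum_spec("age > 6", function(d) d[[var]] > 6))
}

#' @rdname age_strata
#' @export
iq_strata <- function(var = "nonverbal_iq") {
  list(
    stratum_spec("iq < 70", function(d) d[[var]] < 70),
    stratum_spec("iq 70-84", function(d) d[[var]] >= 70 & d[[var]] < 85),
    stratum_spec("iq 85-100", function(d) d[[var]] >= 85 & d[[var]] <= 100),
    stratum_spec("iq > 100", function(d) d[[var]] > 100))
}

#' @rdname age_strata
#' @export
verbal_strata <- function(var = "verbal_status") {
  list(
    stratum_spec("verbal", function(d) d[[var]] == "verbal"),
    stratum_spec("non-verbal", function(d) d[[var]] == "non-verbal"))
}

#' Stratified accuracy report
#'
#' Computes sensitivity and specificity with confidence intervals within
#' each stratum of a scheme, one row per stratum in declaration order.
#' Strata must be disjoint; records whose stratification covariate is
#' missing are excluded from the scheme and their number is reported in the
#' `n_excluded` attribute. Metrics whose denominator is empty in a stratum
#' are reported as `NA` (undefined), never as 0.
#'
#' @inheritParams accuracy_report
#' @param scheme List of [stratum_spec()] objects (e.g. [age_strata()]).
#' @return A tibble of class `stratified_report`: `stratum`, `n`, `n_asd`,
#'   confusion counts, sensitivity / specificity and their interval bounds;
#'   attribute `n_excluded` counts records missing the covariate.
#' @export
stratified_report <- function(data, scheme, truth = clinical_label,
                              screen = risk_class, positive = "ASD",
                              screen_positive = "positive", z = 1.96,
                              ci_method = "wald") {
  membership <- vapply(scheme, function(s) {
    m <- s$predicate(data)
    if (length(m) != nrow(data)) {
      abort("A stratum predicate returned the wrong length.",
            class = "adscreen_config_error")
    }
    m
  }, logical(nrow(data)))
  membership <- matrix(membership, nrow = nrow(data))
  hits <- rowSums(membership, na.rm = TRUE)
  if (any(hits > 1)) {
    abort("Strata overlap: some records match more than one stratum.",
          class = "adscreen_config_error")
  }
  excluded <- apply(membership, 1L, anyNA)
  truth_v <- as.character(dplyr::pull(data, {{ truth }}))
  screen_v <- as.character(dplyr::pull(data, {{ screen }}))

  rows <- imap(scheme, function(s, i) {
    in_s <- !excluded & !is.na(membership[, i]) & membership[, i]
    ct <- confusion_table_counts(truth_v[in_s] == positive,
                                 screen_v[in_s] == screen_positive)
    ci_of <- function(num, den) {
      if (den == 0) return(tibble(estimate = NA_real_, lower = NA_real_,
                                  upper = NA_real_))
      wald_ci(num / den, den, z = z, method = ci_method)[, 1:3]
    }
    sens <- ci_of(ct$tp, ct$tp + ct$fn)
    spec <- ci_of(ct$tn, ct$tn + ct$fp)
    tibble(stratum = s$name, n = sum(in_s),
           n_asd = ct$tp + ct$fn,
           tp = ct$tp, fp = ct$fp, fn = ct$fn, tn = ct$tn,
           sensitivity = sens$estimate, sens_lower = sens$lower,
           sens_upper = sens$upper,
           specificity = spec$estimate, spec_lower = spec$lower,
           spec_upper = spec$upper)
  })
  out <- bind_rows(rows)
  attr(out, "n_excluded") <- sum(excluded)
  class(out) <- c("stratified_report", class(out))
  out
}

#' Format a stratified report the way accuracy tables print it
#'
#' @param report A [stratified_report()].
#' @param digits Decimal places for the percentages.
#' @return A tibble with `stratum`, `n`, `n_asd` and formatted
#'   `percent [lower-upper]` strings for sensitivity and specificity.
#' @export
format_stratified <- function(report, digits = 1) {
  fmt <- function(est, lo, hi) {
    ifelse(is.na(est), "undefined",
           sprintf("%s [%s-%s]", fmt_pct(est, digits),
                   fmt_pct(lo, digits), fmt_pct(hi, digits)))
  }
  tibble(stratum = report$stratum, n = report$n, n_asd = report$n_asd,
         sensitivity = fmt(report$sensitivity, report$sens_lower,
                           report$sens_upper),
         specificity = fmt(report$specificity, report$spec_lower,
                           report$spec_upper))
}

#' Plot a stratified accuracy report
#'
#' @param object A [stratified_report()].
#' @param ... Unused.
#' @return A ggplot of per-stratum sensitivity and specificity with their
#'   confidence intervals.
#' @export
autoplot.stratified_report <- function(object, ...) {
  long <- bind_rows(
    tibble(stratum = object$stratum, metric = "sensitivity",
           estimate = object$sensitivity, lower = object$sens_lower,
           upper = object$sens_upper),
    tibble(stratum = object$stratum, metric = "specificity",
           estimate = object$specificity, lower = object$spec_lower,
           upper = object$spec_upper)) |>
    filter(!is.na(.data$estimate))
  long$stratum <- factor(long$stratum, levels = unique(object$stratum))
  ggplot(long, aes(x = .data$stratum, y = .data$estimate)) +
    geom_pointrange(aes(ymin = .data$lower, ymax = .data$upper)) +
    facet_wrap(~metric) +
    coord_flip() +
    labs(x = NULL, y = "Proportion", title = "Stratified screen accuracy") +
    theme_minimal()
}
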