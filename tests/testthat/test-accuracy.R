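# The reconstructed whole-sample 2x2: 69 clinically diagnosed subjects of
# whom 7 screened negative; 153 without the diagnosis of whom 31 screened
# positive.
study_table <- function() confusion_table(tp = 62, fp = 31, fn = 7, tn = 122)

study_records <- function() {
  tibble::tibble(
    clinical_label = rep(c("ASD", "nonASD"), c(69, 153)),
    risk_class = c(rep(c("positive", "negative"), c(62, 7)),
                   rep(c("positive", "negative"), c(31, 122))))
}

test_that("confusion tables cross-tabulate screen result against diagnosis", {
  ct <- confusion(study_records())
  expect_equal(tibble::as_tibble(ct),
               tibble::tibble(tp = 62L, fp = 31L, fn = 7L, tn = 122L))
  expect_error(confusion(study_records()[0, ]), class = "adscreen_input_error")
  concordant <- tibble::tibble(clinical_label = c("ASD", "nonASD"),
                               risk_class = c("positive", "negative"))
  ct2 <- confusion(concordant)
  expect_equal(ct2$fp + ct2$fn, 0L)
  expect_error(confusion_table(-1, 0, 0, 5), class = "adscreen_input_error")
})

test_that("point metrics reproduce the published whole-sample values", {
  t <- study_table()
  expect_equal(round(100 * sensitivity(t), 2), 89.86)
  expect_equal(round(100 * specificity(t), 2), 79.74)
  expect_equal(round(ppv(t), 2), 0.67)
  expect_equal(round(npv(t), 2), 0.95)
  # non-verbal subgroup: 3 of 4 non-ASD subjects screened positive
  expect_equal(specificity(confusion_table(tp = 13, fp = 3, fn = 0, tn = 1)),
               0.25)
  expect_error(sensitivity(confusion_table(0, 5, 0, 5)),
               class = "adscreen_undefined_metric")
  expect_error(ppv(confusion_table(0, 0, 3, 5)),
               class = "adscreen_undefined_metric")
})

test_that("complements and Bayes identities hold on arbitrary tables", {
  withr::with_seed(14, {
    for (i in 1:25) {
      t <- confusion_table(sample(1:50, 1), sample(1:50, 1),
                           sample(1:50, 1), sample(1:50, 1))
      n <- t$tp + t$fp + t$fn + t$tn
      fnr <- t$fn / (t$tp + t$fn)
      fpr <- t$fp / (t$tn + t$fp)
      expect_equal(sensitivity(t) + fnr, 1)
      expect_equal(specificity(t) + fpr, 1)
      prev <- (t$tp + t$fn) / n
      expect_equal(ppv(t),
                   sensitivity(t) * prev /
                     (sensitivity(t) * prev + (1 - specificity(t)) * (1 - prev)),
                   tolerance = 1e-12)
      expect_equal(npv(t),
                   specificity(t) * (1 - prev) /
                     (specificity(t) * (1 - prev) + (1 - sensitivity(t)) * prev),
                   tolerance = 1e-12)
    }
  })
})

test_that("Wald intervals reproduce the published bounds", {
  sens_ci <- wald_ci(62 / 69, 69)
  expect_equal(round(100 * sens_ci$lower, 1), 82.7)
  expect_equal(round(100 * sens_ci$upper, 1), 97.0)
  spec_ci <- wald_ci(122 / 153, 153)
  expect_equal(round(100 * spec_ci$lower, 1), 73.4)
  expect_equal(round(100 * spec_ci$upper, 1), 86.1)
  # subgroup cells printed at integer precision
  small <- wald_ci(5 / 8, 8)
  expect_equal(round(100 * small$lower), 29)
  expect_equal(round(100 * small$upper), 96)
  degenerate <- wald_ci(7 / 7, 7)
  expect_equal(degenerate$lower, 1)
  expect_equal(degenerate$upper, 1)  # zero width at p = 1
})

test_that("Wald interval width shrinks with n and truncates to [0, 1]", {
  widths <- vapply(c(10, 40, 160, 640), function(n) {
    ci <- wald_ci(0.3, n)
    ci$upper - ci$lower
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  low_n <- wald_ci(0.05, 10)
  expect_gte(low_n$lower, 0)
  expect_lte(wald_ci(0.97, 10)$upper, 1)
  expect_error(wald_ci(0.5, 0), class = "adscreen_input_error")
  expect_error(wald_ci(1.2, 10), class = "adscreen_input_error")
  # alternative constructions are available and differ at small n
  expect_gt(wald_ci(7 / 7, 7, method = "wilson")$lower, 0.5)
  expect_lt(wald_ci(7 / 7, 7, method = "wilson")$lower, 1)
  expect_lt(wald_ci(7 / 7, 7, method = "clopper-pearson")$lower, 1)
})

test_that("Yates chi-square matches stats::chisq.test on random tables", {
  withr::with_seed(90, {
    for (i in 1:50) {
      t <- confusion_table(sample(1:60, 1), sample(1:60, 1),
                           sample(1:60, 1), sample(1:60, 1))
      m <- matrix(c(t$tp, t$fn, t$fp, t$tn), 2)
      ours <- yates_chi2(t)
      ref <- suppressWarnings(stats::chisq.test(m, correct = TRUE))
      expect_equal(ours$statistic, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(ours$p_value, ref$p.value, tolerance = 1e-10)
      # continuity correction can only shrink the statistic
      expect_lte(ours$statistic, pearson_chi2(t)$statistic + 1e-12)
    }
  })
})

test_that("degenerate chi-square cases behave as documented", {
  # identical row proportions: correction floors the statistic at zero
  prop <- confusion_table(tp = 10, fp = 20, fn = 5, tn = 10)
  expect_equal(yates_chi2(prop)$statistic, 0)
  expect_error(yates_chi2(confusion_table(5, 5, 0, 0)),
               class = "adscreen_undefined_test")
})

test_that("whole-sample accuracy reports assemble every headline statistic", {
  acc <- accuracy_report(study_records())
  g <- glance(acc)
  expect_equal(round(100 * g$sensitivity, 2), 89.86)
  expect_equal(round(100 * g$specificity, 2), 79.74)
  expect_equal(round(g$ppv, 2), 0.67)
  expect_equal(round(g$npv, 2), 0.95)
  expect_equal(g$chi2_yates, 91.78, tolerance = 0.005)
  expect_lt(g$chi2_p, 1e-4)
  expect_equal(nrow(tidy(acc)), 4L)
})

# records spanning the age and IQ schemes, with some missing IQ
strata_records <- function() {
  withr::with_seed(26, {
    n <- 240
    tibble::tibble(
      clinical_label = sample(c("ASD", "nonASD"), n, TRUE, prob = c(0.3, 0.7)),
      risk_class = sample(c("positive", "negative"), n, TRUE),
      age_years = runif(n, 1.5, 16),
      nonverbal_iq = ifelse(runif(n) < 0.4, NA, round(runif(n, 45, 130))))
  })
}

test_that("stratified reports cover the declared strata in order", {
  rec <- strata_records()
  rep_age <- stratified_report(rec, age_strata())
  expect_equal(rep_age$stratum, c("age < 3", "age 3-6", "age > 6"))
  expect_equal(attr(rep_age, "n_excluded"), 0L)
  rep_iq <- stratified_report(rec, iq_strata())
  expect_equal(rep_iq$stratum, c("iq < 70", "iq 70-84", "iq 85-100", "iq > 100"))
  expect_equal(attr(rep_iq, "n_excluded"), sum(is.na(rec$nonverbal_iq)))
  expect_equal(sum(rep_iq$n), sum(!is.na(rec$nonverbal_iq)))
})

test_that("pooling a partitioning scheme reproduces the whole-sample table", {
  rec <- strata_records()
  rep_age <- stratified_report(rec, age_strata())
  whole <- confusion(rec)
  expect_equal(sum(rep_age$tp), whole$tp)
  expect_equal(sum(rep_age$fp), whole$fp)
  expect_equal(sum(rep_age$fn), whole$fn)
  expect_equal(sum(rep_age$tn), whole$tn)
})

test_that("undefined stratum metrics are NA, overlaps are rejected", {
  rec <- tibble::tibble(clinical_label = rep("ASD", 5),
                        risk_class = rep("positive", 5),
                        age_years = c(1, 2, 4, 7, 9))
  rep <- stratified_report(rec, age_strata())
  expect_true(all(is.na(rep$specificity)))   # no non-ASD members anywhere
  expect_equal(rep$sensitivity, c(1, 1, 1))
  overlapping <- list(
    stratum_spec("a", function(d) d$age_years < 5),
    stratum_spec("b", function(d) d$age_years < 3))
  expect_error(stratified_report(rec, overlapping),
               class = "adscreen_config_error")
})

test_that("formatted stratified rows read as percent [lower-upper]", {
  rec <- strata_records()
  f <- format_stratified(stratified_report(rec, age_strata()))
  expect_match(f$sensitivity[1], "^[0-9.]+ \\[[0-9.]+-[0-9.]+\\]$")
})
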