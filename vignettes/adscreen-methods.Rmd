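---
title: "Methods: alternating decision trees for brief autism screening"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: alternating decision trees for brief autism screening}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adscreen)
```

## The screening problem

`adscreen` models a Level 2 autism screen: a brief parent questionnaire
administered to children already referred for developmental or behavioral
concerns, whose job is to separate likely autism spectrum disorder (ASD)
from other developmental and behavioral conditions. The instrument has
seven questions about communication, social skills and behaviors, each with
4–5 ordered answer choices plus "not applicable". Answers are encoded as
consecutive integer codes from 0 (code 0 being the most atypical choice);
the codes, not the display labels, are what the model consumes.

## Scoring semantics

The classifier is an alternating decision tree (ADTree): a root prediction
node carrying a baseline contribution, below which test nodes (each holding
a predicate on one item) and further prediction nodes alternate. An
instance's score is the sum of the root value and of every prediction node
reached along paths whose predicates all evaluate true. Unlike an ordinary
decision tree, many paths can be active at once, so the score is an
additive combination of weak judgements rather than a single leaf value.

Conventions fixed by the package:

* **Orientation.** Negative scores are screen-positive for ASD; positive
  scores screen-negative. The magnitude of the score is the confidence of
  the classification — scores near 0 are low-confidence.
* **Score exactly 0.** The published cutoff defines only the strict signs.
  We classify 0 as screen-positive: a screening instrument at the decision
  boundary should err toward sensitivity. The rule is a documented,
  configurable argument (`classify_score(tie =)`), so the opposite
  convention is one keystroke away.
* **Missing answers.** A "not applicable" answer makes any predicate on
  that item unevaluable. We truncate the path at that test node:
  contributions already collected above it stand, nothing below it counts.
  This is the standard ADTree treatment of missing values; masking an item
  can therefore only remove contributions, never add any (a property the
  test suite checks).
* **Predicates.** Ordinal threshold predicates (`code <= cut`) are the
  default; membership predicates over answer-code sets are supported
  because real instruments sometimes collapse adjacent answer choices into
  a single branch.

## The boosting learner

Training follows the classical ADTree induction scheme. Instances carry
positive weights, initially equal. The root value is the smoothed log-odds
of the class balance, `1/2 log((W+ + eps)/(W- + eps))`, with the
screen-positive class mapped to the negative side. Each round scores every
candidate weak rule — a precondition (an existing prediction node) paired
with a threshold predicate — by the objective

`Z = 2 (sqrt(W+(p & c) W-(p & c)) + sqrt(W+(p & !c) W-(p & !c))) + W(rest)`

and attaches the minimiser, with two new prediction values computed as
smoothed log-odds of the class weights in the two branches. Weights then
update multiplicatively under exponential loss, so the recorded training
loss (`fit$history$exp_loss`) is exactly the total instance weight, and it
can never increase from round to round.

Numerical and procedural choices:

* **Candidate cuts** are midpoints between adjacent observed codes per
  item. Ordinal domains are tiny (4–5 codes), so the candidate set is
  exhaustive by construction.
* **Smoothing** `eps = 1` (Laplace-style) keeps prediction values finite
  in pure branches. It is exposed as a parameter.
* **Tie-breaking** is deterministic: candidates within `1e-10` of the
  minimal `Z` resolve by lowest item index, then lowest cut, then earliest
  precondition in insertion order. This, plus the absence of any RNG in
  training, makes training bit-reproducible for a given data set.
* **Missing values during training** mirror scoring: an instance that
  cannot evaluate a candidate predicate contributes its weight to neither
  branch; it joins the constant remainder term of `Z`.
* **Rounds.** The default of 20 rounds reproduces the published screener
  shape (20 decision nodes over 7 items). The stopping rule used to reach
  that count originally is not documented anywhere we can consult, so the
  round count is a plain parameter rather than an inferred criterion.
* **Degenerate inputs.** Single-class training data, all-constant items,
  and `rounds < 1` are rejected with typed errors rather than producing
  degenerate trees.

Scores are accumulated in double precision; test comparisons of scores use
an absolute tolerance of `1e-9`.

## Cross-validation protocol

Accuracy is estimated with k-fold cross-validation (default `k = 10`): the
data are divided evenly into folds, each fold is held out once while the
tree is trained on the remaining nine-tenths, and the held-out screen
results are pooled into a single out-of-fold confusion table. Fold
assignment is a seeded uniform shuffle followed by contiguous chunking;
by default the shuffle is stratified by class (shuffling within class and
dealing fold labels cyclically), which keeps fold sizes within one of each
other both overall and per class and protects small cohorts from
single-class training splits — any such split is still detected and
reported with its fold id.

Cross-validation here is an estimator of performance, not a model
constructor: the deliverable tree is retrained on the full data set with
`adtree_train()`. Descriptions of this family of screeners sometimes
conflate the two ("cross-validation resulted in a final classifier"); we
separate them because a single shipped model and an honest
generalization estimate are different artifacts.

## Diagnostic accuracy statistics

From the 2×2 table of screen result against clinical reference diagnosis,
the package computes sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`,
and predictive values `TP/(TP+FP)`, `TN/(TN+FN)`; zero denominators raise
an undefined-metric error (stratified reports show `NA`, never 0).

* **Confidence intervals** are Wald intervals `p ± z sqrt(p(1-p)/n)` with
  `z = 1.96`, truncated to `[0, 1]`. This is the construction whose bounds
  reproduce the published intervals for this screener exactly, including
  the degenerate zero-width interval at `p = 1`; Wilson and
  Clopper–Pearson intervals are available behind `method =` for users who
  prefer better small-sample coverage.
* **Chi-square** uses the Yates continuity correction,
  `N (max(|TP·TN − FP·FN| − N/2, 0))^2 / ((TP+FP)(FN+TN)(TP+FN)(FP+TN))`
  on 1 df. On the reconstructed whole-sample table the corrected statistic
  is 91.78 against a published 91.77 — the final-digit discrepancy is
  consistent with rounding or truncation at the source, and the uncorrected
  Pearson statistic (94.6) rules out the alternative reading. The package
  exposes both.
* **Stratified reports** use the published age bands (<3, 3–6, >6 years),
  non-verbal IQ bands (<70, 70–84, 85–100, >100) and verbal status. Strata
  must be disjoint; records with a missing stratification covariate are
  excluded from that scheme and counted explicitly, mirroring how clinical
  reports footnote missing IQ data.
* Estimates print as percents with one decimal; raw proportions are always
  available unrounded.

## The synthetic cohort generator

No clinical data ship with the package, so a generative model stands in for
a clinic cohort. Defaults emulate the published study population's
marginals: n = 222, 31% ASD prevalence, 76.1% male, log-normal ages
truncated to 16 months–17 years with class-specific medians (3.9 years ASD
vs 6.6 other; `sdlog` 0.61/0.43 chosen to match the reported interquartile
ranges), non-verbal IQ normal with means 87.5/95 and sd 15 with 105/222
missing at random, and verbal status mostly "verbal" with non-verbal
subjects concentrated in the ASD class (13 of 17).

Item responses come from per-class categorical base tables tied to a latent
severity scalar: each subject draws a severity from a class-specific normal
mixture, and each item's base probabilities are exponentially tilted toward
low (atypical) codes in proportion to `loading_i × severity`. The shared
scalar induces the within-subject correlation across items that real
questionnaires show.

The `"study_like"` preset is calibrated so that a 20-round tree trained on
a large cohort operates near the published headline (sensitivity ≈ 0.90,
specificity ≈ 0.80). Each class is a two-component mixture: a dominant,
well-separated component and a minority crossover component mirrored from
the other class (ASD: 94% at severity N(4.0, 0.6) plus 6% mild cases at
N(−0.8, 0.7); other: 80% at N(−0.8, 0.7) plus 20% ASD-resembling cases at
N(4.0, 0.6); loadings 1.2; 2% of answers "not applicable"). Two properties
motivated the mixture form. Substantively it matches the clinical picture:
the children a screener misses are a small subpopulation with mild
presentation, and its false positives are children with other conditions —
typically language delays — whose answers genuinely resemble ASD.
Statistically it places the decision boundary in a low-density valley, so
the trained tree's operating point is governed by the stable mixture
weights instead of knife-edge threshold placement; an earlier single-normal
calibration met the target on one seed but let the trained tree's
population sensitivity wander by ±6 points across cohort draws, which no
honest cross-validation estimate could track. `"separable"` (disjoint code
ranges per class) and `"uninformative"` (identical distributions) presets
bracket the easy and impossible regimes for testing.

What the generator does *not* emulate: real ADI-R-derived answer
distributions (restricted data), dependence between covariates and item
responses (age, IQ and verbal status are drawn conditionally on class but
do not influence the items), item-specific difficulty structure, and
informative missingness. Consequently, passing end-to-end tests shows the
pipeline is statistically coherent under a plausible generative model — it
does not validate the screener on real children.

## Problem sizes and reproducibility

The test-suite and acceptance-script checks run at deliberately modest
sizes: scoring oracles on ~125 random tree × instance pairs; exhaustive
score-range enumeration on 7-item trees over 3^7 response combinations
(the full 5^7 enumeration is equally exact, just slower); weak-rule
exhaustion on ≤12-instance fixtures; the end-to-end recovery check on a
5,000-subject cohort with a 50,000-subject Monte-Carlo oracle, where the
pooled out-of-fold sensitivity and specificity track the oracle within one
point on typical seeds (three points is the acceptance band). Every
stochastic step takes an explicit integer seed, fold plans echo their seed,
and artifacts written by the workflow commands embed the tool version,
seed, and a hash of the run configuration, so any output can be reproduced
byte-for-byte from its own header.

## Known limitations

* The published tree's exact node values are not printed anywhere (the
  figure in the source is explicitly approximate), so the *reference*
  screener cannot be reconstituted; the package ships the machinery, and
  users with access to the deployed model's values can serialize them via
  the JSON schema.
* Wald intervals misbehave at small n and extreme proportions (zero width
  at 0% or 100%); they are the default because they are what the published
  intervals used, not because they are recommended.
* Score magnitude is a confidence ordering, not a calibrated probability;
  no probability calibration is attempted.
* The post-hoc reanalysis excluding subjects with a prior ASD diagnosis
  (n = 191) is not reproducible from printed counts alone and is therefore
  out of scope.
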