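test_that("classification metrics match hand evaluation", {
  m <- classification_metrics(list(TP = 8, FN = 2, TN = 90, FP = 0))
  expect_equal(unname(m), c(0.8, 1.0, 1.0, 0.9, 8 / 9), tolerance = 1e-9)
  expect_equal(unname(m["f1"]), 0.88889, tolerance = 1e-5)
  perfect <- classification_metrics(list(TP = 5, FN = 0, TN = 10, FP = 0))
  expect_true(all(perfect == 1))
  chance <- classification_metrics(list(TP = 3, FN = 3, TN = 7, FP = 7))
  expect_equal(unname(chance["accuracy"]), 0.5)
})

test_that("metrics match per-sample counting on random predictions", {
  set.seed(51)
  for (i in 1:25) {
    n <- sample(20:200, 1)
    truth <- rbinom(n, 1, runif(1, 0.2, 0.8))
    pred <- rbinom(n, 1, runif(1, 0.2, 0.8))
    if (length(unique(truth)) < 2 || length(unique(pred)) < 2) next
    got <- classification_metrics(confusion_counts(truth, pred))
    expect_equal(got, naive_cls_metrics(truth, pred), tolerance = 1e-12)
  }
})

test_that("degenerate confusion denominators follow the documented rule", {
  # class absent, no false alarms: undefined-as-1
  m <- classification_metrics(list(TP = 0, FN = 0, TN = 50, FP = 0))
  expect_equal(unname(m[c("sensitivity", "precision")]), c(1, 1))
  # class absent but false positives exist
  m2 <- classification_metrics(list(TP = 0, FN = 0, TN = 40, FP = 10))
  expect_equal(unname(m2["sensitivity"]), 0)
})

test_that("MSE and VAF match their definitions", {
  y <- c(0, 1, 0, 1); yh <- c(0, 1, 0, 0)
  expect_equal(mse(y, yh), 0.25)
  expect_equal(vaf(y, yh), 0.0)
  expect_equal(mse(y, y), 0)
  expect_equal(vaf(y, y), 1)
  expect_equal(vaf(y, rep(mean(y), 4)), 0)
  expect_true(is.na(vaf(rep(0.5, 10), rnorm(10))))
})

test_that("VAF-MSE identity holds to 1e-12", {
  set.seed(52)
  for (i in 1:30) {
    n <- sample(10:500, 1)
    y <- runif(n); yh <- runif(n)
    expect_equal(vaf(y, yh), 1 - n * mse(y, yh) / sum((y - mean(y))^2),
                 tolerance = 1e-12)
  }
})

test_that("negative VAF values are flagged, never silently dropped", {
  s <- summarize_vaf(c(0.9, 0.8, -0.4, NA, 0.7))
  expect_equal(s$mean, 0.8)
  expect_equal(s$n_ignored, 1L)
  expect_equal(s$n_undefined, 1L)
  expect_equal(s$n, 3L)
})

test_that("stratified CV assigns every trial to exactly one fold", {
  trials <- fake_trials(duration = 80, step = 1, seed = 6)
  folds <- split_cv(trials, k = 5, seed = 2)
  expect_length(folds, length(trials))
  expect_true(all(folds %in% 1:5))
  expect_true(all(table(folds) >= 1))
  # stratification: each finger-state pattern spreads across folds
  strata <- vapply(trials, function(t) paste(t$finger_state, collapse = ""),
                   character(1))
  for (s in names(which(table(strata) >= 5)))
    expect_gte(length(unique(folds[strata == s])), 2L)
})

test_that("regression split is leakage-free with a sane train fraction", {
  trials <- fake_trials(duration = 103, window = 4, step = 1, seed = 7)
  expect_length(trials, 100L)
  sp <- split_regression(trials, frac = 0.8, n_blocks = 5, seed = 3)
  expect_equal(split_overlap(trials[sp$train], trials[sp$valid]), 0L)
  frac <- length(sp$train) / (length(sp$train) + length(sp$valid))
  expect_gte(frac, 0.75)
  expect_lte(frac, 0.85)
  expect_error(split_regression(trials[1:4], n_blocks = 5), "n >= n_blocks")
})

test_that("split leakage is zero across 100 random configurations", {
  set.seed(53)
  for (i in 1:100) {
    trials <- fake_trials(duration = sample(40:120, 1),
                          window = sample(c(2, 4), 1),
                          step = sample(c(0.5, 1, 2), 1),
                          rate = 20, seed = i)
    nb <- sample(4:10, 1)
    if (length(trials) < nb) next
    sp <- tryCatch(split_regression(trials, 0.8, nb, seed = i),
                   error = function(e) NULL)
    if (is.null(sp)) next
    expect_equal(split_overlap(trials[sp$train], trials[sp$valid]), 0L)
  }
})

test_that("paired comparisons respect ties, effects and Bonferroni", {
  set.seed(54)
  base <- runif(100)
  scores <- rbind(m1 = base, m2 = base, m3 = base + rnorm(100, 1.0, 0.1))
  out <- compare_models(scores, alpha = 0.05)
  self <- out[out$a == "m1" & out$b == "m2", ]
  expect_true(self$tie)
  expect_false(self$significant)
  shift <- out[out$a == "m1" & out$b == "m3", ]
  expect_true(shift$significant)
  expect_gt(abs(shift$t), 50)
  five <- matrix(rnorm(5 * 40), 5)
  out5 <- compare_models(five, alpha = 0.05)
  expect_equal(nrow(out5), 10L)
  expect_equal(unique(out5$threshold), 0.005)
})
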