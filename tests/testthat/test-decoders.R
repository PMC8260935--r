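test_that("baseline specs carry exactly the printed hyperparameters", {
  rfc <- build_baseline("rf", "classification")
  expect_equal(rfc$hyper$n_trees, 5L)
  expect_equal(rfc$hyper$max_depth, 3L)
  rfr <- build_baseline("rf", "regression")
  expect_equal(rfr$hyper$n_trees, 10L)
  expect_equal(rfr$hyper$max_depth, 3L)
  svc <- build_baseline("svm", "classification")
  expect_equal(svc$hyper$kernel, "rbf")
  expect_equal(svc$hyper$C, 1)
  svr <- build_baseline("svm", "regression")
  expect_equal(svr$hyper[c("kernel", "degree", "C")],
               list(kernel = "poly", degree = 3L, C = 1))
  mlr <- build_baseline("mlp", "regression")
  widths <- vapply(Filter(function(l) l[[1]] == "dense", mlr$layer_plan),
                   function(l) l$units, integer(1))
  expect_equal(widths, c(300L, 300L, 300L, 50L, 1L))
  mlc <- build_baseline("mlp", "classification")
  widths_c <- vapply(Filter(function(l) l[[1]] == "dense", mlc$layer_plan),
                     function(l) l$units, integer(1))
  expect_equal(widths_c[1], 200L)           # conv layer replaced by FC-200
  expect_equal(widths_c[-1], c(512L, 128L, 5L))
})

test_that("classifier reaches high held-out accuracy on separable sessions", {
  fx <- cls_session()
  sp <- fx$split
  cdata <- lapply(sp$train, function(i)
    list(x = fx$feats[[i]], y = fx$trials[[i]]$finger_state))
  cls <- train_classifier(model_spec("classification", "rf"), cdata,
                          train_config(seed = 7L))
  pr <- predict(cls, fx$feats[sp$valid])
  truth <- vapply(fx$trials[sp$valid], `[[`, integer(5), "finger_state")
  m <- per_finger_metrics(truth, pr$state)
  expect_true(all(m$accuracy >= 0.95))
})

test_that("all-rest labels trigger the degenerate-class rule", {
  fx <- cls_session()
  cdata <- lapply(fx$split$train[1:12], function(i)
    list(x = fx$feats[[i]], y = rep(0L, 5)))
  expect_warning(
    cls <- train_classifier(model_spec("classification", "rf"), cdata,
                            train_config(seed = 8L)),
    "single-class")
  pr <- predict(cls, fx$feats[1:6])
  expect_true(all(pr$state == 0L))
  truth <- matrix(0L, 5, 6)
  m <- per_finger_metrics(truth, pr$state)
  expect_true(all(m$accuracy == 1))     # degenerate rule: absent class, no errors
})

test_that("classifier training is deterministic given the seed", {
  fx <- cls_session()
  cdata <- lapply(fx$split$train[seq(1, 60, 2)], function(i)
    list(x = fx$feats[[i]], y = fx$trials[[i]]$finger_state))
  cfg <- train_config(max_epochs = 4L, seed = 11L)
  a <- train_classifier(model_spec("classification", "mlp"), cdata, cfg)
  b <- train_classifier(model_spec("classification", "mlp"), cdata, cfg)
  probe <- fx$feats[fx$split$valid[1:8]]
  expect_identical(predict(a, probe)$scores, predict(b, probe)$scores)
  expect_identical(a$history$loss, b$history$loss)
})

test_that("regressors recover a noiseless single-finger trajectory", {
  sc <- session_config(n_repetitions = 6L, snr_db = Inf, rng_seed = 103L)
  sess <- generate_session(sc, c("thumb", "rest"))
  rec <- bandlimit(sess$recording)
  trials <- cut_trials(rec, sess$trajectories, step_s = 0.5)
  stream <- feature_stream(rec)
  sp <- split_regression(trials, 0.8, n_blocks = 6L, seed = 9L)
  consts <- fit_normalizer(lapply(trials[sp$train], feature_matrix,
                                  stream = stream))
  feats <- lapply(trials, function(t)
    apply_normalizer(feature_matrix(t, stream = stream), consts))
  rdata <- nervedecodr:::regressor_data(trials[sp$train], feats[sp$train], 1L)
  reg <- train_regressor(model_spec("regression", "mlp"), rdata,
                         train_config(max_epochs = 30L, seed = 10L),
                         subset = "active_only", dof_id = 1L)
  va <- sp$valid[vapply(trials[sp$valid],
                        function(t) t$finger_state[1] == 1L, logical(1))]
  y <- unlist(lapply(trials[va], function(t) t$trajectory[1, ]))
  yh <- unlist(lapply(va, function(i) predict(reg, feats[[i]])))
  expect_gte(vaf(y, yh), 0.7)
  expect_true(all(yh >= 0 & yh <= 1))
})

test_that("an all-zero target trains to a near-zero prediction", {
  fx <- cls_session()
  idx <- fx$split$train[1:20]
  rdata <- lapply(idx, function(i)
    list(x = fx$feats[[i]], y = rep(0, 200), active = TRUE))
  reg <- train_regressor(model_spec("regression", "rf"), rdata,
                         train_config(seed = 12L), subset = "active_only")
  p <- predict(reg, fx$feats[[fx$split$valid[1]]])
  expect_lt(mse(rep(0, 200), p), 1e-4)
})

test_that("empty active subset errors; full subset weights the minority", {
  fx <- cls_session()
  idx <- fx$split$train[1:10]
  rdata <- lapply(idx, function(i)
    list(x = fx$feats[[i]], y = rep(0, 200), active = FALSE))
  expect_error(
    train_regressor(model_spec("regression", "rf"), rdata,
                    subset = "active_only"),
    "active_only subset is empty")
  # full subset runs with inverse-frequency weighting
  rdata[[1]]$active <- TRUE
  reg <- train_regressor(model_spec("regression", "rf"), rdata,
                         train_config(seed = 13L), subset = "full")
  expect_s3_class(reg, "nd_regressor")
  expect_equal(reg$subset, "full")
})

test_that("one-step class imbalance sits in the published 5:1-10:1 band", {
  fx <- tiny_session()
  # mixed-gesture session mimicking the protocol: equal repetitions of the
  # nine gestures, 4 s cycles alternating rest and flexion
  ratios <- vapply(1:10, function(dof) {
    rdata <- nervedecodr:::regressor_data(fx$trials, lapply(fx$trials,
      function(t) t$trajectory), dof)
    regression_class_ratio(rdata)
  }, numeric(1))
  expect_true(all(ratios >= 4 & ratios <= 11), label = paste(round(ratios, 2),
                                                             collapse = " "))
  expect_true(mean(ratios >= 5 & ratios <= 10) >= 0.8)
})
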