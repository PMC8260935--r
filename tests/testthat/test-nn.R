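check_gradients <- function(layers, x) {
  fw <- nervedecodr:::nn_forward(layers, x, train = FALSE)
  target <- fw$out * 0 + 0.3
  lossf <- function(xx)
    sum((nervedecodr:::nn_forward(layers, xx, train = FALSE)$out - target)^2)
  bw <- nervedecodr:::nn_backward(layers, fw$caches, 2 * (fw$out - target))
  worst <- max(abs(bw$dx - numeric_gradient(lossf, x)))
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    for (p in c("W", "b", "Wx", "Wh")) {
      if (is.null(ly[[p]])) next
      f_p <- function(v) {
        l2 <- layers
        l2[[li]][[p]][] <- v
        sum((nervedecodr:::nn_forward(l2, x, train = FALSE)$out - target)^2)
      }
      worst <- max(worst, max(abs(
        as.vector(bw$grads[[li]][[p]]) -
          numeric_gradient(f_p, as.vector(ly[[p]])))))
    }
  }
  worst
}

test_that("analytic gradients match finite differences for every layer kind", {
  set.seed(31)
  nd <- asNamespace("nervedecodr")
  expect_lt(check_gradients(
    list(nd$nn_conv1d(3, 4, 5, 2), nd$nn_relu(), nd$nn_flatten(),
         nd$nn_dense(16, 2)),
    array(rnorm(3 * 11 * 2), c(3, 11, 2))), 1e-6)
  expect_lt(check_gradients(
    list(nd$nn_lstm(3, 4), nd$nn_lstm(4, 1), nd$nn_squeeze()),
    array(rnorm(3 * 6 * 2), c(3, 6, 2))), 1e-6)
  expect_lt(check_gradients(
    list(nd$nn_lstm(3, 4), nd$nn_last_step(), nd$nn_dense(4, 2)),
    array(rnorm(3 * 6 * 2), c(3, 6, 2))), 1e-6)
})

test_that("loss gradients match finite differences", {
  set.seed(32)
  z <- matrix(rnorm(10), 5)
  y <- matrix(rbinom(10, 1, 0.5), 5)
  w <- c(0.3, 1.7)
  g_num <- numeric_gradient(function(v)
    nervedecodr:::loss_bce(matrix(v, 5), y, w)$loss, as.vector(z))
  expect_lt(max(abs(as.vector(nervedecodr:::loss_bce(z, y, w)$grad) - g_num)),
            1e-7)
  p <- matrix(rnorm(8), 4)
  t <- matrix(rnorm(8), 4)
  g_num <- numeric_gradient(function(v)
    nervedecodr:::loss_mse(matrix(v, 4), t, w)$loss, as.vector(p))
  expect_lt(max(abs(as.vector(nervedecodr:::loss_mse(p, t, w)$grad) - g_num)),
            1e-7)
})

test_that("plateau scheduler drops exactly tenfold after two flat epochs", {
  sch <- plateau_scheduler(lr_init = 0.005, factor = 10, patience = 2)
  lrs <- vapply(c(1.0, 0.9, 0.95, 0.96, 0.5, 0.6, 0.7), sch$step, numeric(1))
  # losses:         imp  imp  bad   bad -> drop; imp  bad  bad -> drop
  expect_equal(lrs, c(0.005, 0.005, 0.005, 0.0005, 0.0005, 0.0005, 5e-05))
  # non-increasing under arbitrary loss sequences
  set.seed(33)
  sch2 <- plateau_scheduler(0.1)
  seq2 <- vapply(runif(50), sch2$step, numeric(1))
  expect_true(all(diff(seq2) <= 0))
})

test_that("training is deterministic given a seed and records its schedule", {
  set.seed(34)
  xs <- lapply(1:30, function(i) rnorm(8))
  ys <- lapply(xs, function(x) sum(x[1:2]) * 0.3)
  cfg <- train_config(max_epochs = 6L, minibatch = 10L,
                      minibatches_per_epoch = 3L, seed = 99L)
  run <- function() nervedecodr:::with_seed(99L, {
    layers <- nervedecodr:::instantiate_plan(
      model_spec("regression", "mlp", c(8L, 1L)))
    nervedecodr:::nn_train(layers, xs, ys, cfg, nervedecodr:::loss_mse,
                           nervedecodr:::stack_vec, nervedecodr:::stack_vec)
  })
  a <- run(); b <- run()
  expect_identical(a$history$loss, b$history$loss)
  expect_identical(a$layers, b$layers)
  expect_equal(a$history$epoch, seq_len(nrow(a$history)))
  expect_true(all(diff(a$history$lr) <= 0))
})

test_that("layer and parameter audits match the published architecture table", {
  cls <- model_spec("classification", "cnn")
  expect_equal(layer_counts(cls), c(conv = 1L, lstm = 0L, fc = 3L))
  reg <- model_spec("regression", "rnn")
  expect_equal(layer_counts(reg), c(conv = 3L, lstm = 2L, fc = 0L))
  expect_equal(layer_counts(model_spec("regression", "cnn")),
               c(conv = 3L, lstm = 2L, fc = 0L))
  n_cls <- spec_param_count(cls)
  expect_gte(n_cls, 0.5 * 1465749)
  expect_lte(n_cls, 2.0 * 1465749)
  n_reg_total <- 10 * spec_param_count(reg)
  expect_gte(n_reg_total, 0.5 * 767200)
  expect_lte(n_reg_total, 2.0 * 767200)
})

test_that("regression output times tile the trial and interpolate back", {
  spec <- model_spec("regression", "rnn")
  ends <- nervedecodr:::conv_output_ends(spec)
  expect_true(all(diff(ends) == 8))     # stride 2 x 2 x 2
  expect_lte(max(ends), 200L)
  expect_gte(min(ends), 1L)
})
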