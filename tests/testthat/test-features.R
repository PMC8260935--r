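test_that("hand-computed values of the worked 4-sample window", {
  x <- c(1, -2, 3, -4)
  want <- c(ZC = 3, SSC = 2, WL = 15, WA = 2, MAB = 2.5, MSQ = 7.5,
            RMS = sqrt(7.5), V3 = -11^(1 / 3), LD = 24^(1 / 4),
            DABS = sqrt(83 / 3), MFL = 0.5 * log(83), MPR = 1,
            MAVS = -2, WMA = 2)
  for (f in FEATURES)
    expect_equal(compute_feature(f, x), unname(want[f]), tolerance = 1e-9,
                 label = f)
  # frozen decimals
  expect_equal(compute_feature("RMS", x), 2.738613, tolerance = 1e-6)
  expect_equal(compute_feature("V3", x), -2.223980, tolerance = 1e-6)
  expect_equal(compute_feature("LD", x), 2.213364, tolerance = 1e-6)
  expect_equal(compute_feature("DABS", x), 5.259911, tolerance = 1e-6)
  expect_equal(compute_feature("MFL", x), 2.209420, tolerance = 1e-6)
})

test_that("all 14 features match the naive oracle on 1000 random windows", {
  set.seed(21)
  worst <- 0
  for (rep in 1:1000) {
    n <- sample(c(4, 7, 32, 500), 1)
    x <- rnorm(n, sd = runif(1, 0.1, 10))
    if (rep %% 7 == 0) x[sample(n, 2)] <- 0       # exercise the LD floor
    blk <- nervedecodr:::feature_block(matrix(x, ncol = 1))
    for (f in FEATURES) {
      o <- naive_feature(f, x)
      expect_equal(compute_feature(f, x), o, tolerance = 1e-9, label = f)
      worst <- max(worst, abs(blk[f, 1] - o) / max(1, abs(o)))
    }
  }
  expect_lt(worst, 1e-9)
})

test_that("compiled kernel agrees with the scalar reference", {
  set.seed(22)
  x <- rnorm(3000)
  out <- nervedecodr:::window_features_cpp(x, 500L, 100L, 500L)
  for (j in c(1, 5, 26)) {
    w <- x[((j - 1) * 100 + 1):((j - 1) * 100 + 500)]  # window j's samples
    for (fi in seq_along(FEATURES))
      expect_equal(out[fi, j], compute_feature(FEATURES[fi], w),
                   tolerance = 1e-9, label = FEATURES[fi])
  }
})

test_that("MFL identity and constant-window degeneracies hold", {
  set.seed(23)
  for (i in 1:50) {
    x <- rnorm(sample(10:200, 1))
    n <- length(x)
    expect_equal(compute_feature("MFL", x),
                 log(compute_feature("DABS", x)) + 0.5 * log(n - 1),
                 tolerance = 1e-9)
  }
  const <- rep(3.7, 100)
  for (f in c("ZC", "SSC", "WL", "WA"))
    expect_equal(compute_feature(f, const), 0)
})

test_that("amplitude features scale linearly; counting features are gain-invariant", {
  set.seed(24)
  for (i in 1:20) {
    x <- rnorm(100)
    gain <- runif(1, 0.5, 20)
    for (f in c("MAB", "RMS", "WL", "DABS", "V3"))
      expect_equal(compute_feature(f, gain * x),
                   gain * compute_feature(f, x), tolerance = 1e-9, label = f)
    for (f in c("ZC", "SSC", "MPR", "WA"))
      expect_equal(compute_feature(f, gain * x), compute_feature(f, x),
                   label = f)
  }
})

test_that("a 4 s 16-channel 5 kHz trial yields a 224 x 200 matrix", {
  fx <- tiny_session()
  m <- feature_matrix(fx$trials[[3]])
  expect_equal(dim(m), c(224L, 200L))
  expect_equal(16L * 14L, 224L)
  expect_equal(4 / 0.020, 200)
})

test_that("matrix columns equal single-feature calls on the raw slices", {
  fx <- tiny_session()
  tr <- fx$trials[[10]]
  m <- feature_matrix(tr)
  set.seed(25)
  for (probe in 1:20) {
    t_col <- sample(200, 1)
    ch <- sample(16, 1)
    fi <- sample(14, 1)
    e <- tr$start - 1L + t_col * 100L
    s <- e - 499L
    w <- if (s >= 1) fx$recording$samples[ch, s:e]
         else c(numeric(1 - s), fx$recording$samples[ch, 1:e])
    expect_equal(m[(ch - 1) * 14 + fi, t_col],
                 compute_feature(FEATURES[fi], w), tolerance = 1e-9)
  }
})

test_that("early columns use real pre-trial context when available", {
  fx <- tiny_session()
  tr <- fx$trials[[8]]                      # has preceding samples
  expect_gt(tr$start, 1L)
  m_direct <- feature_matrix(tr)
  m_stream <- feature_matrix(tr, stream = fx$stream)
  expect_equal(m_direct, m_stream, tolerance = 1e-12)
})

test_that("all-zero trials produce null features except the floored logs", {
  rate <- 5000
  n <- 4 * rate
  rec <- nerve_recording(matrix(0, 16, n), rate)
  traj <- trajectory_set(matrix(0, 10, n), rate)
  tr <- cut_trials(rec, traj, 4, 4)[[1]]
  m <- feature_matrix(tr)
  idx <- function(f) seq(match(f, FEATURES), 224, by = 14)
  for (f in setdiff(FEATURES, c("LD", "MFL")))
    expect_true(all(m[idx(f), ] == 0), label = f)
  expect_true(all(abs(m[idx("LD"), ]) < 1e-11))
  expect_equal(unique(as.vector(m[idx("MFL"), ])), 0.5 * log(1e-12))
})

test_that("normalization constants are fixed, positive, per-feature", {
  fx <- tiny_session()
  mats <- lapply(fx$trials[seq(1, length(fx$trials), by = 7)],
                 feature_matrix, stream = fx$stream)
  consts <- fit_normalizer(mats)
  expect_length(consts, 14L)
  expect_true(all(consts > 0))
  normed <- lapply(mats, apply_normalizer, consts = consts)
  frac_in <- mean(vapply(normed, function(m) mean(abs(m) <= 1), numeric(1)))
  expect_gte(frac_in, 0.99)
  # leakage guard: applying stored constants to unseen data leaves them
  # untouched
  h0 <- config_hash(consts)
  invisible(apply_normalizer(feature_matrix(fx$trials[[2]]), consts))
  expect_identical(config_hash(consts), h0)
  # degenerate all-zero input floors, never zero constants
  z <- fit_normalizer(matrix(0, 224, 10))
  expect_true(all(z > 0))
})

test_that("feature stream refuses inconsistent window/step", {
  fx <- tiny_session()
  expect_error(feature_matrix(fx$trials[[1]], window_ms = 100, step_ms = 50),
               "80%")
  expect_error(feature_stream(fx$recording, 100, 33), "integer multiple")
})
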