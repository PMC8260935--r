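test_that("two-step gating zeroes inactive fingers exactly", {
  fx <- cls_session()
  regs <- gating_models()
  trial <- fx$trials[[fx$split$valid[2]]]
  feat <- fx$feats[[fx$split$valid[2]]]

  rest <- decode_2s(trial, stub_classifier(c(0, 0, 0, 0, 0)), regs, feat)
  expect_true(all(rest$trajectories == 0))
  expect_length(rest$models_invoked, 0L)
  expect_equal(rest$strategy, "2S")

  thumb <- decode_2s(trial, stub_classifier(c(1, 0, 0, 0, 0)), regs, feat)
  expect_equal(thumb$models_invoked, c(1L, 2L))
  expect_true(all(thumb$trajectories[3:10, ] == 0))

  pinch <- decode_2s(trial, stub_classifier(c(0, 0, 0, 1, 1)), regs, feat)
  expect_equal(sort(pinch$models_invoked), c(7L, 8L, 9L, 10L))
  expect_true(all(pinch$trajectories[1:6, ] == 0))
})

test_that("one-step decoding invokes all ten models and wiggles at rest", {
  fx <- cls_session()
  regs <- gating_models()
  rest_idx <- Filter(function(i) all(fx$trials[[i]]$finger_state == 0L),
                     seq_along(fx$trials))
  expect_gt(length(rest_idx), 0)
  r <- decode_1s(fx$trials[[rest_idx[1]]], regs, fx$feats[[rest_idx[1]]])
  expect_equal(r$models_invoked, 1:10)
  expect_equal(r$finger_state, rep(1L, 5))
  # the false-positive wiggle: small but generally nonzero outputs at rest
  expect_gt(max(r$trajectories), 0)
  expect_lt(mean(r$trajectories), 0.35)
  expect_error(decode_1s(fx$trials[[1]], c(regs[1:9], list(NULL)),
                         fx$feats[[1]]), "10 DOF")
})

test_that("2S with a perfect classifier equals 1S on active rows", {
  fx <- cls_session()
  regs <- gating_models()
  i <- Filter(function(i) fx$trials[[i]]$finger_state[1] == 1L,
              fx$split$valid)[1]
  trial <- fx$trials[[i]]
  perfect <- stub_classifier(trial$finger_state)
  r2 <- decode_2s(trial, perfect, regs, fx$feats[[i]])
  r1 <- decode_1s(trial, regs, fx$feats[[i]])
  act_dofs <- unlist(lapply(which(trial$finger_state == 1L),
                            function(f) c(2 * f - 1, 2 * f)))
  expect_equal(r2$trajectories[act_dofs, ], r1$trajectories[act_dofs, ])
  expect_true(all(r2$trajectories[setdiff(1:10, act_dofs), ] == 0))
})

test_that("rest-heavy sessions invoke fewer than 10 models per trial", {
  fx <- cls_session()
  regs <- gating_models()
  truth_states <- lapply(fx$split$valid, function(i)
    fx$trials[[i]]$finger_state)
  invoked <- vapply(seq_along(fx$split$valid), function(k) {
    i <- fx$split$valid[k]
    length(decode_2s(fx$trials[[i]], stub_classifier(truth_states[[k]]),
                     regs, fx$feats[[i]])$models_invoked)
  }, numeric(1))
  expect_lt(mean(invoked), 10)
})

test_that("feature-configuration mismatches are refused", {
  fx <- cls_session()
  regs <- gating_models()
  bad <- regs
  bad[[4]]$feature_hash <- "h2"
  expect_error(decode_1s(fx$trials[[1]], bad, fx$feats[[1]]),
               "hash mismatch")
})

test_that("majority-vote smoother flips isolated states only", {
  st <- rbind(c(0, 0, 1, 0, 0), matrix(0, 4, 5))
  sm <- smooth_states(st, k = 3L)
  expect_equal(sm[1, ], c(0, 0, 0, 0, 0))
  solid <- rbind(c(1, 1, 1, 1, 1), matrix(0, 4, 5))
  expect_equal(smooth_states(solid, 3L)[1, ], rep(1, 5))
  expect_error(smooth_states(st, 2L))
})

test_that("the multi-label head extends to gestures outside the codebook", {
  fx <- cls_session()
  # append a synthetic ring+middle combination unknown to the codebook
  extra <- gesture_code("middle_ring", c(0, 0, 1, 1, 0))
  cfg <- session_config(n_repetitions = 4L, snr_db = 30, rng_seed = 104L)
  sess <- generate_session(cfg, list(extra,
                                     nervedecodr:::lookup_gesture("rest")))
  rec <- bandlimit(sess$recording)
  trials <- cut_trials(rec, sess$trajectories, step_s = 0.5)
  stream <- feature_stream(rec)
  feats <- lapply(trials, function(t)
    apply_normalizer(feature_matrix(t, stream = stream), fx$consts))
  n <- length(trials)
  tr_i <- setdiff(seq_len(n), seq(1L, n, by = 3L))   # interleaved hold-out
  cdata <- lapply(tr_i, function(i)
    list(x = feats[[i]], y = trials[[i]]$finger_state))
  cls <- train_classifier(model_spec("classification", "rf"), cdata,
                          train_config(seed = 30L))
  va_i <- seq(1L, n, by = 3L)
  pr <- predict(cls, feats[va_i])
  truth <- vapply(trials[va_i], `[[`, integer(5), "finger_state")
  # the new combined state is recognized without any architecture change
  combo <- truth[3, ] == 1L & truth[4, ] == 1L
  expect_gt(mean(pr$state[3, combo] == 1L & pr$state[4, combo] == 1L), 0.8)
})
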