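# Shared synthetic fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# Small 9-gesture session (2 cycles each) used across files.
tiny_session <- function() cached("tiny", function() {
  cfg <- session_config(n_repetitions = 2L, snr_db = 20, rng_seed = 101L)
  sess <- generate_session(cfg)
  rec <- bandlimit(sess$recording)
  trials <- cut_trials(rec, sess$trajectories, step_s = 0.5)
  stream <- feature_stream(rec)
  consts <- fit_normalizer(stream)
  list(config = cfg, session = sess, recording = rec, trials = trials,
       stream = stream, consts = consts)
})

# High-SNR 3-gesture session for decoder tests.
cls_session <- function() cached("cls", function() {
  cfg <- session_config(n_repetitions = 6L, snr_db = 30, rng_seed = 102L)
  sess <- generate_session(cfg, c("thumb", "little", "rest"))
  rec <- bandlimit(sess$recording)
  trials <- cut_trials(rec, sess$trajectories, step_s = 0.5)
  stream <- feature_stream(rec)
  sp <- split_regression(trials, 0.8, n_blocks = 9L, seed = 5L)
  consts <- fit_normalizer(lapply(trials[sp$train], feature_matrix,
                                  stream = stream))
  feats <- lapply(trials, function(t)
    apply_normalizer(feature_matrix(t, stream = stream), consts))
  list(config = cfg, trials = trials, split = sp, feats = feats,
       consts = consts)
})

# Cheap fake trials (low rate, random smooth trajectories) for split and
# metric property tests; no signal content is needed.
fake_trials <- function(duration = 60, window = 4, step = 1, rate = 50,
                        seed = 1) {
  n <- round(duration * rate)
  set.seed(seed)
  rec <- nerve_recording(matrix(rnorm(16 * n), 16, n), rate)
  tr <- matrix(0, 10, n)
  for (d in 1:10) {
    phase <- runif(1, 0, 2 * pi)
    tr[d, ] <- pmax(0, sin(2 * pi * seq_len(n) / (8 * rate) + phase))
  }
  cut_trials(rec, trajectory_set(tr, rate), window, step,
             feature_step_s = 0.5)
}

# Small real random-forest regressors shared across gating tests.
gating_models <- function() cached("gating", function() {
  fx <- cls_session()
  lapply(1:10, function(dof) {
    rdata <- nervedecodr:::regressor_data(fx$trials[fx$split$train],
                                          fx$feats[fx$split$train], dof)
    r <- train_regressor(model_spec("regression", "rf"), rdata,
                         train_config(seed = 20L + dof), subset = "full",
                         dof_id = dof)
    r$feature_hash <- "h1"
    r
  })
})

# A classifier stub that always emits a fixed finger state.
stub_classifier <- function(state) {
  structure(list(spec = model_spec("classification", "rf"),
                 fit = lapply(state, function(s) list(constant = s)),
                 threshold = 0.5,
                 constant_outputs = as.numeric(state),
                 history = NULL),
            class = "nd_classifier")
}
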