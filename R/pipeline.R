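#' End-to-end run configuration
#'
#' One validated document collecting every stage's settings: simulation,
#' band-limiting, trial cutting, feature extraction, training, strategy
#' and split. `config_hash(cfg)` stamps all artifacts.
#'
#' @param gestures gesture names simulated (default: the full 9-gesture
#'   codebook)
#' @param n_repetitions cycles per gesture
#' @param snr_db simulation signal-to-noise ratio in dB
#' @param window_s,step_s trial window and increment in seconds
#' @param band pass-band in Hz, length 2
#' @param activity_threshold trajectory level defining an active DOF
#' @param classifier_family,regressor_family model families (see
#'   [model_spec()])
#' @param strategy `"2s"` or `"1s"`
#' @param train a [train_config()]
#' @param split_frac,split_blocks regression-split settings
#' @param seed master seed; stage seeds are derived from it
#' @export
run_config <- function(gestures = names(codebook()),
                       n_repetitions = 6L,
                       snr_db = 20,
                       window_s = 4, step_s = 0.5,
                       band = c(25, 600),
                       activity_threshold = 0.1,
                       classifier_family = "rf",
                       regressor_family = "rnn",
                       strategy = "2s",
                       train = train_config(max_epochs = 40L),
                       split_frac = 0.8, split_blocks = 5L,
                       seed = 1L) {
  fams <- c("cnn", "rnn", "svm", "rf", "mlp")
  if (!strategy %in% c("1s", "2s"))
    stop("invalid config field `strategy`: must be '1s' or '2s'",
         call. = FALSE)
  if (!classifier_family %in% fams)
    stop("invalid config field `classifier_family`", call. = FALSE)
  if (!regressor_family %in% fams)
    stop("invalid config field `regressor_family`", call. = FALSE)
  bad <- setdiff(gestures, names(codebook()))
  if (length(bad))
    stop("invalid config field `gestures`: unknown ", paste(bad, collapse = ", "),
         call. = FALSE)
  structure(list(gestures = gestures,
                 n_repetitions = as.integer(n_repetitions), snr_db = snr_db,
                 window_s = window_s, step_s = step_s, band = band,
                 activity_threshold = activity_threshold,
                 classifier_family = classifier_family,
                 regressor_family = regressor_family, strategy = strategy,
                 train = train, split_frac = split_frac,
                 split_blocks = as.integer(split_blocks),
                 seed = as.integer(seed)),
            class = "nd_run_config")
}

#' Demo-scale configuration
#'
#' A desk-scale pipeline (two gestures, random-forest classifier, MLP
#' regressors) that completes in minutes on one CPU.
#'
#' @param seed master seed
#' @export
demo_config <- function(seed = 1L) {
  run_config(gestures = c("thumb", "rest"), n_repetitions = 10L,
             classifier_family = "rf", regressor_family = "mlp",
             train = train_config(max_epochs = 25L, seed = seed),
             seed = seed)
}

# Normalized per-trial feature matrices, sliced from a session-level
# stream (identical to per-trial computation, but ~window/step times
# cheaper over overlapped trials).
trial_feature_list <- function(trials, stream, consts) {
  lapply(trials, function(tr)
    apply_normalizer(feature_matrix(tr, stream = stream), consts))
}

# Training data for one DOF's regressor.
regressor_data <- function(trials, feats, dof) {
  finger <- (dof + 1L) %/% 2L
  lapply(seq_along(trials), function(i)
    list(x = feats[[i]], y = trials[[i]]$trajectory[dof, ],
         active = trials[[i]]$finger_state[finger] == 1L))
}

#' Run the full decoding pipeline
#'
#' simulate -> band-limit -> cut trials -> extract features -> fit
#' normalizer (training split only) -> train classifier and 10 joint
#' regressors -> decode the held-out split -> evaluate. Every stage is
#' deterministic given the config; re-running an identical config
#' reproduces all outputs. Artifacts (results and metrics CSV/JSON) are
#' written under `out_dir` when given, stamped with the config digest and
#' seed.
#'
#' @param config a [run_config()]
#' @param out_dir optional output directory
#' @param quiet suppress per-stage progress on stderr
#' @return a report list: `config_hash`, `split`, `classification`
#'   (per-finger metrics, 2S only), `regression` (per-DOF MSE/VAF),
#'   `results` (per-trial decode results), `models`, `timings`
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  stopifnot(inherits(config, "nd_run_config"))
  hash <- config_hash(config)
  say <- function(fmt, ...) if (!quiet)
    message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"),
                    sprintf(fmt, ...)))
  tic <- function() proc.time()[["elapsed"]]
  timings <- c()
  stage <- function(name, expr) {
    t0 <- tic()
    out <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- tic() - t0
    say("stage %-10s %6.1f s", name, timings[[name]])
    out
  }

  sess <- stage("simulate", {
    sc <- session_config(n_repetitions = config$n_repetitions,
                         snr_db = config$snr_db,
                         rng_seed = config$seed)
    generate_session(sc, config$gestures)
  })
  rec <- stage("preprocess", bandlimit(sess$recording, config$band[1],
                                       config$band[2],
                                       sess$recording$sample_rate))
  trials <- stage("cut", cut_trials(rec, sess$trajectories, config$window_s,
                                    config$step_s, config$activity_threshold))
  stream <- stage("extract", feature_stream(rec))
  # block length ~ 2 windows: long enough that guard gaps cost few trials,
  # short enough that every gesture segment spans several blocks and both
  # sides of the split see every gesture
  duration_s <- ncol(rec$samples) / rec$sample_rate
  n_blocks <- max(config$split_blocks,
                  floor(duration_s / (2 * config$window_s)))
  split <- split_regression(trials, config$split_frac, n_blocks,
                            seed = config$seed)
  consts <- fit_normalizer(lapply(trials[split$train], feature_matrix,
                                  stream = stream))
  fhash <- config_hash(consts)
  feats <- trial_feature_list(trials, stream, consts)

  tr_i <- split$train; va_i <- split$valid
  cls <- NULL
  models <- stage("train", {
    cfg <- config$train
    pca_shared <- NULL
    if (config$regressor_family %in% c("svm", "rf", "mlp")) {
      cols <- do.call(rbind, lapply(feats[tr_i], function(m)
        t(m[, seq(1, ncol(m), by = 10)])))
      pca_shared <- fit_pca(cols, 30L)
    }
    if (config$strategy == "2s") {
      cdata <- lapply(tr_i, function(i)
        list(x = feats[[i]], y = trials[[i]]$finger_state))
      cls <- train_classifier(model_spec("classification",
                                         config$classifier_family),
                              cdata, cfg)
      cls$feature_hash <- fhash
    }
    subset <- if (config$strategy == "2s") "active_only" else "full"
    regs <- lapply(1:10, function(dof) {
      rdata <- regressor_data(trials[tr_i], feats[tr_i], dof)
      cfg_d <- cfg; cfg_d$seed <- cfg$seed + dof
      if (subset == "active_only" &&
          !any(vapply(rdata, `[[`, logical(1), "active"))) {
        # a DOF never active in this session has nothing to regress; the
        # classifier gate keeps it at zero, so fit the constant-0 model
        message(sprintf("DOF %d has no active trials; using a constant-zero regressor",
                        dof))
        r <- constant_regressor(dof)
      } else {
        r <- train_regressor(model_spec("regression", config$regressor_family),
                             rdata, cfg_d, subset = subset, dof_id = dof,
                             pca_state = pca_shared)
      }
      r$feature_hash <- fhash
      r
    })
    regs
  })

  results <- stage("decode",
    run_decode(trials[va_i], feats[va_i], config$strategy,
               classifier = cls, regressors = models))

  report <- stage("evaluate", {
    truth_state <- vapply(trials[va_i], `[[`, integer(5), "finger_state")
    pred_state <- vapply(results, `[[`, integer(5), "finger_state")
    cls_metrics <- if (config$strategy == "2s")
      per_finger_metrics(truth_state, pred_state) else NULL
    reg <- do.call(rbind, lapply(1:10, function(dof) {
      y <- unlist(lapply(trials[va_i], function(t) t$trajectory[dof, ]))
      yh <- unlist(lapply(results, function(r) r$trajectories[dof, ]))
      data.frame(dof = dof, name = dof_names()[dof],
                 mse = mse(y, yh), vaf = vaf(y, yh))
    }))
    list(classification = cls_metrics, regression = reg)
  })

  out <- list(config = config, config_hash = hash, feature_hash = fhash,
              split = split, classification = report$classification,
              regression = report$regression, results = results,
              classifier = cls, regressors = models, norm_constants = consts,
              timings = timings)
  if (!is.null(out_dir)) write_report(out, trials[va_i], out_dir)
  out
}

# Persist the per-trial decode table and the metric summaries.
write_report <- function(report, valid_trials, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  res <- report$results
  tab <- data.frame(t_end = vapply(res, `[[`, numeric(1), "t_end"))
  st <- t(vapply(res, `[[`, integer(5), "finger_state"))
  colnames(st) <- paste0("state_", FINGERS)
  last <- t(vapply(res, function(r) r$trajectories[, ncol(r$trajectories)],
                   numeric(10)))
  colnames(last) <- dof_names()
  utils::write.csv(cbind(tab, st, last),
                   file.path(out_dir, "results.csv"), row.names = FALSE)
  if (!is.null(report$classification))
    utils::write.csv(report$classification,
                     file.path(out_dir, "classification_metrics.csv"),
                     row.names = FALSE)
  utils::write.csv(report$regression,
                   file.path(out_dir, "regression_metrics.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(config_hash = report$config_hash, seed = report$config$seed,
         feature_hash = report$feature_hash,
         package_version = as.character(utils::packageVersion("nervedecodr")),
         timings = as.list(report$timings)),
    file.path(out_dir, "provenance.json"), auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}
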