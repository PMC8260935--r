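#' Two-step (classify-then-regress) decoding of one trial
#'
#' Runs the finger-state classifier first; only the regressors of fingers
#' predicted active are invoked (two models per finger, MCP and PIP), and
#' the trajectory rows of inactive fingers are set exactly to zero. This
#' gating removes the false-positive "wiggle" of idle joints and skips
#' most model evaluations on rest-heavy data.
#'
#' @param trial an `nd_trial`
#' @param classifier an `nd_classifier`
#' @param regressors list of 10 `nd_regressor`s, DOF order (thumb MCP,
#'   thumb PIP, ..., little PIP)
#' @param features the trial's normalized 224 x 200 feature matrix; if
#'   missing it is computed with [feature_matrix()] and `norm_constants`
#' @param norm_constants constants from [fit_normalizer()] (only used when
#'   `features` is missing)
#' @return an `nd_decode_result`: `finger_state` (5-bit), `trajectories`
#'   (10 x 200, in `[0, 1]`), `strategy`, `models_invoked` (DOF ids) and
#'   `t_end`
#' @export
decode_2s <- function(trial, classifier, regressors, features = NULL,
                      norm_constants = NULL) {
  stopifnot(inherits(classifier, "nd_classifier"), length(regressors) == 10L)
  features <- features %||% normalized_features(trial, norm_constants)
  check_feature_hash(c(list(classifier), regressors))
  state <- as.integer(predict(classifier, list(features))$state[, 1])
  T <- ncol(features)
  traj <- matrix(0, 10L, T)
  invoked <- integer(0)
  for (f in which(state == 1L)) {
    for (dof in c(2L * f - 1L, 2L * f)) {
      traj[dof, ] <- predict(regressors[[dof]], features)
      invoked <- c(invoked, dof)
    }
  }
  decode_result(state, traj, "2S", invoked, trial$t_end)
}

#' One-step (direct regression) decoding of one trial
#'
#' All ten joint regressors are invoked on every trial, regardless of
#' finger state; no output is zeroed. At rest the outputs are typically
#' small but generally nonzero — the false-positive behavior that
#' motivates the two-step gate.
#'
#' @inheritParams decode_2s
#' @return an `nd_decode_result`; `finger_state` records all-active
#' @export
decode_1s <- function(trial, regressors, features = NULL,
                      norm_constants = NULL) {
  stopifnot(length(regressors) == 10L)
  if (any(vapply(regressors, is.null, logical(1))))
    stop("all 10 DOF models are required", call. = FALSE)
  features <- features %||% normalized_features(trial, norm_constants)
  check_feature_hash(regressors)
  T <- ncol(features)
  traj <- matrix(0, 10L, T)
  for (dof in 1:10) traj[dof, ] <- predict(regressors[[dof]], features)
  decode_result(rep(1L, 5), traj, "1S", 1:10, trial$t_end)
}

decode_result <- function(state, traj, strategy, invoked, t_end) {
  structure(list(finger_state = state,
                 trajectories = pmin(pmax(traj, 0), 1),
                 strategy = strategy, models_invoked = invoked,
                 t_end = t_end),
            class = "nd_decode_result")
}

#' @export
print.nd_decode_result <- function(x, ...) {
  cat(sprintf("<%s decode @ %.2f s: state %s, %d model(s) invoked>\n",
              x$strategy, x$t_end, paste(x$finger_state, collapse = ""),
              length(x$models_invoked)))
  invisible(x)
}

normalized_features <- function(trial, norm_constants) {
  if (is.null(norm_constants))
    stop("either `features` or `norm_constants` must be supplied",
         call. = FALSE)
  apply_normalizer(feature_matrix(trial), norm_constants)
}

# Models trained by the pipeline carry the digest of the feature
# configuration they were fitted with; mixing models fitted under
# different normalizations is an error.
check_feature_hash <- function(models) {
  hs <- unlist(lapply(models, function(m) m$feature_hash))
  if (length(hs) > 1L && length(unique(hs)) > 1L)
    stop("model/feature config hash mismatch", call. = FALSE)
  invisible(TRUE)
}

#' Decode a list of trials
#'
#' Convenience loop over [decode_2s()] / [decode_1s()] with precomputed
#' per-trial features. An optional majority-vote smoother over `smooth_k`
#' consecutive classifier decisions is available (off by default).
#'
#' @param trials list of `nd_trial`s
#' @param features list of normalized feature matrices, same length
#' @param strategy `"2s"` or `"1s"`
#' @param classifier required for `"2s"`
#' @param regressors list of 10 fitted regressors
#' @param smooth_k odd window for majority-vote smoothing of the predicted
#'   states (1 = off)
#' @return list of `nd_decode_result`
#' @export
run_decode <- function(trials, features, strategy = c("2s", "1s"),
                       classifier = NULL, regressors, smooth_k = 1L) {
  strategy <- match.arg(strategy)
  if (strategy == "1s")
    return(lapply(seq_along(trials), function(i)
      decode_1s(trials[[i]], regressors, features[[i]])))
  stopifnot(!is.null(classifier))
  states <- predict(classifier, features)$state
  if (smooth_k > 1L) states <- smooth_states(states, smooth_k)
  lapply(seq_along(trials), function(i) {
    st <- states[, i]
    T <- ncol(features[[i]])
    traj <- matrix(0, 10L, T)
    invoked <- integer(0)
    for (f in which(st == 1L)) for (dof in c(2L * f - 1L, 2L * f)) {
      traj[dof, ] <- predict(regressors[[dof]], features[[i]])
      invoked <- c(invoked, dof)
    }
    decode_result(st, traj, "2S", invoked, trials[[i]]$t_end)
  })
}

#' Majority-vote smoothing of consecutive finger states
#'
#' @param states 5 x n binary matrix (columns = consecutive trials)
#' @param k odd smoothing window
#' @export
smooth_states <- function(states, k = 3L) {
  stopifnot(k %% 2L == 1L)
  if (k == 1L) return(states)
  h <- (k - 1L) %/% 2L
  n <- ncol(states)
  out <- states
  for (i in seq_len(n)) {
    sel <- max(1L, i - h):min(n, i + h)
    out[, i] <- (rowMeans(states[, sel, drop = FALSE]) > 0.5) * 1L
  }
  out
}
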