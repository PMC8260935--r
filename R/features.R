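#' The fourteen time-domain features
#'
#' Feature identifiers in canonical order: zero crossings (ZC), slope sign
#' changes (SSC), waveform length (WL), Wilson amplitude (WA), mean
#' absolute value (MAB), mean square (MSQ), root mean square (RMS), v-order
#' 3 (V3), log detector (LD), difference absolute standard deviation
#' (DABS), maximum fractal length (MFL), myopulse percentage rate (MPR),
#' mean absolute value slope (MAVS), and weighted mean absolute (WMA).
#'
#' Conventions (fixed and documented because the classic formulas are
#' ambiguous): the sign function in the counting features ZC, SSC, WA and
#' MPR is the indicator `1[u > 0]` (ties count zero) so counts are
#' non-negative; ZC counts sign changes of the *demeaned* window; the
#' standard deviation uses the sample (N-1) denominator; logarithms are
#' natural; LD floors `|x|` at 1e-12 before the log; V3 takes the signed
#' real cube root; MFL is `log(sqrt(sum(diff(x)^2)))`, which equals
#' `log(DABS) + log(N - 1) / 2`.
#'
#' @export
FEATURES <- c("ZC", "SSC", "WL", "WA", "MAB", "MSQ", "RMS", "V3", "LD",
              "DABS", "MFL", "MPR", "MAVS", "WMA")

LD_EPS <- 1e-12

#' Compute one feature of one window
#'
#' Scalar reference implementation of each formula; the bulk path
#' ([feature_stream()]) is vectorized but must agree with this one exactly.
#'
#' @param feature_id one of [FEATURES], or its index 1..14
#' @param x numeric vector of window samples (N >= 3)
#' @return a single finite number
#' @examples
#' compute_feature("WL", c(1, -2, 3, -4))   # 15
#' @export
compute_feature <- function(feature_id, x) {
  if (is.numeric(feature_id)) feature_id <- FEATURES[feature_id]
  feature_id <- match.arg(feature_id, FEATURES)
  n <- length(x)
  if (n < 3L) stop("feature window needs at least 3 samples", call. = FALSE)
  d <- diff(x)
  xs <- stats::sd(x)
  switch(feature_id,
    ZC   = { xc <- x - mean(x); sum(-xc[-n] * xc[-1] > 0) },
    SSC  = sum(-d[-1] * d[-(n - 1)] > 0),
    WL   = sum(abs(d)),
    WA   = sum(abs(d) - xs > 0),
    MAB  = mean(abs(x)),
    MSQ  = mean(x^2),
    RMS  = sqrt(mean(x^2)),
    V3   = { m <- mean(x^3); sign(m) * abs(m)^(1 / 3) },
    LD   = exp(mean(log(pmax(abs(x), LD_EPS)))),
    DABS = sqrt(sum(d^2) / (n - 1)),
    MFL  = 0.5 * log(max(sum(d^2), LD_EPS)),
    MPR  = sum(abs(x) - xs > 0),
    MAVS = { h <- n %/% 2; (sum(abs(x[1:h])) - sum(abs(x[(h + 1):n]))) / h },
    WMA  = { i <- seq_len(n)
             w <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
             mean(w * abs(x)) })
}

# All 14 features of every column of a windows matrix (N x K), vectorized.
# Returns a 14 x K matrix in FEATURES order.
feature_block <- function(W) {
  n <- nrow(W); k <- ncol(W)
  D <- W[-1, , drop = FALSE] - W[-n, , drop = FALSE]
  absW <- abs(W); absD <- abs(D)
  mu <- colMeans(W)
  ssd <- sqrt((colSums(W^2) - n * mu^2) / (n - 1))
  ssd <- pmax(ssd, 0)                      # guard tiny negative round-off
  Wc <- W - rep(mu, each = n)
  sumd2 <- colSums(D^2)
  h <- n %/% 2
  i <- seq_len(n)
  wma_w <- ifelse(i >= 0.25 * n & i <= 0.75 * n, 1, 0.5)
  m3 <- colMeans(W^3)
  out <- matrix(0, 14, k, dimnames = list(FEATURES, NULL))
  out["ZC", ]   <- colSums(-Wc[-n, , drop = FALSE] * Wc[-1, , drop = FALSE] > 0)
  out["SSC", ]  <- colSums(-D[-1, , drop = FALSE] * D[-(n - 1), , drop = FALSE] > 0)
  out["WL", ]   <- colSums(absD)
  out["WA", ]   <- colSums(absD > rep(ssd, each = n - 1))
  out["MAB", ]  <- colMeans(absW)
  out["MSQ", ]  <- colMeans(W^2)
  out["RMS", ]  <- sqrt(out["MSQ", ])
  out["V3", ]   <- sign(m3) * abs(m3)^(1 / 3)
  out["LD", ]   <- exp(colMeans(log(pmax(absW, LD_EPS))))
  out["DABS", ] <- sqrt(sumd2 / (n - 1))
  out["MFL", ]  <- 0.5 * log(pmax(sumd2, LD_EPS))
  out["MPR", ]  <- colSums(absW > rep(ssd, each = n))
  out["MAVS", ] <- (colSums(absW[1:h, , drop = FALSE]) -
                    colSums(absW[(h + 1):n, , drop = FALSE])) / h
  out["WMA", ]  <- colMeans(wma_w * absW)
  out
}

#' Feature stream of a whole recording
#'
#' Computes the 14 features of every channel over sliding windows of
#' `window_ms` with a `step_ms` increment (defaults 100 ms / 20 ms, i.e.
#' 80% overlap). Column `j` is computed from the `window_ms` of samples
#' *ending* at `j * step_ms`, zero-padded on the left at the very start of
#' the recording, so every column is causal. Rows are channel-major:
#' channel 1 features 1-14, then channel 2, and so on (16 x 14 = 224 rows).
#'
#' @param recording a [nerve_recording()]
#' @param window_ms,step_ms window and step in milliseconds; `window_ms`
#'   must be an integer multiple of `step_ms`
#' @return object of class `nd_feature_stream`: list with `values`
#'   (224 x K), `step_n` (samples per step), `window_n`, `sample_rate`,
#'   `row_index` (data frame channel/feature per row)
#' @export
feature_stream <- function(recording, window_ms = 100, step_ms = 20) {
  stopifnot(inherits(recording, "nd_recording"))
  rate <- recording$sample_rate
  win_n <- round(window_ms / 1000 * rate)
  step_n <- round(step_ms / 1000 * rate)
  if (win_n %% step_n != 0)
    stop("window_ms must be an integer multiple of step_ms", call. = FALSE)
  n <- ncol(recording$samples)
  n_ch <- nrow(recording$samples)
  K <- n %/% step_n
  # window j spans samples (j*step_n - win_n + 1) .. (j*step_n); left pad 0
  vals <- matrix(0, 14L * n_ch, K)
  pad0 <- numeric(win_n - step_n)
  for (ch in seq_len(n_ch)) {
    xp <- c(pad0, recording$samples[ch, ])
    vals[(ch - 1L) * 14L + 1:14, ] <-
      window_features_cpp(xp, win_n, step_n, win_n)
  }
  row_index <- data.frame(channel = rep(seq_len(n_ch), each = 14L),
                          feature = rep(FEATURES, n_ch))
  structure(list(values = vals, step_n = step_n, window_n = win_n,
                 sample_rate = rate, row_index = row_index),
            class = "nd_feature_stream")
}

#' Per-trial feature matrix
#'
#' Assembles the decoder input for one 4 s trial: 224 rows (16 channels x
#' 14 features, channel-major) by 200 columns (one per 20 ms step; 4 s /
#' 20 ms = 200). Column `t` is computed from the 100 ms of raw samples
#' ending at `t * 20 ms` into the trial. The first columns, whose windows
#' reach before the trial start, use real preceding samples from the
#' parent recording when they exist (the pseudo-online case) and left
#' zero-padding otherwise.
#'
#' @param trial an `nd_trial` from [cut_trials()]
#' @param window_ms,step_ms window and step in milliseconds; their ratio
#'   must be 5 (80% overlap)
#' @param stream optional precomputed [feature_stream()] of the parent
#'   recording; slicing it is fast and exactly equivalent
#' @return 224 x 200 numeric matrix (for a 4 s trial at 5 kHz)
#' @export
feature_matrix <- function(trial, window_ms = 100, step_ms = 20,
                           stream = NULL) {
  stopifnot(inherits(trial, "nd_trial"))
  if (round(window_ms / step_ms) != 5)
    stop("window_ms / step_ms must be 5 (80% overlap)", call. = FALSE)
  rate <- trial$recording$sample_rate
  step_n <- round(step_ms / 1000 * rate)
  win_n <- round(window_ms / 1000 * rate)
  n_cols <- (trial$end - trial$start + 1L) %/% step_n
  if (!is.null(stream)) {
    stopifnot(inherits(stream, "nd_feature_stream"),
              stream$step_n == step_n, stream$window_n == win_n)
    if ((trial$start - 1L) %% step_n != 0L)
      stop("trial start is not aligned to the stream step", call. = FALSE)
    j0 <- (trial$start - 1L) %/% step_n
    return(stream$values[, j0 + seq_len(n_cols), drop = FALSE])
  }
  sig <- trial$recording$samples
  n_ch <- nrow(sig)
  offset <- trial$start + step_n - win_n     # first window's first sample
  vals <- matrix(0, 14L * n_ch, n_cols)
  for (ch in seq_len(n_ch)) {
    x <- if (offset >= 1L) sig[ch, offset:trial$end]
         else c(numeric(1L - offset), sig[ch, seq_len(trial$end)])
    vals[(ch - 1L) * 14L + 1:14, ] <-
      window_features_cpp(x, win_n, step_n, win_n)
  }
  vals
}

#' Fit fixed normalization constants
#'
#' Each feature type is normalized by one fixed positive constant shared
#' across channels: the 99th percentile of its absolute value over the
#' training data. Constants are fitted on the training split only and
#' reused unchanged on held-out data (no leakage of held-out statistics).
#'
#' @param x a list of feature matrices, a single matrix, or an
#'   `nd_feature_stream`
#' @return numeric vector of 14 positive constants named by feature
#' @export
fit_normalizer <- function(x) {
  if (inherits(x, "nd_feature_stream")) x <- list(x$values)
  if (is.matrix(x)) x <- list(x)
  stopifnot(length(x) >= 1)
  n_feat <- 14L
  consts <- vapply(seq_len(n_feat), function(f) {
    v <- unlist(lapply(x, function(m) {
      rows <- seq(f, nrow(m), by = n_feat)
      abs(m[rows, ])
    }), use.names = FALSE)
    stats::quantile(v, 0.99, names = FALSE)
  }, numeric(1))
  consts <- pmax(consts, 1e-9)      # floor for degenerate all-zero input
  names(consts) <- FEATURES
  consts
}

#' Apply normalization constants
#'
#' @param m feature matrix (rows channel-major, 14 features per channel)
#' @param consts constants from [fit_normalizer()]
#' @return normalized matrix of the same shape
#' @export
apply_normalizer <- function(m, consts) {
  stopifnot(length(consts) == 14L, all(consts > 0))
  m / rep(consts, length.out = nrow(m))
}
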