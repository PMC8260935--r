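# Independent oracles: naive, loop-based transcriptions of the feature
# formulas and metric definitions, deliberately kept free of any package
# vectorization so they can certify the fast paths.

naive_feature <- function(id, x) {
  n <- length(x)
  xs <- sd(x)
  count <- function(cond) { s <- 0L; for (v in cond) if (v) s <- s + 1L; s }
  switch(id,
    ZC = { xc <- x - mean(x)
           s <- 0L
           for (i in 2:n) if (-xc[i - 1] * xc[i] > 0) s <- s + 1L
           s },
    SSC = { s <- 0L
            for (i in 3:n)
              if (-(x[i] - x[i - 1]) * (x[i - 1] - x[i - 2]) > 0) s <- s + 1L
            s },
    WL = { s <- 0
           for (i in 2:n) s <- s + abs(x[i] - x[i - 1])
           s },
    WA = { s <- 0L
           for (i in 2:n) if (abs(x[i] - x[i - 1]) - xs > 0) s <- s + 1L
           s },
    MAB = sum(abs(x)) / n,
    MSQ = sum(x^2) / n,
    RMS = sqrt(sum(x^2) / n),
    V3 = { m <- sum(x^3) / n; if (m < 0) -((-m)^(1 / 3)) else m^(1 / 3) },
    LD = { s <- 0
           for (i in 1:n) s <- s + log(max(abs(x[i]), 1e-12))
           exp(s / n) },
    DABS = { s <- 0
             for (i in 2:n) s <- s + (x[i] - x[i - 1])^2
             sqrt(s / (n - 1)) },
    MFL = { s <- 0
            for (i in 2:n) s <- s + (x[i] - x[i - 1])^2
            log(sqrt(max(s, 1e-12))) },
    MPR = { s <- 0L
            for (i in 1:n) if (abs(x[i]) - xs > 0) s <- s + 1L
            s },
    MAVS = { h <- n %/% 2
             (sum(abs(x[1:h])) - sum(abs(x[(h + 1):n]))) / h },
    WMA = { s <- 0
            for (i in 1:n) {
              w <- if (i >= 0.25 * n && i <= 0.75 * n) 1 else 0.5
              s <- s + w * abs(x[i])
            }
            s / n },
    stop("unknown feature ", id))
}

# Eq. 1-5 by per-sample counting.
naive_cls_metrics <- function(truth, pred) {
  tp <- tn <- fp <- fn <- 0L
  for (i in seq_along(truth)) {
    if (truth[i] == 1 && pred[i] == 1) tp <- tp + 1L
    if (truth[i] == 0 && pred[i] == 0) tn <- tn + 1L
    if (truth[i] == 0 && pred[i] == 1) fp <- fp + 1L
    if (truth[i] == 1 && pred[i] == 0) fn <- fn + 1L
  }
  sens <- tp / (tp + fn); spec <- tn / (tn + fp); prec <- tp / (tp + fp)
  # harmonic mean of an all-zero pair is taken as 0 (documented convention)
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = (sens + spec) / 2, f1 = f1)
}

# Brute-force slide enumerator for trial counting.
enumerate_slices <- function(duration, window, step) {
  ends <- c()
  e <- window
  while (e <= duration + 1e-9) {
    ends <- c(ends, e)
    e <- e + step
  }
  ends
}

numeric_gradient <- function(f, x, eps = 1e-5) {
  g <- x
  for (i in seq_along(x)) {
    x1 <- x; x2 <- x
    x1[i] <- x1[i] + eps; x2[i] <- x2[i] - eps
    g[i] <- (f(x1) - f(x2)) / (2 * eps)
  }
  g
}
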