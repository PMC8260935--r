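#' Confusion counts
#'
#' @param truth,pred binary vectors of the same length
#' @return list with `TP`, `TN`, `FP`, `FN`
#' @export
confusion_counts <- function(truth, pred) {
  stopifnot(length(truth) == length(pred))
  list(TP = sum(truth == 1 & pred == 1), TN = sum(truth == 0 & pred == 0),
       FP = sum(truth == 0 & pred == 1), FN = sum(truth == 1 & pred == 0))
}

#' Classification metrics
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, precision
#' `TP/(TP+FP)`, balanced accuracy `(sensitivity+specificity)/2` (used
#' because inactive-finger samples vastly outnumber active ones), and
#' `F1 = 2*sensitivity*precision/(sensitivity+precision)`.
#'
#' Degenerate denominators (a class absent from truth, or no positive
#' predictions) are resolved as 1 when no corresponding error was made —
#' e.g. with no positives in truth and none predicted, sensitivity and
#' precision are 1 — and 0 otherwise.
#'
#' @param c confusion counts from [confusion_counts()]
#' @return named numeric vector
#' @export
classification_metrics <- function(c) {
  rate <- function(num, den, errs) if (den > 0) num / den
                                   else if (errs == 0) 1 else 0
  sens <- rate(c$TP, c$TP + c$FN, c$FP)
  spec <- rate(c$TN, c$TN + c$FP, c$FN)
  prec <- rate(c$TP, c$TP + c$FP, c$FN)
  f1 <- if (sens + prec > 0) 2 * sens * prec / (sens + prec) else 0
  c(sensitivity = sens, specificity = spec, precision = prec,
    accuracy = (sens + spec) / 2, f1 = f1)
}

#' Per-finger one-vs-rest classification metrics
#'
#' @param truth,pred 5 x n binary state matrices
#' @return data frame with one row per finger
#' @export
per_finger_metrics <- function(truth, pred) {
  out <- lapply(1:5, function(f)
    as.data.frame(t(classification_metrics(
      confusion_counts(truth[f, ], pred[f, ])))))
  cbind(finger = FINGERS, do.call(rbind, out))
}

#' Regression metrics: MSE and VAF
#'
#' Mean squared error `mean((yhat - y)^2)` and variance accounted for
#' `VAF = 1 - sum((yhat - y)^2) / sum((y - mean(y))^2)`. VAF ranges over
#' `(-Inf, 1]`; it is `NA` (undefined) when the ground truth has zero
#' variance. Negative VAF values are retained in raw output; use
#' [summarize_vaf()] for summary-level filtering.
#'
#' @param y ground-truth trajectory
#' @param y_hat predicted trajectory
#' @export
mse <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat))
  mean((y_hat - y)^2)
}

#' @rdname mse
#' @export
vaf <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) >= 2)
  ss <- sum((y - mean(y))^2)
  if (ss <= 0) return(NA_real_)
  1 - sum((y_hat - y)^2) / ss
}

#' Summarize VAF scores, ignoring negative values
#'
#' Negative VAF values are excluded from the summary (they mark decoders
#' worse than a constant predictor) but never deleted from raw results;
#' the number ignored is reported.
#'
#' @param v vector of VAF scores (may contain `NA`)
#' @return list with `mean`, `n`, `n_ignored`, `n_undefined`
#' @export
summarize_vaf <- function(v) {
  undef <- is.na(v)
  neg <- !undef & v < 0
  keep <- v[!undef & !neg]
  list(mean = if (length(keep)) mean(keep) else NA_real_,
       n = length(keep), n_ignored = sum(neg), n_undefined = sum(undef))
}

#' Gesture-stratified k-fold split
#'
#' Assigns every trial to exactly one validation fold, stratified by its
#' finger-state pattern so each fold sees every gesture.
#'
#' @param trials list of `nd_trial`s
#' @param k number of folds (default 5)
#' @param seed RNG seed
#' @return integer vector of fold ids (1..k), one per trial
#' @export
split_cv <- function(trials, k = 5L, seed = 1L) {
  strata <- vapply(trials, function(t) paste(t$finger_state, collapse = ""),
                   character(1))
  folds <- integer(length(trials))
  with_seed(seed, for (s in unique(strata)) {
    idx <- sample(which(strata == s))
    folds[idx] <- rep_len(seq_len(k), length(idx))
  })
  folds
}

#' Leakage-free train/validation split for overlapped windows
#'
#' Sliding-window trials share raw samples with their neighbors, so a
#' random per-trial split would leak. The timeline is instead cut into
#' `n_blocks` contiguous blocks; whole blocks are drawn at random into the
#' validation set until it holds at least `1 - frac` of the trials, and
#' any training trial whose sample range intersects a validation trial's
#' range is dropped (the guard gap). The result shares zero raw samples
#' across the split, which [split_overlap()] audits.
#'
#' @param trials list of `nd_trial`s
#' @param frac target training fraction (default 0.8)
#' @param n_blocks number of contiguous candidate blocks (default 5)
#' @param seed RNG seed
#' @return list with integer index vectors `train` and `valid`, and
#'   `n_dropped`
#' @export
split_regression <- function(trials, frac = 0.8, n_blocks = 5L, seed = 1L) {
  n <- length(trials)
  stopifnot(n >= n_blocks)
  t_end <- vapply(trials, `[[`, numeric(1), "t_end")
  ord <- order(t_end)
  block <- rep_len(rep(seq_len(n_blocks), each = ceiling(n / n_blocks)), n)
  block_of <- integer(n)
  block_of[ord] <- block[seq_len(n)]
  valid_blocks <- integer(0)
  with_seed(seed, {
    for (b in sample.int(n_blocks)) {
      valid_blocks <- c(valid_blocks, b)
      if (sum(block_of %in% valid_blocks) >= (1 - frac) * n) break
    }
  })
  valid <- which(block_of %in% valid_blocks)
  train <- setdiff(seq_len(n), valid)
  vr <- cbind(vapply(trials[valid], `[[`, integer(1), "start"),
              vapply(trials[valid], `[[`, integer(1), "end"))
  keep <- vapply(train, function(i) {
    s <- trials[[i]]$start; e <- trials[[i]]$end
    !any(s <= vr[, 2] & e >= vr[, 1])
  }, logical(1))
  if (!any(keep))
    stop("too few trials to honor guard gaps", call. = FALSE)
  list(train = train[keep], valid = valid,
       n_dropped = sum(!keep))
}

#' Audit raw-sample overlap between two trial sets
#'
#' @param a,b lists of `nd_trial`s
#' @return number of shared raw-sample indices (0 means leakage-free)
#' @export
split_overlap <- function(a, b) {
  idx_a <- unique(unlist(lapply(a, function(t) t$start:t$end)))
  idx_b <- unique(unlist(lapply(b, function(t) t$start:t$end)))
  length(intersect(idx_a, idx_b))
}

#' Pairwise paired t-tests with Bonferroni correction
#'
#' Compares models on a common trial set by paired t-tests on per-trial
#' score differences; significance uses the Bonferroni-adjusted threshold
#' `alpha / n_comparisons`. Zero-variance differences are reported as
#' exact ties.
#'
#' @param scores models x trials matrix of per-trial scores (rownames are
#'   model names)
#' @param alpha family-wise error level (default 0.05)
#' @return data frame: model pair, mean difference, t, raw p, adjusted
#'   threshold, significance, tie flag
#' @export
compare_models <- function(scores, alpha = 0.05) {
  m <- nrow(scores)
  stopifnot(m >= 2)
  nms <- rownames(scores) %||% paste0("model", seq_len(m))
  pairs <- utils::combn(m, 2)
  n_comp <- ncol(pairs)
  out <- lapply(seq_len(n_comp), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    d <- scores[i, ] - scores[j, ]
    tie <- stats::sd(d) < 1e-15
    if (tie) {
      data.frame(a = nms[i], b = nms[j], mean_diff = mean(d), t = NA_real_,
                 p = NA_real_, threshold = alpha / n_comp,
                 significant = FALSE, tie = TRUE)
    } else {
      tt <- stats::t.test(scores[i, ], scores[j, ], paired = TRUE)
      data.frame(a = nms[i], b = nms[j], mean_diff = mean(d),
                 t = unname(tt$statistic), p = tt$p.value,
                 threshold = alpha / n_comp,
                 significant = tt$p.value < alpha / n_comp, tie = FALSE)
    }
  })
  do.call(rbind, out)
}
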