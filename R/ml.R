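# Native implementations of the classic baselines: depth-limited CART
# random forests, a support-vector classifier trained by sequential
# minimal optimization (SMO) with an RBF kernel, and a polynomial-kernel
# support-vector regressor trained in the primal via an explicit cubic
# feature map. Kept deliberately small: the published baselines are tiny
# (5-10 trees of depth 3, C = 1), so simple solvers suffice.

# --- CART / random forest ---------------------------------------------------

# Recursively grow one tree. X: n x p, y numeric (0/1 for classification
# handled identically through variance reduction, which equals Gini
# impurity reduction up to a constant for binary targets).
grow_tree <- function(X, y, depth, max_depth, mtry, min_node = 5L) {
  n <- length(y)
  if (depth >= max_depth || n < 2L * min_node || stats::var(y) < 1e-12)
    return(list(leaf = TRUE, value = mean(y)))
  feats <- sample.int(ncol(X), mtry)
  best <- NULL; best_score <- Inf
  for (f in feats) {
    v <- X[, f]
    qs <- unique(stats::quantile(v, probs = seq(0.1, 0.9, length.out = 9),
                                 names = FALSE, type = 1))
    for (thr in qs) {
      left <- v <= thr
      nl <- sum(left)
      if (nl < min_node || n - nl < min_node) next
      yl <- y[left]; yr <- y[!left]
      score <- nl * stats::var(yl) * (nl - 1) / nl +
        (n - nl) * stats::var(yr) * (n - nl - 1) / (n - nl)
      if (is.na(score)) next
      if (score < best_score) {
        best_score <- score
        best <- list(f = f, thr = thr, left = left)
      }
    }
  }
  if (is.null(best)) return(list(leaf = TRUE, value = mean(y)))
  list(leaf = FALSE, f = best$f, thr = best$thr,
       l = grow_tree(X[best$left, , drop = FALSE], y[best$left],
                     depth + 1L, max_depth, mtry, min_node),
       r = grow_tree(X[!best$left, , drop = FALSE], y[!best$left],
                     depth + 1L, max_depth, mtry, min_node))
}

predict_tree <- function(node, X) {
  if (node$leaf) return(rep(node$value, nrow(X)))
  out <- numeric(nrow(X))
  left <- X[, node$f] <= node$thr
  if (any(left)) out[left] <- predict_tree(node$l, X[left, , drop = FALSE])
  if (any(!left)) out[!left] <- predict_tree(node$r, X[!left, , drop = FALSE])
  out
}

#' Fit a small random forest
#'
#' Bagged CART trees with a depth cap, matching the published baseline
#' sizes: 5 trees for classification, 10 for regression, maximum depth 3.
#' Binary classification targets are fitted as 0/1 regressions (for binary
#' outcomes variance reduction is equivalent to Gini-impurity reduction);
#' the forest's averaged vote is thresholded by the caller.
#'
#' @param X n x p feature matrix
#' @param y numeric target (0/1 for classification)
#' @param n_trees,max_depth forest shape
#' @param mtry features tried per split (default `ceiling(sqrt(p))`)
#' @param seed RNG seed
#' @export
fit_rf <- function(X, y, n_trees = 10L, max_depth = 3L,
                   mtry = ceiling(sqrt(ncol(X))), seed = 1L) {
  X <- as.matrix(X)
  with_seed(seed, {
    trees <- lapply(seq_len(n_trees), function(i) {
      boot <- sample.int(nrow(X), nrow(X), replace = TRUE)
      grow_tree(X[boot, , drop = FALSE], y[boot], 0L, max_depth, mtry)
    })
    structure(list(trees = trees, n_trees = n_trees, max_depth = max_depth),
              class = "nd_rf")
  })
}

#' @rdname fit_rf
#' @param object fitted forest
#' @param newdata n x p matrix
#' @param ... unused
#' @export
predict.nd_rf <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  preds <- vapply(object$trees, function(tree) predict_tree(tree, newdata),
                  numeric(nrow(newdata)))
  if (is.null(dim(preds))) mean(preds) else rowMeans(preds)
}

# --- SVM classification (RBF, SMO) -----------------------------------------

rbf_kernel <- function(A, B, gamma) {
  an <- rowSums(A^2); bn <- rowSums(B^2)
  d2 <- outer(an, bn, `+`) - 2 * A %*% t(B)
  exp(-gamma * pmax(d2, 0))
}

#' Fit a binary RBF support-vector classifier
#'
#' Simplified sequential-minimal-optimization solver for the soft-margin
#' dual with `C = 1` and an RBF kernel (`gamma` defaults to the scale
#' heuristic `1 / (p * var(X))`). Training sets larger than `max_n` are
#' subsampled, keeping the kernel matrix small.
#'
#' @param X n x p matrix
#' @param y labels in {0, 1}
#' @param C soft-margin constant
#' @param gamma RBF width; `NULL` for the scale heuristic
#' @param tol KKT tolerance
#' @param max_passes SMO passes without updates before stopping
#' @param max_n training-set cap
#' @param seed RNG seed (subsampling)
#' @export
fit_svm <- function(X, y, C = 1, gamma = NULL, tol = 1e-3, max_passes = 5L,
                    max_n = 1200L, seed = 1L) {
  X <- as.matrix(X)
  y2 <- ifelse(y > 0.5, 1, -1)
  if (nrow(X) > max_n) {
    sel <- with_seed(seed, sample.int(nrow(X), max_n))
    X <- X[sel, , drop = FALSE]; y2 <- y2[sel]
  }
  n <- nrow(X)
  if (is.null(gamma)) {
    vx <- mean(apply(X, 2, stats::var))
    gamma <- if (vx > 0) 1 / (ncol(X) * vx) else 1
  }
  if (length(unique(y2)) < 2L)
    return(structure(list(constant = y2[1], gamma = gamma),
                     class = "nd_svm"))
  K <- rbf_kernel(X, X, gamma)
  alpha <- numeric(n); b <- 0
  passes <- 0L; iter <- 0L
  with_seed(seed + 1L, while (passes < max_passes && iter < 200L) {
    iter <- iter + 1L
    changed <- 0L
    fx <- as.vector(K %*% (alpha * y2)) + b
    for (i in seq_len(n)) {
      Ei <- fx[i] - y2[i]
      if ((y2[i] * Ei < -tol && alpha[i] < C) ||
          (y2[i] * Ei > tol && alpha[i] > 0)) {
        j <- sample.int(n - 1L, 1L); if (j >= i) j <- j + 1L
        Ej <- sum(K[, j] * alpha * y2) + b - y2[j]
        ai <- alpha[i]; aj <- alpha[j]
        if (y2[i] != y2[j]) {
          L <- max(0, aj - ai); H <- min(C, C + aj - ai)
        } else {
          L <- max(0, ai + aj - C); H <- min(C, ai + aj)
        }
        if (L >= H) next
        eta <- 2 * K[i, j] - K[i, i] - K[j, j]
        if (eta >= 0) next
        aj_new <- min(max(aj - y2[j] * (Ei - Ej) / eta, L), H)
        if (abs(aj_new - aj) < 1e-5) next
        ai_new <- ai + y2[i] * y2[j] * (aj - aj_new)
        b1 <- b - Ei - y2[i] * (ai_new - ai) * K[i, i] -
          y2[j] * (aj_new - aj) * K[i, j]
        b2 <- b - Ej - y2[i] * (ai_new - ai) * K[i, j] -
          y2[j] * (aj_new - aj) * K[j, j]
        b <- if (ai_new > 0 && ai_new < C) b1
             else if (aj_new > 0 && aj_new < C) b2 else (b1 + b2) / 2
        alpha[i] <- ai_new; alpha[j] <- aj_new
        fx <- as.vector(K %*% (alpha * y2)) + b
        changed <- changed + 1L
      }
    }
    passes <- if (changed == 0L) passes + 1L else 0L
  })
  sv <- alpha > 1e-8
  structure(list(X = X[sv, , drop = FALSE], ay = (alpha * y2)[sv], b = b,
                 gamma = gamma),
            class = "nd_svm")
}

#' @rdname fit_svm
#' @param object fitted model
#' @param newdata n x p matrix
#' @param ... unused
#' @export
predict.nd_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!is.null(object$constant))
    return(rep(ifelse(object$constant > 0, 1, 0), nrow(newdata)))
  f <- as.vector(rbf_kernel(newdata, object$X, object$gamma) %*% object$ay) +
    object$b
  as.numeric(f > 0)
}

# --- SVR (polynomial kernel, primal) ---------------------------------------

# Exponent table of all monomials of total degree <= 3 over p variables.
poly3_exponents <- function(p) {
  ex <- list(matrix(0L, 1, p))
  for (i in seq_len(p)) {
    e <- integer(p); e[i] <- 1L
    ex[[length(ex) + 1L]] <- matrix(e, 1)
  }
  for (i in seq_len(p)) for (j in i:p) {
    e <- integer(p); e[i] <- e[i] + 1L; e[j] <- e[j] + 1L
    ex[[length(ex) + 1L]] <- matrix(e, 1)
  }
  for (i in seq_len(p)) for (j in i:p) for (k in j:p) {
    e <- integer(p); e[i] <- e[i] + 1L; e[j] <- e[j] + 1L; e[k] <- e[k] + 1L
    ex[[length(ex) + 1L]] <- matrix(e, 1)
  }
  do.call(rbind, ex)
}

# Explicit feature map of the kernel (1 + x.y)^3: monomials weighted by
# sqrt of their multinomial coefficients, so phi(x).phi(y) = (1 + x.y)^3.
poly3_map <- function(X, expo = poly3_exponents(ncol(X))) {
  deg <- rowSums(expo)
  coef <- sqrt(choose(3, deg) *
                 apply(expo, 1, function(e) factorial(sum(e)) /
                         prod(factorial(e))))
  Phi <- matrix(1, nrow(X), nrow(expo))
  for (m in seq_len(nrow(expo))) {
    nz <- which(expo[m, ] > 0L)
    for (v in nz) Phi[, m] <- Phi[, m] * X[, v]^expo[m, v]
  }
  sweep(Phi, 2, coef, `*`)
}

#' Fit a polynomial-kernel support-vector regressor
#'
#' Epsilon-insensitive support-vector regression with the cubic kernel
#' `(1 + x.y)^3` and `C = 1`, solved in the primal: the kernel is expanded
#' into its exact explicit feature map (all monomials up to degree 3,
#' multinomially weighted) and the objective
#' `0.5 ||w||^2 + C * sum(max(0, |r| - epsilon))` is minimized by Adam on
#' subgradients. Exact for the kernel; practical because the published
#' model takes only 30 PCA inputs (5,456 monomials).
#'
#' @param X n x p matrix (p <= ~30 advisable)
#' @param y numeric target
#' @param C regularization constant
#' @param epsilon insensitivity tube half-width
#' @param iters optimizer iterations
#' @param max_n training-set cap (subsampled above this)
#' @param seed RNG seed
#' @export
fit_svr_poly <- function(X, y, C = 1, epsilon = 0.05, iters = 300L,
                         max_n = 2000L, seed = 1L) {
  X <- as.matrix(X)
  if (nrow(X) > max_n) {
    sel <- with_seed(seed, sample.int(nrow(X), max_n))
    X <- X[sel, , drop = FALSE]; y <- y[sel]
  }
  expo <- poly3_exponents(ncol(X))
  Phi <- poly3_map(X, expo)
  n <- nrow(Phi); d <- ncol(Phi)
  w <- numeric(d); b <- 0
  m <- numeric(d); v <- numeric(d); mb <- 0; vb <- 0
  lr <- 0.05; b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  for (t in seq_len(iters)) {
    r <- as.vector(Phi %*% w) + b - y
    sg <- sign(r) * (abs(r) > epsilon)
    gw <- w + C * as.vector(crossprod(Phi, sg)) / n
    gb <- C * sum(sg) / n
    m <- b1 * m + (1 - b1) * gw; v <- b2 * v + (1 - b2) * gw^2
    mb <- b1 * mb + (1 - b1) * gb; vb <- b2 * vb + (1 - b2) * gb^2
    w <- w - lr * (m / (1 - b1^t)) / (sqrt(v / (1 - b2^t)) + eps)
    b <- b - lr * (mb / (1 - b1^t)) / (sqrt(vb / (1 - b2^t)) + eps)
  }
  structure(list(w = w, b = b, expo = expo), class = "nd_svr")
}

#' @rdname fit_svr_poly
#' @param object fitted model
#' @param newdata n x p matrix
#' @param ... unused
#' @export
predict.nd_svr <- function(object, newdata, ...) {
  as.vector(poly3_map(as.matrix(newdata), object$expo) %*% object$w) +
    object$b
}

# --- PCA --------------------------------------------------------------------

#' Fit a PCA projection
#'
#' Centered principal components via singular value decomposition, fitted
#' on training data only; held-out data are projected with the stored
#' center and rotation.
#'
#' @param X n x p matrix of training rows
#' @param n_comp number of leading components to keep (default 30)
#' @export
fit_pca <- function(X, n_comp = 30L) {
  X <- as.matrix(X)
  n_comp <- min(n_comp, ncol(X), nrow(X) - 1L)
  ctr <- colMeans(X)
  sv <- svd(sweep(X, 2, ctr), nu = 0, nv = n_comp)
  structure(list(center = ctr, rotation = sv$v,
                 sdev = sv$d[seq_len(n_comp)] / sqrt(max(nrow(X) - 1, 1)),
                 n_comp = n_comp),
            class = "nd_pca")
}

#' @rdname fit_pca
#' @param pca fitted projection
#' @param newX rows to project
#' @export
pca_project <- function(pca, newX) {
  sweep(as.matrix(newX), 2, pca$center) %*% pca$rotation
}
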