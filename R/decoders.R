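#' Decoder model specification
#'
#' Builds the layer plan for a decoding model. Two tasks exist:
#' `classification` (feature matrix in, 5 finger-state logits out) and
#' `regression` (feature matrix in, one joint trajectory out). Five
#' families are available: shallow neural models (`cnn`, `rnn`) that take
#' the full 224 x 200 matrix, and baselines (`svm`, `rf`, `mlp`) that take
#' the reduced inputs of [baseline_inputs()].
#'
#' Neural plans (published layer counts; exact widths are this package's
#' documented defaults): the classification CNN is one convolutional layer
#' (32 filters, kernel 5, stride 2 over time) followed by three
#' fully-connected layers (512, 128, 5); the classification RNN swaps the
#' convolution for a 64-unit LSTM. Regression models have three
#' convolutional layers (32, 32, 16 filters, kernel 5, stride 2) and two
#' LSTM layers, the second a single unit that emits the trajectory
#' directly — so regression uses no fully-connected layer at all (layer
#' counts conv/lstm/fc = 3/2/0, classification CNN = 1/0/3). The `cnn`
#' and `rnn` regression variants differ in the width of the first LSTM
#' (32 vs 64 units).
#'
#' @param task `"classification"` or `"regression"`
#' @param family one of `"cnn"`, `"rnn"`, `"svm"`, `"rf"`, `"mlp"`
#' @param input_shape input dimensions, default `c(224, 200)`
#' @return an `nd_model_spec`
#' @export
model_spec <- function(task = c("classification", "regression"),
                       family = c("cnn", "rnn", "svm", "rf", "mlp"),
                       input_shape = c(224L, 200L)) {
  task <- match.arg(task)
  family <- match.arg(family)
  C <- input_shape[1]; T <- input_shape[2]
  plan <- NULL; hyper <- NULL
  if (task == "classification") {
    plan <- switch(family,
      cnn = list(list("conv", filters = 32L, kernel = 5L, stride = 2L),
                 list("relu"), list("flatten"),
                 list("dense", units = 512L), list("relu"),
                 list("dropout", p = 0.3),
                 list("dense", units = 128L), list("relu"),
                 list("dense", units = 5L)),
      rnn = list(list("lstm", units = 64L), list("last_step"),
                 list("dense", units = 512L), list("relu"),
                 list("dropout", p = 0.3),
                 list("dense", units = 128L), list("relu"),
                 list("dense", units = 5L)),
      # the MLP baseline replaces the convolutional layer with a
      # 200-unit fully-connected layer, on the 224-long mean-feature input
      mlp = list(list("dense", units = 200L), list("relu"),
                 list("dense", units = 512L), list("relu"),
                 list("dropout", p = 0.3),
                 list("dense", units = 128L), list("relu"),
                 list("dense", units = 5L)),
      svm = { hyper <- list(kernel = "rbf", C = 1); NULL },
      rf  = { hyper <- list(n_trees = 5L, max_depth = 3L); NULL })
  } else {
    plan <- switch(family,
      cnn = list(list("conv", filters = 32L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("conv", filters = 32L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("conv", filters = 16L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("lstm", units = 32L), list("lstm", units = 1L),
                 list("squeeze")),
      rnn = list(list("conv", filters = 32L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("conv", filters = 32L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("conv", filters = 16L, kernel = 5L, stride = 2L),
                 list("relu"),
                 list("lstm", units = 64L), list("lstm", units = 1L),
                 list("squeeze")),
      mlp = list(list("dense", units = 300L), list("relu"),
                 list("dense", units = 300L), list("relu"),
                 list("dense", units = 300L), list("relu"),
                 list("dense", units = 50L), list("relu"),
                 list("dense", units = 1L)),
      svm = { hyper <- list(kernel = "poly", degree = 3L, C = 1); NULL },
      rf  = { hyper <- list(n_trees = 10L, max_depth = 3L); NULL })
    # the regression MLP takes the 30 leading PCA scores per time step
    if (family == "mlp" && C == 224L) input_shape <- c(30L, T)
  }
  structure(list(task = task, family = family, input_shape = input_shape,
                 layer_plan = plan, hyper = hyper),
            class = "nd_model_spec")
}

#' Published baseline specifications
#'
#' Convenience wrapper carrying exactly the printed baseline
#' hyperparameters: RBF-kernel SVM for classification and cubic polynomial
#' kernel for regression, both with C = 1; random forests of 5
#' (classification) and 10 (regression) trees with maximum depth 3; an
#' MLP of 300, 300, 300, 50 units for regression, and for classification
#' the CNN plan with its convolution replaced by a 200-unit dense layer.
#'
#' @param family `"svm"`, `"rf"` or `"mlp"`
#' @param task `"classification"` or `"regression"`
#' @export
build_baseline <- function(family = c("svm", "rf", "mlp"),
                           task = c("classification", "regression")) {
  model_spec(match.arg(task), match.arg(family))
}

#' Count layers and learnable parameters of a spec
#'
#' `layer_counts()` reports the number of convolutional, LSTM and
#' fully-connected layers; `spec_param_count()` the number of learnable
#' parameters of the instantiated neural plan.
#'
#' @param spec an `nd_model_spec`
#' @return named integer vector `c(conv, lstm, fc)`
#' @export
layer_counts <- function(spec) {
  stopifnot(inherits(spec, "nd_model_spec"))
  kinds <- vapply(spec$layer_plan, function(l) l[[1]], character(1))
  c(conv = sum(kinds == "conv"), lstm = sum(kinds == "lstm"),
    fc = sum(kinds == "dense"))
}

#' @rdname layer_counts
#' @export
spec_param_count <- function(spec) {
  if (is.null(spec$layer_plan)) return(NA_integer_)
  nn_param_count(instantiate_plan(spec))
}

# Turn a layer plan into initialized engine layers, tracking shapes.
instantiate_plan <- function(spec) {
  C <- spec$input_shape[1]; T <- spec$input_shape[2]
  seq_input <- spec$family %in% c("cnn", "rnn") ||
    (spec$task == "classification" && spec$family == "rnn")
  dense_in <- if (!seq_input) C else NA
  layers <- list()
  for (pl in spec$layer_plan) {
    kind <- pl[[1]]
    ly <- switch(kind,
      conv = { l <- nn_conv1d(C, pl$filters, pl$kernel, pl$stride)
               T <- conv_out_len(T, pl$kernel, pl$stride); C <- pl$filters; l },
      lstm = { l <- nn_lstm(C, pl$units); C <- pl$units; l },
      dense = { l <- nn_dense(dense_in, pl$units); dense_in <- pl$units; l },
      relu = nn_relu(),
      dropout = nn_dropout(pl$p),
      flatten = { dense_in <- C * T; seq_input <- FALSE; nn_flatten() },
      last_step = { dense_in <- C; seq_input <- FALSE; nn_last_step() },
      squeeze = nn_squeeze(),
      stop("unknown plan layer ", kind))
    layers[[length(layers) + 1L]] <- ly
  }
  layers
}

# Sample indices (1..T) at which the regression network emits its outputs:
# the end of each receptive field after the strided convolutions.
conv_output_ends <- function(spec, T = spec$input_shape[2]) {
  ends <- seq_len(T)
  for (pl in spec$layer_plan) {
    if (pl[[1]] != "conv") next
    n_out <- conv_out_len(length(ends), pl$kernel, pl$stride)
    ends <- ends[(seq_len(n_out) - 1L) * pl$stride + pl$kernel]
  }
  ends
}

#' Reduced inputs for the baseline models
#'
#' Classification baselines take the average of the 224 features across
#' the 200 time steps (a length-224 vector). Regression baselines take,
#' per time step, the 30 leading principal-component scores of the
#' feature column; the projection must be fitted on the training split
#' only ([fit_pca()]).
#'
#' @param m 224 x 200 feature matrix
#' @param task `"classification"` or `"regression"`
#' @param pca_state a fitted [fit_pca()] (regression only)
#' @return length-224 vector, or 30 x 200 matrix of component scores
#' @export
baseline_inputs <- function(m, task = c("classification", "regression"),
                            pca_state = NULL) {
  task <- match.arg(task)
  if (task == "classification") return(rowMeans(m))
  if (is.null(pca_state)) stop("pca_state is required for regression",
                               call. = FALSE)
  t(pca_project(pca_state, t(m)))
}

#' Train a finger-state classifier
#'
#' Fits a multi-label model with five independent binary outputs (one per
#' finger) on per-trial feature matrices. Neural families are trained with
#' binary cross-entropy under the published Adam schedule; `svm` and `rf`
#' fit five one-vs-rest models on the mean-feature input. A label column
#' with a single class is fixed to that constant class with a warning.
#'
#' @param spec an `nd_model_spec` with `task = "classification"`
#' @param data list of `list(x = <224 x 200 matrix>, y = <5-bit vector>)`
#' @param cfg a [train_config()]
#' @return an `nd_classifier` with `$threshold` (default 0.5) and
#'   `$history` (per-epoch loss and learning rate, neural families)
#' @export
train_classifier <- function(spec, data, cfg = train_config()) {
  stopifnot(inherits(spec, "nd_model_spec"), spec$task == "classification",
            length(data) > 0)
  Y <- vapply(data, function(d) as.numeric(d$y), numeric(5))
  const_out <- apply(Y, 1, function(r) length(unique(r)) == 1L)
  if (any(const_out))
    warning("label column(s) ", paste(which(const_out), collapse = ", "),
            " are single-class; fixing those outputs to the constant class")
  fit <- NULL; history <- NULL
  if (spec$family %in% c("cnn", "rnn", "mlp")) {
    xs <- if (spec$family == "mlp")
      lapply(data, function(d) baseline_inputs(d$x, "classification"))
    else lapply(data, function(d) d$x)
    ys <- lapply(seq_along(data), function(i) Y[, i])
    stack_x <- if (spec$family == "mlp") stack_vec else stack_seq
    res <- with_seed(cfg$seed, {
      layers <- instantiate_plan(spec)
      nn_train(layers, xs, ys, cfg, loss_bce, stack_x, stack_vec)
    })
    fit <- res$layers; history <- res$history
  } else {
    X <- t(vapply(data, function(d) baseline_inputs(d$x, "classification"),
                  numeric(nrow(data[[1]]$x))))
    fit <- lapply(1:5, function(f) {
      if (const_out[f]) return(list(constant = Y[f, 1]))
      if (spec$family == "rf")
        fit_rf(X, Y[f, ], n_trees = spec$hyper$n_trees,
               max_depth = spec$hyper$max_depth, seed = cfg$seed + f)
      else fit_svm(X, Y[f, ], C = spec$hyper$C, seed = cfg$seed + f)
    })
  }
  structure(list(spec = spec, fit = fit, threshold = 0.5,
                 constant_outputs = ifelse(const_out, Y[, 1], NA),
                 history = history, cfg_hash = config_hash(cfg)),
            class = "nd_classifier")
}

#' @rdname train_classifier
#' @param object fitted classifier
#' @param newdata list of feature matrices
#' @param ... unused
#' @return `predict()` returns a list with `scores` (5 x n) and `state`
#'   (5 x n binary, thresholded at `object$threshold`)
#' @export
predict.nd_classifier <- function(object, newdata, ...) {
  spec <- object$spec
  n <- length(newdata)
  scores <- if (spec$family %in% c("cnn", "rnn", "mlp")) {
    xs <- if (spec$family == "mlp")
      lapply(newdata, function(m) baseline_inputs(m, "classification"))
    else newdata
    out <- matrix(0, 5, n)
    for (b0 in seq(1L, n, by = 64L)) {
      sel <- b0:min(b0 + 63L, n)
      x <- if (spec$family == "mlp") stack_vec(xs[sel]) else stack_seq(xs[sel])
      z <- nn_forward(object$fit, x, train = FALSE)$out
      out[, sel] <- 1 / (1 + exp(-z))
    }
    out
  } else {
    X <- t(vapply(newdata, function(m) baseline_inputs(m, "classification"),
                  numeric(nrow(newdata[[1]]))))
    do.call(rbind, lapply(1:5, function(f) {
      fm <- object$fit[[f]]
      if (!is.null(fm$constant)) rep(fm$constant, n)
      else as.numeric(predict(fm, X))
    }))
  }
  ko <- !is.na(object$constant_outputs)
  if (any(ko)) scores[ko, ] <- object$constant_outputs[ko]
  list(scores = scores, state = (scores > object$threshold) * 1L)
}

#' Train a single-joint trajectory regressor
#'
#' Fits one model that maps a trial's feature matrix to the trajectory of
#' one degree of freedom. Under `subset = "active_only"` (two-step
#' strategy) only trials whose finger is active are used; under
#' `subset = "full"` (one-step strategy) every trial is used and
#' inverse-class-frequency weights compensate the rest-heavy imbalance.
#'
#' Neural families regress the trajectory at the time steps surviving the
#' strided convolutions (their receptive-field ends) and interpolate back
#' to the full 200 steps at prediction; `mlp`, `svm` and `rf` regress the
#' trajectory value per 20 ms step from the 30 leading PCA scores of the
#' feature column.
#'
#' @param spec an `nd_model_spec` with `task = "regression"`
#' @param data list of `list(x = <matrix>, y = <trajectory vector, one
#'   value per time step>, active = <logical>)`
#' @param cfg a [train_config()]
#' @param subset `"active_only"` or `"full"`
#' @param dof_id which DOF (1..10) this model serves (provenance)
#' @param pca_state optional pre-fitted [fit_pca()] shared across DOF
#'   (baseline families); fitted on `data` when missing
#' @param step_subsample for per-step baseline families, train on every
#'   k-th time step (default 5) to bound the training-set size
#' @return an `nd_regressor`
#' @export
train_regressor <- function(spec, data, cfg = train_config(),
                            subset = c("active_only", "full"),
                            dof_id = NA_integer_, pca_state = NULL,
                            step_subsample = 5L) {
  stopifnot(inherits(spec, "nd_model_spec"), spec$task == "regression")
  subset <- match.arg(subset)
  active <- vapply(data, function(d) isTRUE(d$active), logical(1))
  if (subset == "active_only") {
    if (!any(active)) stop("active_only subset is empty for this DOF",
                           call. = FALSE)
    data <- data[active]
    wts <- NULL
  } else {
    n_pos <- sum(active); n_neg <- sum(!active)
    wts <- ifelse(active, length(data) / (2 * max(n_pos, 1)),
                  length(data) / (2 * max(n_neg, 1)))
  }
  fit <- NULL; history <- NULL; ends <- NULL; pca <- NULL
  if (spec$family %in% c("cnn", "rnn")) {
    ends <- conv_output_ends(spec, ncol(data[[1]]$x))
    xs <- lapply(data, function(d) d$x)
    ys <- lapply(data, function(d) d$y[ends])
    res <- with_seed(cfg$seed, {
      layers <- instantiate_plan(spec)
      nn_train(layers, xs, ys, cfg, loss_mse, stack_seq, stack_vec, wts)
    })
    fit <- res$layers; history <- res$history
  } else {
    # per-step training pairs
    T <- ncol(data[[1]]$x)
    steps <- seq(1L, T, by = step_subsample)
    if (spec$family == "mlp" || spec$family == "svm" || spec$family == "rf") {
      if (is.null(pca_state)) {
        cols <- do.call(rbind, lapply(data, function(d) t(d$x[, steps])))
        pca_state <- fit_pca(cols, 30L)
      }
      pca <- pca_state
      X <- do.call(rbind, lapply(data, function(d)
        pca_project(pca, t(d$x[, steps]))))
      y <- unlist(lapply(data, function(d) d$y[steps]), use.names = FALSE)
      sw <- if (is.null(wts)) NULL else rep(wts, each = length(steps))
      fit <- switch(spec$family,
        mlp = {
          xs <- lapply(seq_len(nrow(X)), function(i) X[i, ])
          ys <- as.list(y)
          res <- with_seed(cfg$seed, {
            layers <- instantiate_plan(spec)
            nn_train(layers, xs, ys, cfg, loss_mse, stack_vec, stack_vec, sw)
          })
          history <- res$history
          res$layers
        },
        svm = {
          sel <- if (is.null(sw)) seq_len(nrow(X)) else
            with_seed(cfg$seed, sample.int(nrow(X), nrow(X), replace = TRUE,
                                           prob = sw))
          fit_svr_poly(X[sel, , drop = FALSE], y[sel], C = spec$hyper$C,
                       seed = cfg$seed)
        },
        rf = {
          sel <- if (is.null(sw)) seq_len(nrow(X)) else
            with_seed(cfg$seed, sample.int(nrow(X), nrow(X), replace = TRUE,
                                           prob = sw))
          fit_rf(X[sel, , drop = FALSE], y[sel], n_trees = spec$hyper$n_trees,
                 max_depth = spec$hyper$max_depth, seed = cfg$seed)
        })
    }
  }
  structure(list(spec = spec, fit = fit, ends = ends, pca = pca,
                 dof_id = dof_id, subset = subset, history = history,
                 cfg_hash = config_hash(cfg)),
            class = "nd_regressor")
}

#' A regressor that always predicts the resting position
#'
#' Used by the pipeline for a DOF with no active training trials under the
#' two-step strategy, where the classification gate keeps it at zero.
#'
#' @param dof_id which DOF (1..10) this model serves
#' @export
constant_regressor <- function(dof_id = NA_integer_) {
  structure(list(spec = list(task = "regression", family = "constant"),
                 fit = NULL, dof_id = dof_id, subset = "active_only"),
            class = "nd_regressor")
}

#' @rdname train_regressor
#' @param object fitted regressor
#' @param newdata a single feature matrix or a list of them
#' @param ... unused
#' @return `predict()` returns a time-step trajectory (length = input
#'   columns) per input, clipped to `[0, 1]`; a matrix (steps x n) for a
#'   list input
#' @export
predict.nd_regressor <- function(object, newdata, ...) {
  single <- is.matrix(newdata)
  if (single) newdata <- list(newdata)
  T <- ncol(newdata[[1]])
  n <- length(newdata)
  out <- matrix(0, T, n)
  if (object$spec$family == "constant") {
    return(if (single) out[, 1] else out)
  }
  if (object$spec$family %in% c("cnn", "rnn")) {
    for (b0 in seq(1L, n, by = 64L)) {
      sel <- b0:min(b0 + 63L, n)
      y <- nn_forward(object$fit, stack_seq(newdata[sel]), train = FALSE)$out
      y <- matrix(y, length(object$ends), length(sel))
      for (j in seq_along(sel))
        out[, sel[j]] <- stats::approx(object$ends, y[, j], xout = seq_len(T),
                                       rule = 2)$y
    }
  } else if (object$spec$family == "mlp") {
    for (j in seq_len(n)) {
      X <- pca_project(object$pca, t(newdata[[j]]))
      z <- nn_forward(object$fit, t(X), train = FALSE)$out
      out[, j] <- as.vector(z)
    }
  } else {
    for (j in seq_len(n)) {
      X <- pca_project(object$pca, t(newdata[[j]]))
      out[, j] <- predict(object$fit, X)
    }
  }
  out <- pmin(pmax(out, 0), 1)
  if (single) out[, 1] else out
}

#' Per-DOF class balance of a training set
#'
#' Ratio of negative (inactive) to positive (active) samples at the 20 ms
#' step level, the unit at which the one-step regressors see their
#' targets. On mixed-gesture sessions that mimic the recording protocol
#' the imbalance typically falls in the 5:1 to 10:1 range.
#'
#' @param data regressor training list (see [train_regressor()])
#' @param threshold activity threshold on the trajectory (default 0.1)
#' @return negative:positive ratio (a single number)
#' @export
regression_class_ratio <- function(data, threshold = 0.1) {
  y <- unlist(lapply(data, `[[`, "y"), use.names = FALSE)
  pos <- sum(y > threshold)
  sum(y <= threshold) / max(pos, 1)
}
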