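# Minimal neural-network engine.
#
# No deep-learning runtime is assumed: the shallow decoder architectures
# used here (one or a few conv1d layers, one or two LSTM layers, small
# fully-connected stacks) are implemented directly with BLAS-backed matrix
# algebra. Sequence tensors are arrays of dim (channels, time, batch);
# dense activations are matrices of dim (units, batch). Every layer has an
# explicit backward pass; gradients are verified against finite
# differences in the test suite.

nn_conv1d <- function(in_ch, out_ch, kernel, stride = 1L) {
  sc <- sqrt(2 / (in_ch * kernel))
  list(type = "conv1d", in_ch = in_ch, out_ch = out_ch, kernel = kernel,
       stride = as.integer(stride),
       W = matrix(stats::rnorm(out_ch * in_ch * kernel, 0, sc), out_ch),
       b = numeric(out_ch))
}

nn_dense <- function(in_d, out_d) {
  sc <- sqrt(2 / in_d)
  list(type = "dense", W = matrix(stats::rnorm(out_d * in_d, 0, sc), out_d),
       b = numeric(out_d))
}

nn_lstm <- function(in_d, hidden) {
  sc <- sqrt(1 / (in_d + hidden))
  list(type = "lstm", in_d = in_d, hidden = hidden,
       Wx = matrix(stats::rnorm(4 * hidden * in_d, 0, sc), 4 * hidden),
       Wh = matrix(stats::rnorm(4 * hidden * hidden, 0, sc), 4 * hidden),
       b = numeric(4 * hidden))
}

nn_relu <- function() list(type = "relu")
nn_dropout <- function(p) list(type = "dropout", p = p)
nn_flatten <- function() list(type = "flatten")
nn_last_step <- function() list(type = "last_step")   # (C,T,B) -> (C,B)
nn_squeeze <- function() list(type = "squeeze")       # (1,T,B) -> (T,B)

conv_out_len <- function(T, kernel, stride) (T - kernel) %/% stride + 1L

# im2col column selector: columns of the (C, T*B) matrix feeding kernel
# position k, for all (t_out, batch).
conv_cols <- function(k, T, T_out, B, stride) {
  tin <- (seq_len(T_out) - 1L) * stride + k
  as.vector(outer(tin, (seq_len(B) - 1L) * T, `+`))
}

layer_forward <- function(ly, x, train = FALSE) {
  cache <- NULL
  out <- switch(ly$type,
    conv1d = {
      d <- dim(x); C <- d[1]; T <- d[2]; B <- d[3]
      T_out <- conv_out_len(T, ly$kernel, ly$stride)
      X <- matrix(x, C, T * B)
      col <- matrix(0, C * ly$kernel, T_out * B)
      for (k in seq_len(ly$kernel))
        col[(k - 1L) * C + seq_len(C), ] <-
          X[, conv_cols(k, T, T_out, B, ly$stride), drop = FALSE]
      y <- ly$W %*% col + ly$b
      cache <- list(col = col, dims = d, T_out = T_out)
      array(y, c(ly$out_ch, T_out, B))
    },
    dense = {
      cache <- list(x = x)
      ly$W %*% x + ly$b
    },
    lstm = {
      d <- dim(x); C <- d[1]; T <- d[2]; B <- d[3]; H <- ly$hidden
      h <- matrix(0, H, B); cc <- matrix(0, H, B)
      hs <- array(0, c(H, T, B))
      gates <- vector("list", T); cs <- vector("list", T)
      for (t in seq_len(T)) {
        xt <- matrix(x[, t, ], C, B)
        z <- ly$Wx %*% xt + ly$Wh %*% h + ly$b
        i <- 1 / (1 + exp(-z[seq_len(H), , drop = FALSE]))
        f <- 1 / (1 + exp(-z[H + seq_len(H), , drop = FALSE]))
        g <- tanh(z[2 * H + seq_len(H), , drop = FALSE])
        o <- 1 / (1 + exp(-z[3 * H + seq_len(H), , drop = FALSE]))
        cprev <- cc
        cc <- f * cprev + i * g
        tc <- tanh(cc)
        hprev <- h
        h <- o * tc
        hs[, t, ] <- h
        gates[[t]] <- list(i = i, f = f, g = g, o = o, cprev = cprev,
                           hprev = hprev, tc = tc)
        cs[[t]] <- cc
      }
      cache <- list(x = x, gates = gates, dims = d)
      hs
    },
    relu = { cache <- list(mask = x > 0); x * (x > 0) },
    dropout = {
      if (train && ly$p > 0) {
        mask <- array(stats::runif(length(x)) >= ly$p, dim = dim(x) %||% length(x))
        cache <- list(mask = mask)
        x * mask / (1 - ly$p)
      } else { cache <- list(mask = NULL); x }
    },
    flatten = {
      d <- dim(x); cache <- list(dims = d)
      matrix(x, prod(d[-length(d)]), d[length(d)])
    },
    last_step = {
      d <- dim(x); cache <- list(dims = d)
      matrix(x[, d[2], ], d[1], d[3])
    },
    squeeze = {
      d <- dim(x); cache <- list(dims = d)
      matrix(x[1, , ], d[2], d[3])
    },
    stop("unknown layer type ", ly$type))
  list(out = out, cache = cache)
}

layer_backward <- function(ly, dout, cache) {
  switch(ly$type,
    conv1d = {
      d <- cache$dims; C <- d[1]; T <- d[2]; B <- d[3]; T_out <- cache$T_out
      dY <- matrix(dout, ly$out_ch, T_out * B)
      gW <- dY %*% t(cache$col)
      gb <- rowSums(dY)
      dcol <- crossprod(ly$W, dY)
      dX <- matrix(0, C, T * B)
      for (k in seq_len(ly$kernel)) {
        cc <- conv_cols(k, T, T_out, B, ly$stride)
        dX[, cc] <- dX[, cc] + dcol[(k - 1L) * C + seq_len(C), , drop = FALSE]
      }
      list(dx = array(dX, d), grads = list(W = gW, b = gb))
    },
    dense = list(dx = crossprod(ly$W, dout),
                 grads = list(W = dout %*% t(cache$x), b = rowSums(dout))),
    lstm = {
      d <- cache$dims; C <- d[1]; T <- d[2]; B <- d[3]; H <- ly$hidden
      gWx <- matrix(0, 4 * H, C); gWh <- matrix(0, 4 * H, H)
      gb <- numeric(4 * H)
      dx <- array(0, d)
      dh_next <- matrix(0, H, B); dc_next <- matrix(0, H, B)
      for (t in rev(seq_len(T))) {
        gt <- cache$gates[[t]]
        dh <- matrix(dout[, t, ], H, B) + dh_next
        dc <- dc_next + dh * gt$o * (1 - gt$tc^2)
        dzo <- dh * gt$tc * gt$o * (1 - gt$o)
        dzi <- dc * gt$g * gt$i * (1 - gt$i)
        dzf <- dc * gt$cprev * gt$f * (1 - gt$f)
        dzg <- dc * gt$i * (1 - gt$g^2)
        dc_next <- dc * gt$f
        dz <- rbind(dzi, dzf, dzg, dzo)
        xt <- matrix(cache$x[, t, ], C, B)
        gWx <- gWx + dz %*% t(xt)
        gWh <- gWh + dz %*% t(gt$hprev)
        gb <- gb + rowSums(dz)
        dx[, t, ] <- crossprod(ly$Wx, dz)
        dh_next <- crossprod(ly$Wh, dz)
      }
      list(dx = dx, grads = list(Wx = gWx, Wh = gWh, b = gb))
    },
    relu = list(dx = dout * cache$mask, grads = NULL),
    dropout = {
      if (is.null(cache$mask)) list(dx = dout, grads = NULL)
      else list(dx = dout * cache$mask / (1 - ly$p), grads = NULL)
    },
    flatten = list(dx = array(dout, cache$dims), grads = NULL),
    last_step = {
      d <- cache$dims
      dx <- array(0, d)
      dx[, d[2], ] <- dout
      list(dx = dx, grads = NULL)
    },
    squeeze = {
      d <- cache$dims
      list(dx = array(dout, d), grads = NULL)
    })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

nn_forward <- function(layers, x, train = FALSE) {
  caches <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    r <- layer_forward(layers[[i]], x, train)
    x <- r$out
    caches[[i]] <- r$cache
  }
  list(out = x, caches = caches)
}

nn_backward <- function(layers, caches, dout) {
  grads <- vector("list", length(layers))
  for (i in rev(seq_along(layers))) {
    r <- layer_backward(layers[[i]], dout, caches[[i]])
    dout <- r$dx
    grads[i] <- list(r$grads)   # not [[<-]]: NULL grads must keep their slot
  }
  list(grads = grads, dx = dout)
}

PARAM_NAMES <- c("W", "b", "Wx", "Wh")

nn_param_count <- function(layers) {
  sum(vapply(layers, function(ly)
    sum(vapply(PARAM_NAMES, function(p)
      if (!is.null(ly[[p]])) length(ly[[p]]) else 0L, numeric(1))),
    numeric(1)))
}

# --- losses -----------------------------------------------------------------

# Binary cross-entropy with logits; y in {0,1}, optional per-sample
# (column) weights. Loss is the weighted mean over all (output, sample)
# elements. Returns list(loss, grad) with grad matching z's shape.
loss_bce <- function(z, y, w = NULL) {
  if (is.null(w)) w <- rep(1, ncol(z))
  wm <- rep(w, each = nrow(z))
  elems <- pmax(z, 0) - z * y + log1p(exp(-abs(z)))    # stable BCE
  p <- 1 / (1 + exp(-z))
  list(loss = sum(wm * elems) / sum(wm),
       grad = matrix(wm * (p - y) / sum(wm), nrow(z)))
}

# Mean squared error over all elements, with optional per-sample (last
# dimension) weights. Returns list(loss, grad).
loss_mse <- function(pred, target, w = NULL) {
  dm <- dim(pred)
  B <- if (is.null(dm)) length(pred) else dm[length(dm)]
  if (is.null(w)) w <- rep(1, B)
  per <- length(pred) / B
  wm <- rep(w, each = per)
  diffv <- pred - target
  g <- 2 * wm * diffv / sum(wm)
  if (!is.null(dm)) dim(g) <- dm
  list(loss = sum(wm * diffv^2) / sum(wm), grad = g)
}

# --- optimizer and scheduler ------------------------------------------------

adam_init <- function(layers) {
  lapply(layers, function(ly)
    lapply(PARAM_NAMES[vapply(PARAM_NAMES, function(p) !is.null(ly[[p]]),
                              logical(1))],
           function(p) list(name = p, m = ly[[p]] * 0, v = ly[[p]] * 0)))
}

adam_step <- function(layers, grads, state, lr, beta1, beta2,
                      weight_decay, t, eps = 1e-8) {
  for (i in seq_along(layers)) {
    if (is.null(grads[[i]])) next
    for (j in seq_along(state[[i]])) {
      p <- state[[i]][[j]]$name
      g <- grads[[i]][[p]] + weight_decay * layers[[i]][[p]]
      st <- state[[i]][[j]]
      st$m <- beta1 * st$m + (1 - beta1) * g
      st$v <- beta2 * st$v + (1 - beta2) * g^2
      mh <- st$m / (1 - beta1^t)
      vh <- st$v / (1 - beta2^t)
      layers[[i]][[p]] <- layers[[i]][[p]] - lr * mh / (sqrt(vh) + eps)
      state[[i]][[j]] <- st
    }
  }
  list(layers = layers, state = state)
}

#' Plateau learning-rate scheduler
#'
#' The learning rate starts at `lr_init` and is divided by `factor` each
#' time the training loss has failed to improve for `patience` consecutive
#' epochs. The returned object is stepped once per epoch with that epoch's
#' loss and yields the rate to use for the next epoch; the sequence is
#' non-increasing by construction.
#'
#' @param lr_init initial learning rate (default 0.005)
#' @param factor drop factor (default 10)
#' @param patience epochs without improvement before a drop (default 2)
#' @param tol minimum decrease that counts as an improvement
#' @return list with `step(loss)` returning the updated rate, and `rate()`
#' @export
plateau_scheduler <- function(lr_init = 0.005, factor = 10, patience = 2,
                              tol = 0) {
  env <- new.env()
  env$lr <- lr_init
  env$best <- Inf
  env$bad <- 0L
  list(
    step = function(loss) {
      if (loss < env$best - tol) {
        env$best <- loss
        env$bad <- 0L
      } else {
        env$bad <- env$bad + 1L
        if (env$bad >= patience) {
          env$lr <- env$lr / factor
          env$bad <- 0L
        }
      }
      env$lr
    },
    rate = function() env$lr)
}

#' Training configuration
#'
#' The optimizer follows the published schedule: Adam with beta1 = 0.99
#' (as printed — deliberately not the conventional 0.9), beta2 = 0.999, L2
#' weight decay 1e-5, minibatch 38, 10 minibatches per epoch, learning
#' rate initialized to 0.005 and cut tenfold after two epochs without
#' training-loss improvement. Training stops at `max_epochs` or when the
#' rate falls below `lr_min`.
#'
#' @param max_epochs cap on epochs (default 200)
#' @param minibatch minibatch size (default 38)
#' @param minibatches_per_epoch minibatches per epoch (default 10)
#' @param lr_init,lr_drop_factor,plateau_epochs,lr_min scheduler settings
#' @param beta1,beta2,weight_decay Adam settings
#' @param seed RNG seed controlling init, batching and dropout
#' @export
train_config <- function(max_epochs = 200L, minibatch = 38L,
                         minibatches_per_epoch = 10L, lr_init = 0.005,
                         lr_drop_factor = 10, plateau_epochs = 2L,
                         lr_min = 1e-6, beta1 = 0.99, beta2 = 0.999,
                         weight_decay = 1e-5, seed = 1L) {
  stopifnot(max_epochs >= 1, minibatch >= 1, lr_init > 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 minibatch = as.integer(minibatch),
                 minibatches_per_epoch = as.integer(minibatches_per_epoch),
                 lr_init = lr_init, lr_drop_factor = lr_drop_factor,
                 plateau_epochs = as.integer(plateau_epochs),
                 lr_min = lr_min, beta1 = beta1, beta2 = beta2,
                 weight_decay = weight_decay, seed = as.integer(seed)),
            class = "nd_train_config")
}

# Core SGD loop shared by the neural decoders. `xs` is a list of inputs
# (arrays or vectors), `ys` a list of targets, `wts` optional per-sample
# weights; `stack_x`/`stack_y` collate a minibatch. `loss_fn(pred, target,
# w)` returns list(loss, grad). Deterministic for a fixed cfg$seed.
nn_train <- function(layers, xs, ys, cfg, loss_fn, stack_x, stack_y,
                     wts = NULL) {
  n <- length(xs)
  state <- adam_init(layers)
  sched <- plateau_scheduler(cfg$lr_init, cfg$lr_drop_factor,
                             cfg$plateau_epochs)
  lr <- cfg$lr_init
  history <- data.frame(epoch = integer(), loss = numeric(), lr = numeric())
  t_adam <- 0L
  for (epoch in seq_len(cfg$max_epochs)) {
    if (lr < cfg$lr_min) break
    # an epoch is exactly `minibatches_per_epoch` minibatches; small
    # datasets are resampled with replacement so epochs keep their size
    # (and their loss estimate keeps its variance) regardless of n
    epoch_n <- cfg$minibatch * cfg$minibatches_per_epoch
    order <- sample.int(n, epoch_n, replace = n < epoch_n)
    eloss <- 0; nb <- 0L
    for (b0 in seq(1L, length(order), by = cfg$minibatch)) {
      sel <- order[b0:min(b0 + cfg$minibatch - 1L, length(order))]
      x <- stack_x(xs[sel])
      y <- stack_y(ys[sel])
      w <- if (is.null(wts)) NULL else wts[sel]
      fw <- nn_forward(layers, x, train = TRUE)
      ls <- loss_fn(fw$out, y, w)
      bw <- nn_backward(layers, fw$caches, ls$grad)
      t_adam <- t_adam + 1L
      up <- adam_step(layers, bw$grads, state, lr, cfg$beta1, cfg$beta2,
                      cfg$weight_decay, t_adam)
      layers <- up$layers; state <- up$state
      eloss <- eloss + ls$loss; nb <- nb + 1L
    }
    eloss <- eloss / nb
    history <- rbind(history, data.frame(epoch = epoch, loss = eloss, lr = lr))
    lr <- sched$step(eloss)
  }
  list(layers = layers, history = history)
}

# Collation helpers: stack a list of (C,T) matrices into (C,T,B), or a
# list of vectors into a (D,B) matrix.
stack_seq <- function(lst) {
  d <- dim(lst[[1]])
  array(unlist(lst, use.names = FALSE), c(d[1], d[2], length(lst)))
}
stack_vec <- function(lst) matrix(unlist(lst, use.names = FALSE),
                                  ncol = length(lst))
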