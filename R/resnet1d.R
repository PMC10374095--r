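# 1-D residual convolutional network for end-to-end window classification.
#
# Architecture: five residual blocks, each halving the signal length
# (main path: kernel-121 stride-2 convolution with symmetric padding 60 ->
# batch norm; skip path: kernel-1 stride-2 convolution -> batch norm;
# sum -> ReLU -> dropout), then a kernel-1 convolution to a single channel
# with batch norm, flatten, one fully connected unit and a sigmoid.  A
# 12,000-sample window therefore yields a 375-length feature vector
# (12000 -> 6000 -> 3000 -> 1500 -> 750 -> 375).
#
# No deep-learning runtime exists in this environment, so forward, backward
# and the AdamW optimizer are implemented directly.  Convolutions are
# evaluated one kernel tap at a time as dense (C_out x C_in) x
# (C_in x L_out*B) matrix products, which routes all heavy lifting through
# BLAS; a batch is stored as a C x (L*B) matrix with samples concatenated
# along columns.

#' Residual CNN architecture configuration
#'
#' @param in_channels input channel count (retained gastric channels,
#'   default 3).
#' @param block_channels output channels of the five residual blocks.
#' @param block_kernel main-path kernel size (default 121, i.e. 0.6 s at
#'   200 Hz).
#' @param block_stride stride of every block (default 2).
#' @param dropout_rate dropout probability after each block (default 0.2).
#' @param seed parameter-initialization seed.
#' @return object of class `cnn_config`.
#' @export
cnn_config <- function(in_channels = 3L, block_channels = c(6L, 12L, 24L, 48L, 96L),
                       block_kernel = 121L, block_stride = 2L,
                       dropout_rate = 0.2, seed = 1L) {
  stopifnot(length(block_channels) == 5L, all(block_channels >= 1L),
            block_kernel %% 2L == 1L, block_stride == 2L,
            dropout_rate >= 0, dropout_rate < 1, in_channels >= 1L)
  structure(list(in_channels = as.integer(in_channels),
                 block_channels = as.integer(block_channels),
                 block_kernel = as.integer(block_kernel),
                 block_stride = as.integer(block_stride),
                 dropout_rate = dropout_rate, seed = seed),
            class = "cnn_config")
}

#' Training configuration for the residual CNN
#'
#' @param max_epochs maximum training epochs (default 200).
#' @param batch_size minibatch size (default 20).
#' @param learning_rate AdamW learning rate (default 0.001).
#' @param patience early-stopping patience in epochs (default 50).
#' @param weight_decay decoupled weight-decay coefficient (default 0.01).
#' @param seed RNG seed for shuffling and dropout.
#' @return object of class `train_config`.
#' @export
train_config <- function(max_epochs = 200L, batch_size = 20L,
                         learning_rate = 1e-3, patience = 50L,
                         weight_decay = 0.01, seed = 1L) {
  stopifnot(batch_size >= 1L, patience >= 1L, patience < max_epochs,
            learning_rate > 0, weight_decay >= 0)
  structure(list(max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 patience = as.integer(patience),
                 weight_decay = weight_decay, seed = seed),
            class = "train_config")
}

# ---- convolution plumbing --------------------------------------------------

# Column-index plan for a strided 1-D convolution over a batch stored as
# C x (L*B).  One entry per kernel tap: input columns `ic` map onto output
# columns `oc` (taps reaching into the zero padding simply skip those
# positions).  Plans are cached per (L_in, B, K, stride, pad).
conv_plan <- function(cache, L_in, B, K, stride, pad) {
  key <- paste(L_in, B, K, stride, pad, sep = "_")
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  L_out <- (L_in + 2L * pad - K) %/% stride + 1L
  off_in <- (seq_len(B) - 1L) * L_in
  off_out <- (seq_len(B) - 1L) * L_out
  taps <- vector("list", K)
  for (k in seq_len(K)) {
    p <- (seq_len(L_out) - 1L) * stride + k - pad
    valid <- which(p >= 1L & p <= L_in)
    if (length(valid) == 0L) next
    taps[[k]] <- list(
      ic = rep(p[valid], B) + rep(off_in, each = length(valid)),
      oc = rep(valid, B) + rep(off_out, each = length(valid)),
      full = length(valid) == L_out)
  }
  res <- list(L_out = L_out, taps = taps)
  cache[[key]] <- res
  res
}

conv_fwd <- function(X, W, plan, B) {
  C_out <- dim(W)[1]
  Y <- matrix(0, C_out, plan$L_out * B)
  for (k in seq_along(plan$taps)) {
    tp <- plan$taps[[k]]
    if (is.null(tp)) next
    Z <- matrix(W[, , k], C_out) %*% X[, tp$ic, drop = FALSE]
    if (tp$full) Y <- Y + Z else Y[, tp$oc] <- Y[, tp$oc, drop = FALSE] + Z
  }
  Y
}

conv_bwd <- function(dY, X, W, plan) {
  dW <- array(0, dim(W))
  dX <- matrix(0, nrow(X), ncol(X))
  C_out <- dim(W)[1]
  for (k in seq_along(plan$taps)) {
    tp <- plan$taps[[k]]
    if (is.null(tp)) next
    dYk <- if (tp$full) dY else dY[, tp$oc, drop = FALSE]
    Xk <- X[, tp$ic, drop = FALSE]
    dW[, , k] <- tcrossprod(dYk, Xk)
    dX[, tp$ic] <- dX[, tp$ic, drop = FALSE] +
      crossprod(matrix(W[, , k], C_out), dYk)
  }
  list(dW = dW, dX = dX)
}

# ---- batch normalization ---------------------------------------------------

bn_fwd <- function(X, gamma, beta, run, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    mu <- rowMeans(X)
    v <- rowMeans(X * X) - mu^2
    v <- pmax(v, 0)
    invstd <- 1 / sqrt(v + eps)
    xhat <- (X - mu) * invstd
    N <- ncol(X)
    run$mean <- (1 - momentum) * run$mean + momentum * mu
    run$var <- (1 - momentum) * run$var + momentum * v * N / max(N - 1, 1)
  } else {
    invstd <- 1 / sqrt(run$var + eps)
    xhat <- (X - run$mean) * invstd
  }
  list(Y = xhat * gamma + beta, xhat = xhat, invstd = invstd, run = run)
}

bn_bwd <- function(dY, cache, gamma) {
  N <- ncol(dY)
  dbeta <- rowSums(dY)
  dgamma <- rowSums(dY * cache$xhat)
  dX <- (gamma * cache$invstd) * (dY - dbeta / N - cache$xhat * (dgamma / N))
  list(dX = dX, dgamma = dgamma, dbeta = dbeta)
}

# ---- model -----------------------------------------------------------------

#' Build the residual CNN
#'
#' @param cfg a [cnn_config()].
#' @param input_len samples per window (default 12000; must be at least 32 so
#'   all five stride-2 blocks shorten the signal).
#' @return object of class `cnn_model`.  The flattened feature length is
#'   `ceiling(input_len / 32)` (375 at 12,000).
#' @export
build_model <- function(cfg = cnn_config(), input_len = 12000L) {
  input_len <- as.integer(input_len)
  if (input_len < 32L) {
    stop("input_len must be >= 32 (five stride-2 blocks); got ", input_len)
  }
  lens <- integer(6)
  lens[1] <- input_len
  for (b in 1:5) lens[b + 1] <- (lens[b] + 1L) %/% 2L  # ceil(L/2)
  feature_len <- lens[6]
  chans <- c(cfg$in_channels, cfg$block_channels)
  K <- cfg$block_kernel
  params <- list()
  running <- list()
  with_seed(stable_seed(cfg$seed, "init"), {
    for (b in 1:5) {
      ci <- chans[b]; co <- chans[b + 1]
      params[[paste0("Wm", b)]] <- array(stats::rnorm(co * ci * K, 0, sqrt(2 / (ci * K))),
                                         dim = c(co, ci, K))
      params[[paste0("Ws", b)]] <- array(stats::rnorm(co * ci, 0, sqrt(2 / ci)),
                                         dim = c(co, ci, 1))
      params[[paste0("gm", b)]] <- rep(1, co); params[[paste0("bm", b)]] <- rep(0, co)
      params[[paste0("gs", b)]] <- rep(1, co); params[[paste0("bs", b)]] <- rep(0, co)
      running[[paste0("m", b)]] <- list(mean = rep(0, co), var = rep(1, co))
      running[[paste0("s", b)]] <- list(mean = rep(0, co), var = rep(1, co))
    }
    co <- chans[6]
    params$W6 <- array(stats::rnorm(co, 0, sqrt(2 / co)), dim = c(1, co, 1))
    params$g6 <- 1; params$b6 <- 0
    running$bn6 <- list(mean = 0, var = 1)
    params$fc_w <- stats::rnorm(feature_len, 0, sqrt(1 / feature_len))
    params$fc_b <- 0
  })
  structure(list(cfg = cfg, input_len = input_len, lens = lens,
                 feature_len = feature_len, params = params,
                 running = running, plans = new.env(parent = emptyenv())),
            class = "cnn_model")
}

#' Number of learnable parameters
#' @param model a `cnn_model`.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

# Forward pass over a batch.  X: in_channels x (input_len * B).
# Returns scores, pre-sigmoid logits, per-block feature lengths and (when
# training) the caches needed for backprop.
cnn_forward <- function(model, X, B, training = FALSE) {
  cfg <- model$cfg
  pr <- model$params
  pad <- (cfg$block_kernel - 1L) %/% 2L
  caches <- vector("list", 5)
  for (b in 1:5) {
    pm <- conv_plan(model$plans, model$lens[b], B, cfg$block_kernel, 2L, pad)
    ps <- conv_plan(model$plans, model$lens[b], B, 1L, 2L, 0L)
    Zm <- conv_fwd(X, pr[[paste0("Wm", b)]], pm, B)
    Zs <- conv_fwd(X, pr[[paste0("Ws", b)]], ps, B)
    bm <- bn_fwd(Zm, pr[[paste0("gm", b)]], pr[[paste0("bm", b)]],
                 model$running[[paste0("m", b)]], training)
    bs <- bn_fwd(Zs, pr[[paste0("gs", b)]], pr[[paste0("bs", b)]],
                 model$running[[paste0("s", b)]], training)
    if (training) {
      model$running[[paste0("m", b)]] <- bm$run
      model$running[[paste0("s", b)]] <- bs$run
    }
    S <- bm$Y + bs$Y
    mask <- S > 0
    R <- S * mask
    if (training && cfg$dropout_rate > 0) {
      dmask <- (matrix(stats::runif(length(R)), nrow(R)) >= cfg$dropout_rate) /
        (1 - cfg$dropout_rate)
      O <- R * dmask
    } else {
      dmask <- NULL
      O <- R
    }
    caches[[b]] <- list(X = X, bm = bm, bs = bs, relu_mask = mask,
                        dmask = dmask, pm = pm, ps = ps)
    X <- O
  }
  p6 <- conv_plan(model$plans, model$lens[6], B, 1L, 1L, 0L)
  Z6 <- conv_fwd(X, pr$W6, p6, B)
  b6 <- bn_fwd(Z6, pr$g6, pr$b6, model$running$bn6, training)
  if (training) model$running$bn6 <- b6$run
  F6 <- matrix(b6$Y, model$feature_len, B)
  z <- as.vector(crossprod(F6, pr$fc_w)) + pr$fc_b
  list(scores = stats::plogis(z), z = z,
       caches = if (training) list(blocks = caches, X5 = X, b6 = b6,
                                   F6 = F6, p6 = p6) else NULL,
       model = model)
}

cnn_backward <- function(model, fwd, dz, B) {
  pr <- model$params
  grads <- list()
  cc <- fwd$caches
  grads$fc_w <- as.vector(cc$F6 %*% dz)
  grads$fc_b <- sum(dz)
  dF6 <- outer(pr$fc_w, dz)
  dY6 <- matrix(dF6, 1, model$feature_len * B)
  g6 <- bn_bwd(dY6, cc$b6, pr$g6)
  grads$g6 <- g6$dgamma; grads$b6 <- g6$dbeta
  cb6 <- conv_bwd(g6$dX, cc$X5, pr$W6, cc$p6)
  grads$W6 <- cb6$dW
  dX <- cb6$dX
  for (b in 5:1) {
    cache <- cc$blocks[[b]]
    dO <- dX
    dR <- if (is.null(cache$dmask)) dO else dO * cache$dmask
    dS <- dR * cache$relu_mask
    gm <- bn_bwd(dS, cache$bm, pr[[paste0("gm", b)]])
    gs <- bn_bwd(dS, cache$bs, pr[[paste0("gs", b)]])
    grads[[paste0("gm", b)]] <- gm$dgamma; grads[[paste0("bm", b)]] <- gm$dbeta
    grads[[paste0("gs", b)]] <- gs$dgamma; grads[[paste0("bs", b)]] <- gs$dbeta
    cm <- conv_bwd(gm$dX, cache$X, pr[[paste0("Wm", b)]], cache$pm)
    cs <- conv_bwd(gs$dX, cache$X, pr[[paste0("Ws", b)]], cache$ps)
    grads[[paste0("Wm", b)]] <- cm$dW
    grads[[paste0("Ws", b)]] <- cs$dW
    dX <- cm$dX + cs$dX
  }
  grads
}

bce_loss <- function(p, y, eps = 1e-12) {
  -mean(y * log(pmax(p, eps)) + (1 - y) * log(pmax(1 - p, eps)))
}

adamw_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adamw_step <- function(params, grads, state, lr, wd, beta1 = 0.9,
                       beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           wd * params[[nm]])
  }
  list(params = params, state = state)
}

windows_to_batch <- function(windows, idx = seq_along(windows)) {
  do.call(cbind, lapply(windows[idx], `[[`, "data"))
}

# Incremental early-stopping state machine (strictly lower validation loss
# counts as improvement; training halts once `patience` epochs pass without
# one).
es_init <- function(patience) {
  list(patience = patience, best_loss = Inf, best_epoch = 0L,
       epoch = 0L, stop = FALSE)
}

es_step <- function(st, loss) {
  st$epoch <- st$epoch + 1L
  if (loss < st$best_loss) {
    st$best_loss <- loss
    st$best_epoch <- st$epoch
  }
  if (st$epoch - st$best_epoch >= st$patience) st$stop <- TRUE
  st
}

#' Replay an early-stopping schedule on a fixed validation-loss trace
#'
#' Pure helper exposing the training loop's stopping rule: training halts
#' after epoch `best_epoch + patience` (or `max_epochs`), and the retained
#' checkpoint is the epoch with the minimum validation loss.
#'
#' @param val_losses per-epoch validation losses.
#' @param patience epochs without improvement tolerated.
#' @param max_epochs hard cap.
#' @return list with `best_epoch`, `n_epochs`, `stopped_early`.
#' @export
early_stop_schedule <- function(val_losses, patience = 50L, max_epochs = 200L) {
  st <- es_init(patience)
  n <- 0L
  for (loss in val_losses[seq_len(min(length(val_losses), max_epochs))]) {
    st <- es_step(st, loss)
    n <- st$epoch
    if (st$stop) break
  }
  list(best_epoch = st$best_epoch, n_epochs = n, stopped_early = st$stop)
}

#' Train the residual CNN
#'
#' Minimizes binary cross-entropy with AdamW over shuffled minibatches;
#' validation loss is evaluated once per epoch in inference mode (running
#' batch-norm statistics, no dropout) and drives early stopping.  The
#' returned model carries the parameters of the best validation epoch.
#'
#' @param model a [build_model()] result.
#' @param train_windows,val_windows lists of `labeled_window`s; both classes
#'   must appear in training, and validation must be non-empty.
#' @param tcfg a [train_config()].
#' @param verbose print per-epoch losses.
#' @return list with the trained `model` and a `history` (per-epoch
#'   `train_loss`, `val_loss`, `best_epoch`, `stopped_early`).
#' @export
train_model <- function(model, train_windows, val_windows,
                        tcfg = train_config(), verbose = FALSE) {
  ytr <- window_labels(train_windows)
  if (length(unique(ytr)) < 2L) stop("training windows contain a single class")
  if (length(val_windows) == 0L) stop("validation set is empty")
  yva <- window_labels(val_windows)
  check_window_shape(model, train_windows[[1]])
  Xva <- windows_to_batch(val_windows)
  n <- length(train_windows)
  state <- adamw_init(model$params)
  es <- es_init(tcfg$patience)
  train_hist <- val_hist <- numeric(0)
  best <- list(params = model$params, running = model$running)
  with_seed(stable_seed(tcfg$seed, "train"), {
    for (epoch in seq_len(tcfg$max_epochs)) {
      ord <- sample.int(n)
      starts <- seq(1L, n, by = tcfg$batch_size)
      batch_losses <- numeric(length(starts))
      for (i in seq_along(starts)) {
        idx <- ord[starts[i]:min(starts[i] + tcfg$batch_size - 1L, n)]
        B <- length(idx)
        Xb <- windows_to_batch(train_windows, idx)
        fwd <- cnn_forward(model, Xb, B, training = TRUE)
        model <- fwd$model
        loss <- bce_loss(fwd$scores, ytr[idx])
        if (!is.finite(loss)) {
          cond <- structure(
            class = c("slowwave_nan_loss", "error", "condition"),
            list(message = paste0("training diverged (non-finite loss) at epoch ",
                                  epoch),
                 call = sys.call(-1),
                 history = list(train_loss = train_hist, val_loss = val_hist)))
          stop(cond)
        }
        batch_losses[i] <- loss
        dz <- (fwd$scores - ytr[idx]) / B
        grads <- cnn_backward(model, fwd, dz, B)
        upd <- adamw_step(model$params, grads, state, tcfg$learning_rate,
                          tcfg$weight_decay)
        model$params <- upd$params
        state <- upd$state
      }
      vl <- bce_loss(cnn_forward(model, Xva, length(val_windows),
                                 training = FALSE)$scores, yva)
      train_hist <- c(train_hist, mean(batch_losses))
      val_hist <- c(val_hist, vl)
      if (verbose) {
        message(sprintf("epoch %3d train %.4f val %.4f", epoch,
                        mean(batch_losses), vl))
      }
      es <- es_step(es, vl)
      if (es$best_epoch == epoch) {
        best <- list(params = model$params, running = model$running)
      }
      if (es$stop) break
    }
  })
  model$params <- best$params
  model$running <- best$running
  list(model = model,
       history = list(train_loss = train_hist, val_loss = val_hist,
                      best_epoch = es$best_epoch,
                      stopped_early = es$stop))
}

check_window_shape <- function(model, w) {
  if (nrow(w$data) != model$cfg$in_channels) {
    stop("channel-count mismatch: model expects ", model$cfg$in_channels,
         " channels, window has ", nrow(w$data))
  }
  if (ncol(w$data) != model$input_len) {
    stop("window length mismatch: model expects ", model$input_len,
         " samples, window has ", ncol(w$data))
  }
  invisible(TRUE)
}

#' Score windows with a (trained) CNN
#'
#' Inference mode: dropout off, batch-norm running statistics; scores are
#' therefore independent of batch composition.
#'
#' @param model a `cnn_model`.
#' @param windows list of `labeled_window`s.
#' @param batch_size scoring batch size.
#' @return numeric scores in (0, 1).
#' @export
score_windows <- function(model, windows, batch_size = 32L) {
  if (length(windows) == 0L) return(numeric(0))
  check_window_shape(model, windows[[1]])
  out <- numeric(length(windows))
  starts <- seq(1L, length(windows), by = batch_size)
  for (s in starts) {
    idx <- s:min(s + batch_size - 1L, length(windows))
    X <- windows_to_batch(windows, idx)
    out[idx] <- cnn_forward(model, X, length(idx), training = FALSE)$scores
  }
  out
}
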