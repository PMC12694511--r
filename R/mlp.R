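#' Configuration of the flow-regression MLP
#'
#' Defaults are the published winning configuration of the flow regressor:
#' hidden layers `[150, 550, 800, 200, 550]`, dropout rate 0.3, AdamW with
#' learning rate 1.5e-4, Huber loss, and ten Monte-Carlo-dropout passes at
#' inference. Epoch budget, patience and batch size are training-procedure
#' knobs (the model definition itself fixes none).
#'
#' @param hidden Integer vector of hidden-layer widths.
#' @param dropout_rate Dropout probability on hidden activations, in (0, 1).
#' @param learning_rate AdamW learning rate.
#' @param weight_decay Decoupled weight decay (applied to weights, not biases).
#' @param huber_delta Huber loss transition point (scaled target units).
#' @param mc_passes Number of stochastic forward passes for the reliability
#'   estimate (>= 2).
#' @param input_window Odd number of consecutive feature rows presented per
#'   target sample (default 1: pointwise, one five-feature row).
#' @param max_epochs,patience Early-stopping budget on the held-in validation
#'   split.
#' @param batch_size Minibatch size.
#' @param val_fraction Fraction of training rows held in for early stopping.
#' @return An object of class `respiq_mlp_config`.
#' @export
mlp_config <- function(hidden = c(150, 550, 800, 200, 550),
                       dropout_rate = 0.3,
                       learning_rate = 1.5e-4,
                       weight_decay = 0.01,
                       huber_delta = 1,
                       mc_passes = 10,
                       input_window = 1,
                       max_epochs = 30,
                       patience = 5,
                       batch_size = 256,
                       val_fraction = 0.1) {
  if (any(hidden <= 0)) abort("hidden sizes must be positive")
  if (dropout_rate <= 0 || dropout_rate >= 1) abort("dropout_rate must lie in (0, 1)")
  if (mc_passes < 2) abort("mc_passes must be >= 2")
  if (input_window %% 2 != 1) abort("input_window must be odd")
  structure(list(hidden = hidden, dropout_rate = dropout_rate,
                 learning_rate = learning_rate, weight_decay = weight_decay,
                 huber_delta = huber_delta, mc_passes = mc_passes,
                 input_window = input_window, max_epochs = max_epochs,
                 patience = patience, batch_size = batch_size,
                 val_fraction = val_fraction),
            class = "respiq_mlp_config")
}

huber_loss <- function(err, delta) {
  a <- abs(err)
  mean(ifelse(a <= delta, 0.5 * err^2, delta * (a - 0.5 * delta)))
}

huber_grad <- function(err, delta) {
  pmin(pmax(err, -delta), delta)
}

# Expand a feature matrix into sliding windows of `w` consecutive rows
# (edge rows replicated), so row i carries rows (i-w2):(i+w2).
make_windows <- function(X, w) {
  if (w == 1L) return(X)
  w2 <- (w - 1L) %/% 2L
  n <- nrow(X)
  idx <- function(shift) pmin(pmax(seq_len(n) + shift, 1L), n)
  do.call(cbind, lapply(seq(-w2, w2), function(s) X[idx(s), , drop = FALSE]))
}

mlp_init <- function(dims) {
  L <- length(dims) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (l in seq_len(L)) {
    bound <- 1 / sqrt(dims[l])
    W[[l]] <- matrix(runif(dims[l] * dims[l + 1], -bound, bound), dims[l], dims[l + 1])
    b[[l]] <- runif(dims[l + 1], -bound, bound)
  }
  list(W = W, b = b)
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# Forward pass. `dropout` > 0 draws fresh inverted-dropout masks on hidden
# activations (training and Monte-Carlo inference); 0 is the deterministic net.
mlp_forward <- function(params, X, dropout = 0, keep_state = FALSE) {
  L <- length(params$W)
  A <- X
  Zs <- if (keep_state) vector("list", L) else NULL
  As <- if (keep_state) vector("list", L) else NULL
  Ms <- if (keep_state) vector("list", L) else NULL
  for (l in seq_len(L - 1L)) {
    Z <- add_bias(A %*% params$W[[l]], params$b[[l]])
    H <- pmax(Z, 0)
    M <- NULL
    if (dropout > 0) {
      keep <- 1 - dropout
      M <- matrix((runif(length(H)) < keep) / keep, nrow(H), ncol(H))
      H <- H * M
    }
    if (keep_state) { Zs[[l]] <- Z; As[[l]] <- A; Ms[[l]] <- M }
    A <- H
  }
  out <- add_bias(A %*% params$W[[L]], params$b[[L]])
  if (keep_state) {
    As[[L]] <- A
    list(out = drop(out), Zs = Zs, As = As, Ms = Ms)
  } else {
    drop(out)
  }
}

#' Train the flow-regression MLP
#'
#' Minibatch AdamW on the Huber loss with inverted dropout on hidden ReLU
#' activations. A held-in validation split of the training rows drives early
#' stopping (patience on the validation Huber loss, evaluated with dropout
#' off); the best-epoch weights are restored. All randomness (initialisation,
#' validation split, shuffling, dropout masks) is governed by `seed`.
#'
#' @param x Numeric feature matrix (rows aligned with `y`), already scaled.
#' @param y Numeric target vector in scaled units.
#' @param config An [mlp_config()].
#' @param seed Integer seed.
#' @return An object of class `respiq_mlp`: weights, config, training log.
#' @export
mlp_fit <- function(x, y, config = mlp_config(), seed = 1L) {
  stopifnot(inherits(config, "respiq_mlp_config"))
  x <- as.matrix(x)
  if (nrow(x) != length(y)) abort("x and y must have matching rows")
  check_finite(x, "training features"); check_finite(y, "training targets")
  set.seed(seed)
  x <- make_windows(x, config$input_window)

  n <- nrow(x)
  n_val <- max(1L, round(config$val_fraction * n))
  val_idx <- sort(sample.int(n, n_val))
  tr_idx <- setdiff(seq_len(n), val_idx)
  Xtr <- x[tr_idx, , drop = FALSE]; ytr <- y[tr_idx]
  Xval <- x[val_idx, , drop = FALSE]; yval <- y[val_idx]

  dims <- c(ncol(x), config$hidden, 1L)
  params <- mlp_init(dims)
  L <- length(params$W)
  opt <- list(mW = lapply(params$W, function(w) w * 0),
              vW = lapply(params$W, function(w) w * 0),
              mb = lapply(params$b, function(b) b * 0),
              vb = lapply(params$b, function(b) b * 0), t = 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- config$learning_rate; wd <- config$weight_decay; delta <- config$huber_delta

  best <- list(loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  log <- vector("list", config$max_epochs)

  for (epoch in seq_len(config$max_epochs)) {
    ord <- sample.int(nrow(Xtr))
    tr_loss_sum <- 0; tr_n <- 0
    for (start in seq(1, length(ord), by = config$batch_size)) {
      bi <- ord[start:min(start + config$batch_size - 1L, length(ord))]
      Xb <- Xtr[bi, , drop = FALSE]; yb <- ytr[bi]
      fw <- mlp_forward(params, Xb, dropout = config$dropout_rate, keep_state = TRUE)
      err <- fw$out - yb
      loss <- huber_loss(err, delta)
      if (!is.finite(loss)) abort(sprintf("non-finite training loss at epoch %d", epoch))
      tr_loss_sum <- tr_loss_sum + loss * length(bi); tr_n <- tr_n + length(bi)

      dZ <- matrix(huber_grad(err, delta) / length(bi), ncol = 1)
      gW <- vector("list", L); gb <- vector("list", L)
      for (l in rev(seq_len(L))) {
        gW[[l]] <- crossprod(fw$As[[l]], dZ)
        gb[[l]] <- colSums(dZ)
        if (l > 1L) {
          dA <- tcrossprod(dZ, params$W[[l]])
          if (!is.null(fw$Ms[[l - 1L]])) dA <- dA * fw$Ms[[l - 1L]]
          dZ <- dA * (fw$Zs[[l - 1L]] > 0)
        }
      }
      opt$t <- opt$t + 1
      bc1 <- 1 - beta1^opt$t; bc2 <- 1 - beta2^opt$t
      for (l in seq_len(L)) {
        opt$mW[[l]] <- beta1 * opt$mW[[l]] + (1 - beta1) * gW[[l]]
        opt$vW[[l]] <- beta2 * opt$vW[[l]] + (1 - beta2) * gW[[l]]^2
        opt$mb[[l]] <- beta1 * opt$mb[[l]] + (1 - beta1) * gb[[l]]
        opt$vb[[l]] <- beta2 * opt$vb[[l]] + (1 - beta2) * gb[[l]]^2
        params$W[[l]] <- params$W[[l]] -
          lr * ((opt$mW[[l]] / bc1) / (sqrt(opt$vW[[l]] / bc2) + eps) + wd * params$W[[l]])
        params$b[[l]] <- params$b[[l]] -
          lr * (opt$mb[[l]] / bc1) / (sqrt(opt$vb[[l]] / bc2) + eps)
      }
    }
    val_loss <- huber_loss(mlp_forward(params, Xval) - yval, delta)
    if (!is.finite(val_loss)) abort(sprintf("non-finite validation loss at epoch %d", epoch))
    log[[epoch]] <- tibble(epoch = epoch, train_loss = tr_loss_sum / tr_n,
                           val_loss = val_loss)
    if (val_loss < best$loss - 1e-9) {
      best <- list(loss = val_loss, params = params, epoch = epoch)
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (wait >= config$patience) break
    }
  }

  structure(list(params = best$params, config = config,
                 log = dplyr::bind_rows(log), best_epoch = best$epoch,
                 val_loss = best$loss, n_inputs = ncol(x), seed = seed),
            class = "respiq_mlp")
}

#' Deterministic prediction from a trained MLP
#'
#' @param object A [mlp_fit()] result.
#' @param x Feature matrix in the same scaled units as training.
#' @param ... Unused.
#' @return Numeric vector of predictions in scaled target units.
#' @export
predict.respiq_mlp <- function(object, x, ...) {
  x <- make_windows(as.matrix(x), object$config$input_window)
  if (ncol(x) != object$n_inputs) abort("feature count does not match the trained model")
  mlp_forward(object$params, x)
}

#' Monte-Carlo-dropout forward passes
#'
#' Runs `passes` stochastic forward passes with dropout active at inference;
#' the spread across passes is the predictive-uncertainty proxy used for the
#' reliability score.
#'
#' @param fit A [mlp_fit()] result.
#' @param x Scaled feature matrix.
#' @param passes Number of passes (default from the fit's config).
#' @param seed Integer seed; pass `p` derives its own stream from it.
#' @return Matrix of size `nrow(x)` x `passes`, scaled target units.
#' @export
mlp_mc_passes <- function(fit, x, passes = fit$config$mc_passes, seed = 1L) {
  if (passes < 2) abort("mc_passes must be >= 2")
  x <- make_windows(as.matrix(x), fit$config$input_window)
  out <- matrix(NA_real_, nrow(x), passes)
  for (p in seq_len(passes)) {
    set.seed(derive_seed(seed, paste0("mc_pass/", p)))
    out[, p] <- mlp_forward(fit$params, x, dropout = fit$config$dropout_rate)
  }
  out
}

#' @export
print.respiq_mlp <- function(x, ...) {
  cat(sprintf("<respiq_mlp> layers [%s], best epoch %d, val Huber loss %.4g\n",
              paste(x$config$hidden, collapse = ", "), x$best_epoch, x$val_loss))
  invisible(x)
}

#' @method tidy respiq_mlp
#' @export
tidy.respiq_mlp <- function(x, ...) x$log

#' @method glance respiq_mlp
#' @export
glance.respiq_mlp <- function(x, ...) {
  tibble(best_epoch = x$best_epoch, val_loss = x$val_loss,
         epochs_run = nrow(x$log),
         n_parameters = sum(purrr::map_int(x$params$W, length)) +
           sum(purrr::map_int(x$params$b, length)))
}
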