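# Compact feed-forward network trainer used by the protonation-state
# classifier and the ADMET endpoint heads.  ReLU hidden layers, a sigmoid or
# linear output, binary cross-entropy / MSE / MAE losses, Adam with an
# optional per-epoch learning-rate decay, mini-batching and early stopping
# on a validation set.  Everything is plain matrix algebra so runs are
# reproducible from the seed alone.

mlp_init <- function(widths, seed) {
  set.seed(seed)
  params <- list()
  for (k in seq_len(length(widths) - 1L)) {
    params[[paste0("W", k)]] <- glorot(widths[k], widths[k + 1L])
    params[[paste0("b", k)]] <- matrix(0, 1, widths[k + 1L])
  }
  params
}

mlp_forward <- function(params, X, out_act, keep = FALSE) {
  K <- length(params) / 2L
  acts <- vector("list", K + 1L)
  acts[[1L]] <- X
  for (k in seq_len(K)) {
    a <- acts[[k]] %*% params[[paste0("W", k)]]
    a <- sweep(a, 2L, params[[paste0("b", k)]], "+")
    if (k < K) a[a < 0] <- 0
    else if (out_act == "sigmoid") a <- 1 / (1 + exp(-a))
    acts[[k + 1L]] <- a
  }
  if (keep) acts else acts[[K + 1L]]
}

# dout: gradient of the loss w.r.t. the output PRE-activation for sigmoid
# + BCE (canceled algebraically) or the output itself for linear.
mlp_backward <- function(params, acts, dout) {
  K <- length(params) / 2L
  grads <- vector("list", length(params))
  names(grads) <- names(params)
  da <- dout
  for (k in rev(seq_len(K))) {
    if (k < K) da <- da * (acts[[k + 1L]] > 0)
    grads[[paste0("W", k)]] <- crossprod(acts[[k]], da)
    grads[[paste0("b", k)]] <- matrix(colSums(da), 1)
    if (k > 1L) da <- da %*% t(params[[paste0("W", k)]])
  }
  grads
}

mlp_loss <- function(pred, y, loss) {
  switch(loss,
         bce = {
           p <- pmin(pmax(pred, 1e-12), 1 - 1e-12)
           -mean(y * log(p) + (1 - y) * log(1 - p))
         },
         mse = mean((pred - y)^2),
         mae = mean(abs(pred - y)))
}

mlp_dout <- function(pred, y, loss, n) {
  switch(loss,
         bce = (pred - y) / n,      # w.r.t. pre-sigmoid logit
         mse = 2 * (pred - y) / n,
         mae = sign(pred - y) / n)
}

#' Fit a feed-forward network
#'
#' @param X numeric feature matrix (rows = samples).
#' @param y numeric target vector (0/1 for classification).
#' @param hidden integer vector of hidden-layer widths.
#' @param out_act `"sigmoid"` or `"linear"` output activation.
#' @param loss `"bce"`, `"mse"` or `"mae"`.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay multiplicative per-epoch learning-rate factor (1 = none);
#'   the rate at epoch e (0-based) is `learning_rate * lr_decay^e`.
#' @param batch_size mini-batch size.
#' @param epochs maximum epochs.
#' @param patience early-stopping patience on the validation loss.
#' @param validation either a fraction in (0, 1) split off `X` or a
#'   list(X, y) of explicit validation data; `NULL` disables early stopping.
#' @param weight_decay decoupled L2 penalty applied to the weights at each
#'   update (0 disables).
#' @param seed RNG seed (initialization, shuffling, validation split).
#' @return an `mlp_model` with the best-validation weights.
#' @export
mlp_fit <- function(X, y, hidden, out_act = c("sigmoid", "linear"),
                    loss = c("bce", "mse", "mae"), learning_rate = 1e-4,
                    lr_decay = 1, batch_size = 128L, epochs = 100L,
                    patience = Inf, validation = 0.1, weight_decay = 0,
                    seed = 1L) {
  out_act <- match.arg(out_act)
  loss <- match.arg(loss)
  if ((out_act == "sigmoid") != (loss == "bce"))
    stop("sigmoid output pairs with bce loss; linear with mse/mae")
  X <- as.matrix(X); y <- as.numeric(y)
  stopifnot(nrow(X) == length(y), all(is.finite(X)), all(is.finite(y)))
  set.seed(seed)
  if (is.numeric(validation) && length(validation) == 1L) {
    n_val <- max(1L, round(validation * nrow(X)))
    vi <- sample.int(nrow(X), n_val)
    val <- list(X = X[vi, , drop = FALSE], y = y[vi])
    X <- X[-vi, , drop = FALSE]; y <- y[-vi]
  } else val <- validation
  widths <- c(ncol(X), hidden, 1L)
  params <- mlp_init(widths, seed = sample.int(.Machine$integer.max, 1L))
  opt <- adam_init(params)
  n <- nrow(X)
  best_loss <- Inf; best_params <- params; stale <- 0L
  history <- numeric(0)
  for (ep in seq_len(epochs)) {
    lr <- learning_rate * lr_decay^(ep - 1L)
    ord <- sample.int(n)
    for (bi in split(ord, ceiling(seq_along(ord) / batch_size))) {
      acts <- mlp_forward(params, X[bi, , drop = FALSE], out_act, keep = TRUE)
      pred <- acts[[length(acts)]][, 1L]
      dout <- matrix(mlp_dout(pred, y[bi], loss, length(bi)), ncol = 1L)
      grads <- mlp_backward(params, acts, dout)
      st <- adam_step(opt, params, grads, lr)
      opt <- st$opt; params <- st$params
      if (weight_decay > 0) {
        wk <- grep("^W", names(params))
        params[wk] <- lapply(params[wk], function(w)
          w * (1 - lr * weight_decay))
      }
    }
    monitor <- if (!is.null(val))
      mlp_loss(mlp_forward(params, val$X, out_act)[, 1L], val$y, loss)
    else
      mlp_loss(mlp_forward(params, X, out_act)[, 1L], y, loss)
    history <- c(history, monitor)
    if (monitor < best_loss - 1e-6) {
      best_loss <- monitor; best_params <- params; stale <- 0L
    } else stale <- stale + 1L
    if (stale >= patience) break
  }
  structure(list(params = best_params, out_act = out_act, loss = loss,
                 n_features = ncol(X), history = history,
                 best_val_loss = best_loss),
            class = "mlp_model")
}

#' Predict from a fitted network
#'
#' Deterministic and order-equivariant; classification outputs are
#' probabilities in \[0, 1\], regression outputs are unbounded.
#'
#' @param object an `mlp_model`.
#' @param newdata feature matrix with `n_features` columns.
#' @param ... unused.
#' @return numeric vector of predictions.
#' @export
predict.mlp_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$n_features)
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$n_features)
  mlp_forward(object$params, newdata, object$out_act)[, 1L]
}

#' Average the probabilities of several fitted networks
#'
#' @param object an `mlp_ensemble` (list of `mlp_model` members).
#' @param newdata feature matrix.
#' @param ... unused.
#' @return numeric vector of averaged predictions.
#' @export
predict.mlp_ensemble <- function(object, newdata, ...) {
  rowMeans(vapply(object$members, predict, numeric(nrow(as.matrix(newdata))),
                  newdata = newdata))
}
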