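# ADMET endpoint heads on latent descriptors: per-endpoint regression or
# binary classification with class-imbalance resampling (random
# undersampling or SMOTE), 5-fold cross-validation, a per-epoch
# learning-rate decay and early stopping.

ADMET_ENDPOINTS <- c(caco2 = "regression", bioav = "classification",
                     lipo = "regression", sol = "regression",
                     bbb = "classification", ppbr = "classification",
                     hl = "classification", cyp2c19 = "classification",
                     cyp2d6 = "classification", cyp3a4 = "classification",
                     cyp1a2 = "classification", cyp2c9 = "classification",
                     ames = "classification", herg = "classification")

#' Define an ADMET prediction task
#'
#' The 14 canonical endpoints have fixed kinds (caco2, lipo and sol are
#' regression; the rest binary classification); custom endpoint names
#' require an explicit `kind`.
#'
#' @param endpoint endpoint name.
#' @param kind `"regression"` or `"classification"` (auto-filled for the 14
#'   canonical endpoints).
#' @param resampling `"none"`, `"undersample"` or `"smote"`
#'   (classification only).
#' @return an `admet_task`.
#' @export
admet_task <- function(endpoint,
                       kind = c("auto", "regression", "classification"),
                       resampling = c("none", "undersample", "smote")) {
  kind <- match.arg(kind)
  resampling <- match.arg(resampling)
  if (kind == "auto") {
    if (!endpoint %in% names(ADMET_ENDPOINTS))
      stop("unknown endpoint '", endpoint, "'; give `kind` explicitly")
    kind <- ADMET_ENDPOINTS[[endpoint]]
  } else if (endpoint %in% names(ADMET_ENDPOINTS) &&
             !identical(kind, ADMET_ENDPOINTS[[endpoint]])) {
    stop("endpoint '", endpoint, "' is a ", ADMET_ENDPOINTS[[endpoint]],
         " task")
  }
  if (kind == "regression" && resampling != "none")
    stop("resampling applies to classification tasks only")
  structure(list(endpoint = endpoint, kind = kind, resampling = resampling),
            class = "admet_task")
}

#' Default ADMET head configuration
#'
#' Four fully connected layers of 2048, 1024, 1024 and 1 neurons (ReLU
#' hidden; linear output for regression, sigmoid for classification), mean
#' absolute error / binary cross-entropy losses, Adam starting at 1e-4 and
#' decayed by 10% after each epoch, 5-fold cross-validation with
#' early-stopping patience 10, SMOTE with 5 neighbours and undersampling at
#' seed 42.
#'
#' @param hidden hidden-layer widths.
#' @param learning_rate initial Adam learning rate.
#' @param lr_decay per-epoch learning-rate factor.
#' @param batch_size mini-batch size.
#' @param epochs maximum epochs per fold.
#' @param folds cross-validation folds.
#' @param patience early-stopping patience.
#' @param smote_k SMOTE neighbour count.
#' @param undersample_seed RNG seed for random undersampling.
#' @return an `admet_config`.
#' @export
admet_config <- function(hidden = c(2048L, 1024L, 1024L),
                         learning_rate = 1e-4, lr_decay = 0.9,
                         batch_size = 128L, epochs = 100L, folds = 5L,
                         patience = 10L, smote_k = 5L,
                         undersample_seed = 42L) {
  stopifnot(lr_decay > 0, lr_decay <= 1, all(hidden > 0))
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 lr_decay = lr_decay, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 patience = as.integer(patience),
                 smote_k = as.integer(smote_k),
                 undersample_seed = as.integer(undersample_seed)),
            class = "admet_config")
}

#' Rebalance a binary training set
#'
#' `"undersample"` randomly drops majority samples down to the minority
#' count (reproducible at `config$undersample_seed`); `"smote"` adds
#' synthetic minority samples interpolated between a minority point and one
#' of its `smote_k` nearest minority neighbours until the classes are
#' balanced.  Original samples are never modified: undersampling subsets,
#' SMOTE only adds.
#'
#' @param latents feature matrix.
#' @param labels 0/1 vector.
#' @param method `"none"`, `"undersample"` or `"smote"`.
#' @param config an [admet_config()].
#' @return list(latents, labels) with equal class counts (unless "none").
#' @export
rebalance <- function(latents, labels, method = c("none", "undersample",
                                                  "smote"),
                      config = admet_config()) {
  method <- match.arg(method)
  latents <- as.matrix(latents)
  labels <- as.integer(labels)
  stopifnot(nrow(latents) == length(labels), all(labels %in% 0:1))
  if (method == "none") return(list(latents = latents, labels = labels))
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == n0) return(list(latents = latents, labels = labels))
  minority <- if (n1 < n0) 1L else 0L
  min_idx <- which(labels == minority)
  maj_idx <- which(labels != minority)
  if (method == "undersample") {
    set.seed(config$undersample_seed)
    keep <- sort(c(min_idx, sample(maj_idx, length(min_idx))))
    return(list(latents = latents[keep, , drop = FALSE],
                labels = labels[keep]))
  }
  # SMOTE
  k <- config$smote_k
  if (length(min_idx) < k + 1L)
    stop("minority class has ", length(min_idx), " samples; SMOTE needs > ",
         k, " - consider method = 'undersample'")
  Xm <- latents[min_idx, , drop = FALSE]
  d2 <- as.matrix(dist(Xm))^2
  diag(d2) <- Inf
  nn <- t(apply(d2, 1L, function(r) order(r)[seq_len(k)]))
  need <- length(maj_idx) - length(min_idx)
  base <- sample(length(min_idx), need, replace = TRUE)
  pick <- nn[cbind(base, sample(k, need, replace = TRUE))]
  gap <- runif(need)
  synth <- Xm[base, , drop = FALSE] +
    gap * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  list(latents = rbind(latents, synth),
       labels = c(labels, rep(minority, need)))
}

#' Train an ADMET endpoint head
#'
#' K-fold cross-validation with resampling applied inside each training
#' fold only (validation folds stay untouched).  Regression targets are
#' z-scored for training and predictions inverse-transformed, so MAE is
#' reported on the original scale; classification metrics are the full
#' binary suite.
#'
#' @param latents feature matrix.
#' @param targets numeric targets (0/1 for classification).
#' @param task an [admet_task()].
#' @param config an [admet_config()].
#' @param seed RNG seed.
#' @return an `admet_model` with `model` (final fit on all data),
#'   `fold_metrics`, `task`, `config` and (regression) `target_center`,
#'   `target_scale`.
#' @export
train_admet <- function(latents, targets, task, config = admet_config(),
                        seed = 1L) {
  latents <- as.matrix(latents)
  targets <- as.numeric(targets)
  stopifnot(inherits(task, "admet_task"), nrow(latents) == length(targets))
  if (anyNA(targets))
    stop("NA targets in rows: ", paste(which(is.na(targets)), collapse = ", "))
  regression <- task$kind == "regression"
  if (!regression) stopifnot(all(targets %in% 0:1))
  ctr <- if (regression) mean(targets) else 0
  scl <- if (regression) sd(targets) else 1
  if (regression && (!is.finite(scl) || scl == 0)) stop("constant targets")
  y <- if (regression) (targets - ctr) / scl else targets
  set.seed(seed)
  fold <- sample(rep_len(seq_len(config$folds), length(y)))
  fit_one <- function(X, yy, val, fold_seed) {
    if (!regression && task$resampling != "none") {
      rb <- rebalance(X, yy, task$resampling, config)
      X <- rb$latents; yy <- rb$labels
    }
    mlp_fit(X, yy, hidden = config$hidden,
            out_act = if (regression) "linear" else "sigmoid",
            loss = if (regression) "mae" else "bce",
            learning_rate = config$learning_rate,
            lr_decay = config$lr_decay, batch_size = config$batch_size,
            epochs = config$epochs, patience = config$patience,
            validation = val, seed = fold_seed)
  }
  fold_metrics <- vector("list", config$folds)
  for (k in seq_len(config$folds)) {
    tr <- fold != k
    fit <- fit_one(latents[tr, , drop = FALSE], y[tr],
                   list(X = latents[!tr, , drop = FALSE], y = y[!tr]),
                   seed + k)
    pred <- predict(fit, latents[!tr, , drop = FALSE])
    fold_metrics[[k]] <- if (regression)
      regression_metrics(targets[!tr], pred * scl + ctr)
    else
      classification_metrics(y[!tr], pred)
  }
  final <- fit_one(latents, y, 0.1, seed)
  structure(list(model = final, fold_metrics = fold_metrics, task = task,
                 config = config, target_center = ctr, target_scale = scl),
            class = "admet_model")
}

#' Predict an ADMET endpoint
#'
#' Regression predictions are returned on the original target scale;
#' classification predictions are probabilities in \[0, 1\].
#'
#' @param object an `admet_model`.
#' @param newdata latent matrix.
#' @param ... unused.
#' @return numeric vector.
#' @export
predict.admet_model <- function(object, newdata, ...) {
  p <- predict(object$model, newdata)
  if (object$task$kind == "regression")
    p * object$target_scale + object$target_center
  else p
}
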