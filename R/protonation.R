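# Protonation-state ranking: binarize state-penalty tables (the
# minimum-penalty state of each parent is class 1), train a latent-vector
# binary classifier with parent-stratified 5-fold cross-validation and early
# stopping, and pick the predominant state of new compounds by argmax
# probability.

#' Default protonation classifier configuration
#'
#' Four fully connected layers of 1024, 512, 512 and 1 neurons (ReLU hidden,
#' sigmoid output), binary cross-entropy, Adam at 1e-4, batch 128, 5-fold
#' cross-validation with early-stopping patience 5 and decision threshold
#' 0.5.
#'
#' @param hidden hidden-layer widths.
#' @param learning_rate Adam learning rate.
#' @param batch_size mini-batch size.
#' @param epochs maximum epochs per fold.
#' @param folds cross-validation folds.
#' @param patience early-stopping patience.
#' @param weight_decay decoupled L2 penalty on the classifier weights.
#' @param threshold decision threshold for thresholded metrics.
#' @return a `protonation_config` list.
#' @export
protonation_config <- function(hidden = c(1024L, 512L, 512L),
                               learning_rate = 1e-4, batch_size = 128L,
                               epochs = 100L, folds = 5L, patience = 5L,
                               weight_decay = 0, threshold = 0.5) {
  stopifnot(all(hidden > 0), threshold > 0, threshold < 1, folds >= 2)
  structure(list(hidden = as.integer(hidden), learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), folds = as.integer(folds),
                 patience = as.integer(patience),
                 weight_decay = weight_decay, threshold = threshold),
            class = "protonation_config")
}

#' Binarize state penalties into class labels
#'
#' Per parent, the state with the lowest penalty becomes class 1 and all
#' others class 0.  Penalty ties are broken by the lowest state index, with
#' a warning.
#'
#' @param table data.frame with columns `parent_id` and `penalty` (rows =
#'   states, grouped by parent in any order).
#' @return the table with a `label` column appended.
#' @export
binarize_states <- function(table) {
  stopifnot(all(c("parent_id", "penalty") %in% names(table)),
            nrow(table) > 0, all(is.finite(table$penalty)))
  label <- integer(nrow(table))
  tie_parents <- character(0)
  for (rows in split(seq_len(nrow(table)), table$parent_id)) {
    pen <- table$penalty[rows]
    winner <- rows[which.min(pen)]   # first minimum = lowest state index
    if (sum(pen == min(pen)) > 1L)
      tie_parents <- c(tie_parents, as.character(table$parent_id[rows[1L]]))
    label[winner] <- 1L
  }
  if (length(tie_parents) > 0L)
    warning("penalty ties broken by lowest state index for parent(s): ",
            paste(tie_parents, collapse = ", "))
  table$label <- label
  table
}

# parent-stratified fold assignment: all states of a parent share a fold
parent_folds <- function(parent_id, folds) {
  parents <- unique(parent_id)
  assignment <- sample(rep_len(seq_len(folds), length(parents)))
  assignment[match(parent_id, parents)]
}

#' Train the protonation-state classifier
#'
#' Runs parent-stratified k-fold cross-validation (all states of a parent
#' stay in the same fold, preventing leakage), records per-fold metrics, and
#' refits a final model on all data with a small random validation split for
#' early stopping.
#'
#' @param latents numeric matrix of state latent vectors (rows = states).
#' @param table binarized state table (from [binarize_states()]) aligned
#'   with `latents`.
#' @param config a [protonation_config()].
#' @param seed RNG seed.
#' @param final `"refit"` retrains one model on all data with a small
#'   random validation split; `"ensemble"` keeps the per-fold models and
#'   predicts with their average probability (lower variance).
#' @return a `protonation_model` with fields `model` (the final
#'   `mlp_model` or `mlp_ensemble`), `fold_metrics` (list of per-fold
#'   metric lists) and `config`.
#' @export
train_protonation <- function(latents, table, config = protonation_config(),
                              seed = 1L, final = c("refit", "ensemble")) {
  final <- match.arg(final)
  latents <- as.matrix(latents)
  stopifnot(nrow(latents) == nrow(table), "label" %in% names(table))
  y <- table$label
  if (length(unique(y)) < 2L) stop("need both classes to train")
  set.seed(seed)
  fold <- parent_folds(table$parent_id, config$folds)
  fold_metrics <- vector("list", config$folds)
  fold_models <- vector("list", config$folds)
  for (k in seq_len(config$folds)) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2L || length(unique(y[!tr])) < 2L)
      stop("fold ", k, " lost a class; use more parents or fewer folds")
    fit <- mlp_fit(latents[tr, , drop = FALSE], y[tr],
                   hidden = config$hidden, out_act = "sigmoid", loss = "bce",
                   learning_rate = config$learning_rate,
                   batch_size = config$batch_size, epochs = config$epochs,
                   patience = config$patience,
                   weight_decay = config$weight_decay,
                   validation = list(X = latents[!tr, , drop = FALSE],
                                     y = y[!tr]),
                   seed = seed + k)
    probs <- predict(fit, latents[!tr, , drop = FALSE])
    fold_metrics[[k]] <- classification_metrics(y[!tr], probs,
                                                config$threshold)
    fold_models[[k]] <- fit
  }
  model <- if (final == "ensemble") {
    structure(list(members = fold_models,
                   n_features = ncol(latents)), class = "mlp_ensemble")
  } else {
    mlp_fit(latents, y, hidden = config$hidden, out_act = "sigmoid",
            loss = "bce", learning_rate = config$learning_rate,
            batch_size = config$batch_size, epochs = config$epochs,
            patience = config$patience,
            weight_decay = config$weight_decay, validation = 0.1,
            seed = seed)
  }
  structure(list(model = model, fold_metrics = fold_metrics,
                 config = config),
            class = "protonation_model")
}

#' Rank the protonation states of one compound
#'
#' The predominant state is the argmax of the predicted class-1 probability
#' (never thresholded: even when no state clears the decision threshold, or
#' several do, exactly one state is selected).  Ties break to the lowest
#' state index.
#'
#' @param model a `protonation_model` (or bare `mlp_model`).
#' @param latents latent matrix of the compound's enumerated states.
#' @return list with `probabilities` and `predominant` (row index).
#' @export
rank_states <- function(model, latents) {
  latents <- as.matrix(latents)
  if (nrow(latents) == 0L) stop("empty state set")
  mlp <- if (inherits(model, "protonation_model")) model$model else model
  p <- predict(mlp, latents)
  list(probabilities = p, predominant = which.max(p))
}

#' Predominant-state accuracy over parents
#'
#' Fraction of parents whose argmax-probability state is the labelled
#' class-1 state.
#'
#' @param model a `protonation_model`.
#' @param latents state latent matrix.
#' @param table binarized state table aligned with `latents`.
#' @return accuracy in \[0, 1\].
#' @export
predominant_state_accuracy <- function(model, latents, table) {
  latents <- as.matrix(latents)
  probs <- predict(if (inherits(model, "protonation_model")) model$model
                   else model, latents)
  hits <- vapply(split(seq_len(nrow(table)), table$parent_id),
                 function(rows)
                   table$label[rows[which.max(probs[rows])]] == 1L,
                 NA)
  mean(hits)
}
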