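# R-level interface to the sequence-to-sequence autoencoder: configuration,
# parameter initialization, Adam training with teacher forcing and latent
# noise, deterministic encode/greedy-decode, and reconstruction validation.

#' Autoencoder model configuration
#'
#' Defaults mirror the reference full-scale configuration: three LSTM layers
#' of 1024 units, a 512-dimensional tanh latent bottleneck fed by the
#' concatenated hidden and cell states of all layers, six dense
#' initial-state heads for the decoder, Gaussian latent noise with sd 0.05
#' during training, Adam at 1e-4, batch size 256, and 13 property-regression
#' stacks of widths (512, 256, 128, 1) weighted by `lambda` in the joint
#' loss. Reduced configurations are obtained by overriding fields.
#'
#' @param lstm_layers number of stacked LSTM layers (encoder and decoder).
#' @param lstm_units memory units per LSTM layer.
#' @param latent_dim latent descriptor length.
#' @param noise_sd sd of the zero-mean Gaussian noise added to the latent
#'   during training only.
#' @param learning_rate Adam learning rate.
#' @param batch_size training batch size.
#' @param lambda weight of each property-regression MSE in the joint loss.
#' @param n_properties number of property-regression heads (0 disables).
#' @param prop_widths hidden widths of each property stack (last layer of
#'   width 1 is appended automatically).
#' @param bottleneck `"all"` to feed the concatenated (h, c) of every layer
#'   into the bottleneck, `"last"` for the top layer only.
#' @param reverse_input feed the encoder the token sequence in reverse
#'   (decoder output order unchanged).  Reversing shortens the path between
#'   the encoder's final state and the first decoded tokens, a standard
#'   sequence-to-sequence accuracy improvement.
#' @param epochs default training epoch count.
#' @param seed default RNG seed for initialization/shuffling/noise.
#' @return an `ae_config` list.
#' @export
ae_config <- function(lstm_layers = 3L, lstm_units = 1024L, latent_dim = 512L,
                      noise_sd = 0.05, learning_rate = 1e-4,
                      batch_size = 256L, lambda = 1.0, n_properties = 13L,
                      prop_widths = c(512L, 256L, 128L),
                      bottleneck = c("all", "last"), reverse_input = TRUE,
                      epochs = 6L, seed = 1L) {
  bottleneck <- match.arg(bottleneck)
  cfg <- list(lstm_layers = as.integer(lstm_layers),
              lstm_units = as.integer(lstm_units),
              latent_dim = as.integer(latent_dim),
              noise_sd = noise_sd, learning_rate = learning_rate,
              batch_size = as.integer(batch_size), lambda = lambda,
              n_properties = as.integer(n_properties),
              prop_widths = as.integer(prop_widths),
              bottleneck = bottleneck,
              reverse_input = isTRUE(reverse_input),
              epochs = as.integer(epochs),
              seed = as.integer(seed))
  stopifnot(cfg$lstm_layers > 0, cfg$lstm_units > 0, cfg$latent_dim > 0,
            cfg$batch_size > 0, cfg$noise_sd >= 0, cfg$n_properties >= 0,
            all(cfg$prop_widths > 0))
  class(cfg) <- "ae_config"
  cfg
}

# reverse each row's content tokens in place: [start t1..tn end pads] ->
# [start tn..t1 end pads]
reverse_content <- function(tokens, lengths) {
  for (i in seq_len(nrow(tokens))) {
    n <- lengths[i]
    if (n > 3L) tokens[i, 2:(n - 1L)] <- tokens[i, (n - 1L):2]
  }
  tokens
}

enc_input <- function(config, tokens, lengths) {
  if (isTRUE(config$reverse_input)) reverse_content(tokens, lengths)
  else tokens
}

# dims list handed to the C++ core
ae_dims <- function(config, vocab) {
  list(L = config$lstm_layers, U = config$lstm_units,
       V = length(vocab$tokens), D = config$latent_dim,
       P = config$n_properties,
       bottleneck_all = identical(config$bottleneck, "all"),
       widths = c(config$prop_widths, 1L),
       start = vocab$start, end = vocab$end, pad = vocab$pad)
}

glorot <- function(nr, nc) {
  r <- sqrt(6 / (nr + nc))
  matrix(runif(nr * nc, -r, r), nr, nc)
}

# orthogonal recurrent initialization, one orthonormal block per LSTM gate
orthogonal_gates <- function(u, gates = 4L) {
  do.call(cbind, replicate(gates, qr.Q(qr(matrix(rnorm(u * u), u))),
                           simplify = FALSE))
}

#' Build an untrained autoencoder model
#'
#' Allocates all weight matrices for the configured architecture.  LSTM
#' gate order within the stacked weight matrices is (input, forget, cell,
#' output); forget-gate biases start at 1.
#'
#' @param config an [ae_config()].
#' @param vocab a `token_vocabulary` the model is bound to.
#' @param scaler optional `property_scaler` stored for target
#'   (de)normalization.
#' @param seed RNG seed for weight initialization (defaults to
#'   `config$seed`).
#' @return an `ae_model` with fields `params`, `config`, `vocab`, `scaler`.
#' @export
build_model <- function(config, vocab, scaler = NULL, seed = config$seed) {
  stopifnot(inherits(config, "ae_config"), inherits(vocab, "token_vocabulary"))
  set.seed(seed)
  L <- config$lstm_layers; U <- config$lstm_units
  V <- length(vocab$tokens); D <- config$latent_dim
  p <- list()
  forget_bias <- function() {
    b <- matrix(0, 1, 4 * U)
    b[1, (U + 1):(2 * U)] <- 1
    b
  }
  for (side in c("enc", "dec")) {
    for (l in seq_len(L)) {
      inw <- if (l == 1L) V else U
      p[[paste0(side, l, "_W")]] <- glorot(inw, 4 * U)
      p[[paste0(side, l, "_U")]] <- orthogonal_gates(U)
      p[[paste0(side, l, "_b")]] <- forget_bias()
    }
  }
  cw <- if (config$bottleneck == "all") 2 * L * U else 2 * U
  p$bott_W <- glorot(cw, D)
  p$bott_b <- matrix(0, 1, D)
  for (j in seq_len(2 * L)) {
    p[[paste0("init_W", j)]] <- glorot(D, U)
    p[[paste0("init_b", j)]] <- matrix(0, 1, U)
  }
  p$out_W <- glorot(U, V)
  p$out_b <- matrix(0, 1, V)
  if (config$n_properties > 0) {
    widths <- c(D, config$prop_widths, 1L)
    for (pr in seq_len(config$n_properties)) {
      for (k in seq_len(length(widths) - 1L)) {
        p[[paste0("prop_W", pr, "_", k)]] <- glorot(widths[k], widths[k + 1])
        p[[paste0("prop_b", pr, "_", k)]] <- matrix(0, 1, widths[k + 1])
      }
    }
  }
  structure(list(params = p, config = config, vocab = vocab, scaler = scaler),
            class = "ae_model")
}

#' @export
print.ae_model <- function(x, ...) {
  cat("Sequence autoencoder:", x$config$lstm_layers, "x",
      x$config$lstm_units, "LSTM, latent", x$config$latent_dim, ",",
      length(x$vocab$tokens), "tokens,", x$config$n_properties,
      "property heads;", format(count_parameters(x), big.mark = ","),
      "parameters\n")
  invisible(x)
}

#' Count trainable parameters
#'
#' @param model an `ae_model`.
#' @return total number of trainable scalars.
#' @export
count_parameters <- function(model) {
  sum(vapply(model$params, length, 1L))
}

#' Analytic parameter count for a configuration
#'
#' Closed-form count for the configured sizes, used as an independent oracle
#' against [count_parameters()]: each LSTM layer holds 4((in + units) units
#' + units) weights, plus the bottleneck, decoder initial-state heads,
#' softmax output layer, and property stacks.
#'
#' @param config an [ae_config()].
#' @param vocab_size token-library size.
#' @return total parameter count.
#' @export
analytic_parameter_count <- function(config, vocab_size) {
  L <- config$lstm_layers; U <- config$lstm_units
  V <- vocab_size; D <- config$latent_dim
  lstm <- function(inw) 4 * ((inw + U) * U + U)
  one_stack <- sum(lstm(V), if (L > 1) rep(lstm(U), L - 1))
  cw <- if (config$bottleneck == "all") 2 * L * U else 2 * U
  widths <- c(D, config$prop_widths, 1L)
  prop <- sum((widths[-length(widths)] + 1) * widths[-1])
  2 * one_stack +                      # encoder + decoder LSTMs
    (cw * D + D) +                     # bottleneck
    2 * L * (D * U + U) +              # decoder init heads
    (U * V + V) +                      # output softmax layer
    config$n_properties * prop
}

adam_step <- function(opt, params, grads, lr, beta1 = 0.9, beta2 = 0.98,
                      eps = 1e-8) {
  opt$t <- opt$t + 1L
  bc1 <- 1 - beta1^opt$t
  bc2 <- 1 - beta2^opt$t
  for (nmp in names(params)) {
    g <- grads[[nmp]]
    opt$m[[nmp]] <- beta1 * opt$m[[nmp]] + (1 - beta1) * g
    opt$v[[nmp]] <- beta2 * opt$v[[nmp]] + (1 - beta2) * g * g
    params[[nmp]] <- params[[nmp]] -
      lr * (opt$m[[nmp]] / bc1) / (sqrt(opt$v[[nmp]] / bc2) + eps)
  }
  list(opt = opt, params = params)
}

adam_init <- function(params) {
  zeros <- lapply(params, function(x) array(0, dim(x)))
  list(t = 0L, m = zeros, v = zeros)
}

#' Train the autoencoder
#'
#' Joint teacher-forced training: the total loss is the decoder's
#' categorical cross-entropy (mean per non-pad token) plus `lambda` times
#' the sum of per-property mean squared errors.  The decoder input at step
#' t is the ground-truth token at t-1; zero-mean Gaussian noise of sd
#' `config$noise_sd` is added to the latent during training only.  Fully
#' reproducible for a given seed.
#'
#' @param model an `ae_model` (from [build_model()]).
#' @param corpus character vector of curated canonical SMILES.
#' @param targets optional numeric matrix of z-scored property targets
#'   (rows aligned with `corpus`); required when the model has property
#'   heads.
#' @param epochs number of passes over the corpus (default from config).
#' @param seed RNG seed for shuffling and noise.
#' @param stop_at_full_reconstruction if `TRUE`, greedy reconstruction of
#'   the training corpus is checked every `check_every` epochs and training
#'   stops early once it reaches 100%.
#' @param check_every epochs between reconstruction checks.
#' @param patience stop when the epoch-mean decoder loss has not improved
#'   by `min_delta` for this many consecutive epochs (`Inf` disables).
#' @param min_delta minimum improvement counted by `patience`.
#' @param bucket_by_length if `TRUE`, group similar-length sequences into
#'   the same batch (batch order still shuffled).  Because the encoder
#'   carry-masks beyond each sequence's length, bucketing changes only
#'   speed, not semantics.
#' @param clip_norm global gradient-norm ceiling (`Inf` disables).
#' @param lr_schedule `NULL` for a constant rate; `list(type = "cosine",
#'   min = x)` for cosine annealing from the configured rate down to `min`
#'   across the epoch budget; `list(type = "plateau", factor, patience,
#'   min)` for stall-triggered decay.
#' @param verbose print per-epoch progress.
#' @return the trained `ae_model`, with a `history` element: a data.frame of
#'   per-step decoder loss, token accuracy and total loss, plus per-property
#'   losses.
#' @export
ae_train <- function(model, corpus, targets = NULL,
                     epochs = model$config$epochs, seed = model$config$seed,
                     stop_at_full_reconstruction = FALSE, check_every = 5L,
                     patience = Inf, min_delta = 1e-4,
                     bucket_by_length = TRUE, clip_norm = 5,
                     lr_schedule = list(type = "cosine", min = 2e-5),
                     verbose = FALSE) {
  cfg <- model$config
  vocab <- model$vocab
  if (cfg$n_properties > 0) {
    if (is.null(targets)) stop("model has property heads but no targets given")
    targets <- as.matrix(targets)
    stopifnot(nrow(targets) == length(corpus),
              ncol(targets) == cfg$n_properties)
    if (anyNA(targets)) stop("NaN/NA property targets in rows: ",
                             paste(which(rowSums(is.na(targets)) > 0),
                                   collapse = ", "))
  } else {
    targets <- matrix(0, length(corpus), 0)
  }
  enc <- encode_corpus(corpus, vocab)
  dims <- ae_dims(cfg, vocab)
  set.seed(seed)
  opt <- adam_init(model$params)
  n <- length(corpus)
  hist_loss <- hist_acc <- hist_total <- numeric(0)
  hist_prop <- NULL
  best <- Inf; stale <- 0L
  lr <- cfg$learning_rate
  lr_best <- Inf; lr_stale <- 0L
  for (ep in seq_len(epochs)) {
    if (!is.null(lr_schedule) && identical(lr_schedule$type, "cosine")) {
      floor_lr <- if (is.null(lr_schedule$min)) 0 else lr_schedule$min
      lr <- floor_lr + (cfg$learning_rate - floor_lr) *
        0.5 * (1 + cos(pi * (ep - 1) / max(epochs - 1, 1)))
    }
    ord <- sample.int(n)
    if (bucket_by_length) ord <- ord[order(enc$lengths[ord])]
    batches <- split(ord, ceiling(seq_along(ord) / cfg$batch_size))
    batches <- batches[sample.int(length(batches))]
    ep_loss <- 0
    for (bi in batches) {
      len <- enc$lengths[bi]
      tmax <- max(len)
      tok <- enc$tokens[bi, seq_len(tmax), drop = FALSE]
      enc_tok <- enc_input(cfg, tok, len)
      # teacher forcing: input starts at the start token, target is shifted
      dec_in <- tok[, seq_len(tmax - 1L), drop = FALSE]
      dec_tgt <- tok[, 2:tmax, drop = FALSE]
      noise <- matrix(if (cfg$noise_sd > 0)
                        rnorm(length(bi) * cfg$latent_dim, 0, cfg$noise_sd)
                      else 0, length(bi), cfg$latent_dim)
      res <- cpp_ae_grad(model$params, enc_tok, len, dec_in, dec_tgt, noise,
                         targets[bi, , drop = FALSE], cfg$lambda, dims)
      if (!is.finite(res$loss))
        stop("non-finite loss at epoch ", ep,
             "; lower the learning rate or check the inputs")
      if (is.finite(clip_norm)) {
        gn <- sqrt(sum(vapply(res$grads, function(g) sum(g * g), 0)))
        if (gn > clip_norm)
          res$grads <- lapply(res$grads, `*`, clip_norm / gn)
      }
      st <- adam_step(opt, model$params, res$grads, lr)
      opt <- st$opt; model$params <- st$params
      hist_loss <- c(hist_loss, res$loss_decoder)
      hist_acc <- c(hist_acc, res$token_accuracy)
      hist_total <- c(hist_total, res$loss)
      if (cfg$n_properties > 0)
        hist_prop <- rbind(hist_prop, res$loss_property)
      ep_loss <- ep_loss + res$loss_decoder * length(bi) / n
    }
    if (verbose)
      message(sprintf("epoch %d: decoder loss %.4f, token accuracy %.4f",
                      ep, ep_loss, hist_acc[length(hist_acc)]))
    if (stop_at_full_reconstruction && ep %% check_every == 0L) {
      rr <- reconstruction_rate(model, corpus, check_validity = FALSE)
      if (verbose) message(sprintf("  reconstruction %.4f", rr$rate))
      if (rr$rate >= 1) break
    }
    if (ep_loss < best - min_delta) { best <- ep_loss; stale <- 0L }
    else stale <- stale + 1L
    if (stale >= patience) break
    if (!is.null(lr_schedule) && identical(lr_schedule$type, "plateau")) {
      if (ep_loss < lr_best - min_delta) { lr_best <- ep_loss; lr_stale <- 0L }
      else lr_stale <- lr_stale + 1L
      if (lr_stale >= lr_schedule$patience && lr > lr_schedule$min) {
        lr <- max(lr * lr_schedule$factor, lr_schedule$min)
        lr_stale <- 0L
        if (verbose) message("  learning rate -> ", lr)
      }
    }
  }
  model$history <- list(
    steps = data.frame(loss_decoder = hist_loss, token_accuracy = hist_acc,
                       loss_total = hist_total),
    property = hist_prop)
  model
}

#' Encode SMILES to latent descriptors
#'
#' Deterministic (no noise), order-preserving and independent of batch
#' composition.
#'
#' @param model a (trained) `ae_model`.
#' @param smiles character vector of in-vocabulary SMILES.
#' @return numeric matrix (length(smiles) x latent_dim).
#' @export
ae_encode <- function(model, smiles) {
  enc <- encode_corpus(smiles, model$vocab)
  tmax <- max(enc$lengths)
  tok <- enc_input(model$config,
                   enc$tokens[, seq_len(tmax), drop = FALSE], enc$lengths)
  cpp_ae_encode(model$params, tok, enc$lengths,
                ae_dims(model$config, model$vocab))
}

#' Greedy-decode latent vectors back to SMILES
#'
#' Token-by-token argmax decoding feeding each prediction back as the next
#' input, stopping at the end token or `max_steps`.
#'
#' @param model a (trained) `ae_model`.
#' @param latent numeric matrix (n x latent_dim) or a single vector.
#' @param max_steps decoding step budget (defaults to the vocabulary's
#'   padded width).
#' @param check_validity also canonicalize each decoded string via the
#'   chemistry toolkit and report validity flags (requires the RDKit
#'   bridge).
#' @return data.frame with `smiles` and, when `check_validity`, `valid` and
#'   `canonical` columns.
#' @export
ae_decode <- function(model, latent, max_steps = NULL, check_validity = FALSE) {
  if (is.null(dim(latent))) latent <- matrix(latent, 1)
  if (ncol(latent) != model$config$latent_dim)
    stop("latent has ", ncol(latent), " columns; model latent_dim is ",
         model$config$latent_dim)
  if (is.null(max_steps)) max_steps <- model$vocab$max_sequence_length
  toks <- cpp_ae_decode(model$params, latent, as.integer(max_steps),
                        ae_dims(model$config, model$vocab))
  smiles <- apply(toks, 1L, detokenize, vocab = model$vocab)
  out <- data.frame(smiles = smiles, stringsAsFactors = FALSE)
  if (check_validity) {
    canon <- canonicalize_smiles(smiles)
    out$valid <- !is.na(canon)
    out$canonical <- canon
  }
  out
}

#' Exact-reconstruction rate of a corpus
#'
#' Fraction of molecules whose greedy decode of `encode(s)` returns exactly
#' the input canonical SMILES; failures are listed with character-level
#' (Levenshtein) edit distance.
#'
#' @param model a trained `ae_model`.
#' @param corpus character vector of canonical SMILES.
#' @param batch_size encode/decode batch size.
#' @param check_validity compute validity flags for failures.
#' @return list with `rate` in \[0, 1\], `n`, and `failures` data.frame
#'   (`input`, `decoded`, `edit_distance`).
#' @export
reconstruction_rate <- function(model, corpus, batch_size = 512L,
                                check_validity = FALSE) {
  decoded <- character(length(corpus))
  for (i in seq(1L, length(corpus), by = batch_size)) {
    j <- min(i + batch_size - 1L, length(corpus))
    z <- ae_encode(model, corpus[i:j])
    decoded[i:j] <- ae_decode(model, z)$smiles
  }
  ok <- decoded == corpus
  failures <- data.frame(input = corpus[!ok], decoded = decoded[!ok],
                         stringsAsFactors = FALSE)
  if (nrow(failures) > 0) {
    failures$edit_distance <- as.integer(adist(failures$input,
                                               failures$decoded)[cbind(
                                                 seq_len(nrow(failures)),
                                                 seq_len(nrow(failures)))])
    if (check_validity)
      failures$valid <- !is.na(canonicalize_smiles(failures$decoded))
  }
  list(rate = mean(ok), n = length(corpus), failures = failures)
}

#' Save / load a model checkpoint
#'
#' The checkpoint bundles weights, vocabulary, property scaler and
#' configuration so that encode/decode is self-contained.
#'
#' @param model an `ae_model`.
#' @param path file path.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(format = "latentmol_checkpoint", version = 1L,
               params = model$params, config = unclass(model$config),
               vocab = unclass(model$vocab), scaler = model$scaler), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$format, "latentmol_checkpoint"))
    stop("not a latentmol checkpoint: ", path)
  structure(list(params = x$params,
                 config = structure(x$config, class = "ae_config"),
                 vocab = structure(x$vocab, class = "token_vocabulary"),
                 scaler = x$scaler),
            class = "ae_model")
}
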