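# Reference desk-scale benchmarks: a reduced-autoencoder exact-reconstruction
# run and a null-calibration of the screening enrichment factor.  Both are
# used by the test suite and by scripts/acceptance.R so the protocol is
# defined once.

#' Reduced-scale exact-reconstruction benchmark
#'
#' Generates a 500-molecule toy corpus (4-15 heavy atoms, grammar-based,
#' corpus seed 1), trains a reduced autoencoder (2 LSTM layers of 256
#' units, latent dimension 64, no property heads, teacher forcing, Adam at
#' 1e-3, batch 64, latent noise sd 0.05) until the training loss plateaus
#' or the corpus is fully reconstructed, for at most 200 epochs, and
#' reports the percentage of molecules whose latent vector greedy-decodes
#' back to the exact input SMILES.
#'
#' @param train_seed RNG seed for weight initialization, shuffling and
#'   latent noise.
#' @param corpus_seed corpus generator seed (1 = the reference corpus).
#' @param n_molecules corpus size.
#' @param epochs epoch cap.
#' @param verbose print training progress.
#' @return list with `rate_percent`, `n`, `failures` and the trained
#'   `model`.
#' @export
reconstruction_benchmark <- function(train_seed = 11L, corpus_seed = 1L,
                                     n_molecules = 500L, epochs = 200L,
                                     verbose = FALSE) {
  corpus <- toy_corpus(n_molecules, max_heavy_atoms = 15L,
                       seed = corpus_seed)
  vocab <- build_vocabulary(corpus)
  cfg <- ae_config(lstm_layers = 2L, lstm_units = 256L, latent_dim = 64L,
                   noise_sd = 0.05, learning_rate = 1e-3, batch_size = 64L,
                   lambda = 0, n_properties = 0L, epochs = epochs,
                   seed = train_seed)
  model <- build_model(cfg, vocab, seed = train_seed)
  model <- ae_train(model, corpus, epochs = epochs, seed = train_seed,
                    stop_at_full_reconstruction = TRUE, check_every = 10L,
                    lr_schedule = list(type = "cosine", min = 2e-5),
                    verbose = verbose)
  rr <- reconstruction_rate(model, corpus)
  list(rate_percent = 100 * rr$rate, n = rr$n, failures = rr$failures,
       model = model)
}

#' Null-calibration of the screening enrichment factor
#'
#' Estimates the expected enrichment factor of the max-cosine screening
#' protocol when the library carries no signal: per iteration a fresh
#' signal-free library (200 "actives" and 9,800 "decoys" drawn i.i.d. from
#' the same multivariate normal; library seed stream starting at 7) is
#' generated, 5 actives are sampled as queries, the remaining compounds
#' are ranked by maximum cosine similarity, and EF at the top 1% is
#' recorded.  The library must be redrawn each iteration: on any fixed
#' library the per-iteration EFs are correlated (the same chance
#' similarity hubs dominate every draw), so the average converges to that
#' library's conditional EF — which deviates from 1 by far more than the
#' Monte-Carlo error — rather than to the null expectation.  With fresh
#' draws the iterations are independent and the expectation is exactly
#' the random-selection baseline, EF = 1.
#'
#' @param iterations number of independent library + query draws.
#' @param seed RNG seed for the query sampling.
#' @param n_actives,n_decoys library composition.
#' @param latent_dim library latent dimension.
#' @param library_seed seed of the first library; iteration i uses
#'   `library_seed + i - 1`.
#' @return list with `mean_ef`, `mean_auc` and the per-iteration
#'   data.frame `per_iteration`.
#' @export
null_screening_benchmark <- function(iterations = 500L, seed = 1L,
                                     n_actives = 200L, n_decoys = 9800L,
                                     latent_dim = 32L, library_seed = 7L) {
  ef <- auc <- numeric(iterations)
  for (it in seq_len(iterations)) {
    lib <- screening_library(n_actives, n_decoys, cluster_spread = 1,
                             signal = 0, latent_dim = latent_dim,
                             seed = library_seed + it - 1L)
    run <- run_screening_benchmark(lib$latents, lib$labels, n_queries = 5L,
                                   iterations = 1L, fraction = 0.01,
                                   seed = seed + it)
    ef[it] <- run$per_iteration$ef
    auc[it] <- run$per_iteration$roc_auc
  }
  list(mean_ef = mean(ef), mean_auc = mean(auc),
       per_iteration = data.frame(roc_auc = auc, ef = ef))
}
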