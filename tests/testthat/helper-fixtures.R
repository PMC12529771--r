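# Shared fixtures, memoized so expensive generators run once per session.

fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

# the reduced-scale benchmark corpus: 500 unique 4-15-heavy-atom molecules
benchmark_corpus <- function() {
  memo("benchmark_corpus", toy_corpus(500L, max_heavy_atoms = 15L, seed = 1L))
}

small_corpus <- function(n = 60L) {
  memo(paste0("small_corpus_", n),
       toy_corpus(n, max_heavy_atoms = 10L, seed = 42L))
}

# a tiny untrained model for interface-level tests
tiny_model <- function(n_properties = 0L) {
  key <- paste0("tiny_model_", n_properties)
  memo(key, {
    vocab <- build_vocabulary(small_corpus(30L))
    cfg <- ae_config(lstm_layers = 2L, lstm_units = 16L, latent_dim = 8L,
                     n_properties = n_properties,
                     prop_widths = c(12L, 6L), batch_size = 16L,
                     noise_sd = 0.05, seed = 7L)
    build_model(cfg, vocab, seed = 7L)
  })
}
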