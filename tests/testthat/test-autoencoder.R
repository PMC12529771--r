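test_that("parameter counts match the analytic closed form across configs", {
  set.seed(3)
  vocab <- build_vocabulary(small_corpus(30L))
  grid <- list(
    list(L = 2L, U = 64L, D = 32L, P = 0L, bott = "all"),
    list(L = 1L, U = 48L, D = 16L, P = 0L, bott = "all"),
    list(L = 3L, U = 24L, D = 12L, P = 2L, bott = "all"),
    list(L = 2L, U = 32L, D = 24L, P = 1L, bott = "last"),
    list(L = 2L, U = 16L, D = 8L,  P = 3L, bott = "all"),
    list(L = 1L, U = 80L, D = 40L, P = 0L, bott = "last"))
  for (g in grid) {
    cfg <- ae_config(lstm_layers = g$L, lstm_units = g$U, latent_dim = g$D,
                     n_properties = g$P, prop_widths = c(20L, 10L),
                     bottleneck = g$bott)
    model <- build_model(cfg, vocab, seed = 1L)
    expect_equal(count_parameters(model),
                 analytic_parameter_count(cfg, length(vocab$tokens)))
  }
  # one full-scale property stack: (512,256,128,1) on a 512 latent
  with_heads <- ae_config(n_properties = 1L)
  without <- ae_config(n_properties = 0L)
  expect_equal(analytic_parameter_count(with_heads, 34L) -
                 analytic_parameter_count(without, 34L), 427009L)
})

test_that("analytic gradients match numerical differentiation", {
  corpus <- c("CCO", "CCCN", "c1ccccc1", "CC(C)O")
  vocab <- build_vocabulary(corpus)
  cfg <- ae_config(lstm_layers = 2L, lstm_units = 5L, latent_dim = 4L,
                   n_properties = 2L, prop_widths = 6L, batch_size = 4L,
                   noise_sd = 0.05)
  model <- build_model(cfg, vocab, seed = 42L)
  p <- model$params
  dims <- latentmol:::ae_dims(cfg, vocab)
  enc <- encode_corpus(corpus, vocab)
  tmax <- max(enc$lengths)
  tok <- enc$tokens[, seq_len(tmax), drop = FALSE]
  dec_in <- tok[, seq_len(tmax - 1L), drop = FALSE]
  dec_tgt <- tok[, 2:tmax, drop = FALSE]
  set.seed(9)
  noise <- matrix(rnorm(nrow(tok) * 4, 0, 0.05), nrow(tok))
  ptgt <- matrix(rnorm(nrow(tok) * 2), nrow(tok))
  lambda <- 0.7
  lossfun <- function(pp)
    latentmol:::cpp_ae_grad(pp, tok, enc$lengths, dec_in, dec_tgt, noise,
                            ptgt, lambda, dims)$loss
  res <- latentmol:::cpp_ae_grad(p, tok, enc$lengths, dec_in, dec_tgt,
                                 noise, ptgt, lambda, dims)
  worst <- 0
  for (nm in names(p)) {
    g <- res$grads[[nm]]
    expect_equal(dim(g), dim(p[[nm]]), info = nm)
    for (i in sample(length(p[[nm]]), min(4L, length(p[[nm]])))) {
      eps <- 1e-5
      p1 <- p; p1[[nm]][i] <- p1[[nm]][i] + eps
      p2 <- p; p2[[nm]][i] <- p2[[nm]][i] - eps
      num <- (lossfun(p1) - lossfun(p2)) / (2 * eps)
      rel <- abs(num - g[i]) / max(1e-6, abs(num) + abs(g[i]))
      worst <- max(worst, rel)
    }
  }
  expect_lt(worst, 1e-3)
})

test_that("encoding is deterministic, order-equivariant and padding-invariant", {
  model <- tiny_model()
  smiles <- small_corpus(30L)[1:12]
  z1 <- ae_encode(model, smiles)
  z2 <- ae_encode(model, smiles)
  expect_identical(z1, z2)
  expect_equal(ncol(z1), model$config$latent_dim)
  perm <- c(5:12, 1:4)
  expect_equal(ae_encode(model, smiles[perm]), z1[perm, ],
               ignore_attr = TRUE)
  # batch composition (hence padding width) does not change encodings
  expect_equal(ae_encode(model, smiles[3]), z1[3, , drop = FALSE],
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("decoding is total, bounded and flags validity", {
  model <- tiny_model()
  z0 <- matrix(0, 2, model$config$latent_dim)
  out <- ae_decode(model, z0, max_steps = 12L)
  expect_equal(nrow(out), 2L)
  expect_true(all(nchar(out$smiles) <= 2 * 12L))  # two-char halogen tokens
  outv <- ae_decode(model, z0, max_steps = 12L, check_validity = TRUE)
  expect_type(outv$valid, "logical")
  expect_error(ae_decode(model, matrix(0, 1, 3)), "latent_dim")
})

test_that("an untrained model reconstructs (almost) nothing", {
  model <- tiny_model()
  rr <- reconstruction_rate(model, small_corpus(30L))
  expect_lt(rr$rate, 0.05)
  expect_true(all(rr$failures$edit_distance >= 1))
})

test_that("training reduces the decoder loss and is seed-reproducible", {
  corpus <- small_corpus(40L)
  vocab <- build_vocabulary(corpus)
  cfg <- ae_config(lstm_layers = 1L, lstm_units = 32L, latent_dim = 16L,
                   learning_rate = 1e-3, batch_size = 20L,
                   n_properties = 0L, noise_sd = 0.05)
  run <- function() {
    m <- build_model(cfg, vocab, seed = 5L)
    ae_train(m, corpus, epochs = 8L, seed = 5L)
  }
  m1 <- run()
  steps <- m1$history$steps
  expect_lt(mean(tail(steps$loss_decoder, 4)),
            mean(head(steps$loss_decoder, 4)))
  m2 <- run()
  expect_identical(m1$history$steps, m2$history$steps)
  expect_identical(m1$params, m2$params)
  # noise ablation: exact reproducibility also holds with noise disabled
  cfg0 <- ae_config(lstm_layers = 1L, lstm_units = 32L, latent_dim = 16L,
                    learning_rate = 1e-3, batch_size = 20L,
                    n_properties = 0L, noise_sd = 0)
  m3 <- ae_train(build_model(cfg0, vocab, seed = 5L), corpus, epochs = 3L,
                 seed = 5L)
  m4 <- ae_train(build_model(cfg0, vocab, seed = 5L), corpus, epochs = 3L,
                 seed = 5L)
  expect_identical(m3$params, m4$params)
})

test_that("with zero property weight the heads do not touch the autoencoder", {
  corpus <- small_corpus(40L)
  vocab <- build_vocabulary(corpus)
  cfg <- ae_config(lstm_layers = 1L, lstm_units = 24L, latent_dim = 12L,
                   learning_rate = 1e-3, batch_size = 20L,
                   n_properties = 2L, prop_widths = c(16L, 8L),
                   lambda = 0, noise_sd = 0)
  t1 <- matrix(rnorm(length(corpus) * 2), ncol = 2)
  t2 <- matrix(rnorm(length(corpus) * 2, mean = 5), ncol = 2)
  m1 <- ae_train(build_model(cfg, vocab, seed = 3L), corpus, targets = t1,
                 epochs = 3L, seed = 3L)
  m2 <- ae_train(build_model(cfg, vocab, seed = 3L), corpus, targets = t2,
                 epochs = 3L, seed = 3L)
  ae_names <- grep("^prop", names(m1$params), invert = TRUE, value = TRUE)
  expect_identical(m1$params[ae_names], m2$params[ae_names])
})

test_that("a small model memorizes a small corpus exactly", {
  corpus <- toy_corpus(30L, max_heavy_atoms = 8L, seed = 21L)
  vocab <- build_vocabulary(corpus)
  cfg <- ae_config(lstm_layers = 1L, lstm_units = 96L, latent_dim = 32L,
                   learning_rate = 1e-3, batch_size = 30L,
                   n_properties = 0L, noise_sd = 0.05)
  model <- build_model(cfg, vocab, seed = 2L)
  model <- ae_train(model, corpus, epochs = 800L, seed = 2L,
                    stop_at_full_reconstruction = TRUE, check_every = 25L)
  rr <- reconstruction_rate(model, corpus)
  expect_equal(rr$rate, 1.0)
})

test_that("checkpoints restore a model that encodes identically", {
  model <- tiny_model()
  path <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(model, path)
  restored <- load_checkpoint(path)
  smiles <- small_corpus(30L)[1:5]
  expect_identical(ae_encode(restored, smiles), ae_encode(model, smiles))
  expect_error(suppressWarnings(
    load_checkpoint(withr::local_tempfile(fileext = ".rds"))))
})
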