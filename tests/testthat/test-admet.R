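test_that("endpoint kinds are fixed for the canonical 14", {
  expect_equal(admet_task("caco2")$kind, "regression")
  expect_equal(admet_task("herg")$kind, "classification")
  expect_error(admet_task("caco2", kind = "classification"), "regression")
  expect_error(admet_task("mystery"), "kind")
  expect_error(admet_task("lipo", resampling = "smote"), "classification")
})

test_that("undersampling balances classes without touching survivors", {
  set.seed(41)
  X <- matrix(rnorm(1000 * 6), 1000)
  y <- rep(c(1L, 0L), c(100, 900))
  rb <- rebalance(X, y, "undersample")
  expect_equal(sum(rb$labels == 1), 100)
  expect_equal(sum(rb$labels == 0), 100)
  # every surviving row is an original row
  key <- apply(X, 1, function(r) paste(signif(r, 12), collapse = ","))
  kept <- apply(rb$latents, 1, function(r) paste(signif(r, 12), collapse = ","))
  expect_true(all(kept %in% key))
  # reproducible at the configured seed
  rb2 <- rebalance(X, y, "undersample")
  expect_identical(rb, rb2)
})

test_that("SMOTE adds convex minority combinations and only adds", {
  set.seed(42)
  X <- matrix(rnorm(400 * 4), 400)
  y <- rep(c(1L, 0L), c(40, 360))
  rb <- rebalance(X, y, "smote")
  expect_equal(sum(rb$labels == 1), 360)
  expect_equal(sum(rb$labels == 0), 360)
  # originals are untouched and come first
  expect_identical(rb$latents[seq_len(400), ], X)
  # synthetic points stay inside the minority bounding box
  synth <- rb$latents[-seq_len(400), , drop = FALSE]
  lo <- apply(X[y == 1, ], 2, min); hi <- apply(X[y == 1, ], 2, max)
  expect_true(all(sweep(synth, 2, lo, ">=") & sweep(synth, 2, hi, "<=")))
  expect_error(rebalance(X[c(1:3, 41:100), ], y[c(1:3, 41:100)], "smote"),
               "undersample")
  rb0 <- rebalance(X, y, "none")
  expect_identical(rb0$latents, X)
})

test_that("rebalancing does not hurt minority recall on imbalanced data", {
  fx <- admet_table(600, "classification", effect = 1.5, noise = 0.5,
                    imbalance = 0.15, latent_dim = 8L, seed = 43L)
  cfg <- admet_config(hidden = c(32L, 16L), learning_rate = 1e-3,
                      epochs = 25L, patience = 5L, folds = 3L)
  plain <- train_admet(fx$latents, fx$target,
                       admet_task("x", kind = "classification",
                                  resampling = "none"), cfg, seed = 6L)
  balanced <- train_admet(fx$latents, fx$target,
                          admet_task("x", kind = "classification",
                                     resampling = "undersample"), cfg,
                          seed = 6L)
  rec <- function(m) mean(vapply(m$fold_metrics, `[[`, 0, "recall"))
  expect_gte(rec(balanced), rec(plain) - 0.02)
})

test_that("regression heads report original-scale errors and predict deterministically", {
  fx <- admet_table(500, "regression", effect = 3, noise = 0.3,
                    latent_dim = 8L, seed = 44L)
  target <- fx$target * 10 + 100  # far from z-scale
  cfg <- admet_config(hidden = c(32L, 16L), learning_rate = 3e-3,
                      lr_decay = 0.99, epochs = 200L, patience = 20L,
                      folds = 3L)
  fit <- train_admet(fx$latents, target, admet_task("x", kind = "regression"),
                     cfg, seed = 7L)
  r <- mean(vapply(fit$fold_metrics, `[[`, 0, "pearson_r"))
  expect_gte(r, 0.9)
  mae <- mean(vapply(fit$fold_metrics, `[[`, 0, "mae"))
  expect_lt(mae, 10)        # original units, noise sd is 3 on this scale
  expect_gt(mae, 0.05)      # clearly not z-scale
  p1 <- predict(fit, fx$latents[1:7, ])
  expect_identical(p1, predict(fit, fx$latents[1:7, ]))
  perm <- c(3, 1, 2, 7, 4, 6, 5)
  expect_equal(predict(fit, fx$latents[perm, ]), p1[perm])
  expect_error(predict(fit, fx$latents[, 1:3]), "features")
})
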