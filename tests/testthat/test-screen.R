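test_that("max-cosine ranking matches hand-computed 2D scores", {
  q <- matrix(c(1, 0), 1)
  lib <- rbind(c(1, 0), c(0, 1), c(-1, 0))
  rk <- rank_by_max_cosine(q, lib)
  expect_equal(rk$scores, c(1, 0, -1))
  expect_equal(rk$order, c(1, 2, 3))
  # an identical library item scores exactly 1 and ranks first
  set.seed(51)
  lib2 <- matrix(rnorm(50 * 8), 50)
  rk2 <- rank_by_max_cosine(lib2[17, , drop = FALSE] * 3, lib2)
  expect_equal(rk2$scores[17], 1)
  expect_equal(rk2$order[1], 17)
  # max over queries is monotone in the query set
  q2 <- matrix(rnorm(16), 2)
  expect_true(all(rank_by_max_cosine(rbind(q2, rnorm(8)), lib2)$scores >=
                    rank_by_max_cosine(q2, lib2)$scores - 1e-12))
  expect_warning(rank_by_max_cosine(q, rbind(lib, 0)), "zero-norm")
})

test_that("the enrichment factor follows its definition exactly", {
  # 1000 compounds, 10 actives, the whole top-1% bucket active
  labels <- c(rep(1, 10), rep(0, 990))
  expect_equal(enrichment_factor(labels, 0.01), 100)
  # top bucket without actives
  expect_equal(enrichment_factor(c(0, 0, 1, rep(0, 97)), 0.02), 0)
  # fraction = 1 is exactly 1 for any ranking
  set.seed(52)
  for (i in 1:5)
    expect_equal(enrichment_factor(sample(c(1, 0), 73, TRUE, c(.2, .8))[
      seq_len(73)], 1), 1)
  # invariant to permutations below the top bucket
  r <- c(1, 0, 1, rep(c(0, 1), 20))
  top <- ceiling(0.05 * length(r))
  tail_perm <- c(seq_len(top), top + sample(length(r) - top))
  expect_equal(enrichment_factor(r, 0.05),
               enrichment_factor(r[tail_perm], 0.05))
  expect_error(enrichment_factor(rep(0, 10), 0.01), "no actives")
})

test_that("ROC-AUC hits its boundary cases", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0)), 0)
})

test_that("benchmark iterations exclude the query actives from the pool", {
  lib <- screening_library(20, 200, latent_dim = 8L, seed = 53L)
  run <- run_screening_benchmark(lib$latents, lib$labels, n_queries = 5L,
                                 iterations = 10L, seed = 3L)
  expect_equal(nrow(run$per_iteration), 10L)
  # pool size = library - queries; EF bounded by pool composition
  expect_true(all(run$per_iteration$ef >= 0))
  run2 <- run_screening_benchmark(lib$latents, lib$labels, n_queries = 5L,
                                  iterations = 10L, seed = 3L)
  expect_identical(run$per_iteration, run2$per_iteration)
  expect_error(run_screening_benchmark(lib$latents, lib$labels,
                                       n_queries = 25L, iterations = 2L),
               "actives")
})

test_that("planted active clusters produce strong enrichment", {
  lib <- screening_library(40, 2000, cluster_spread = 0.4, signal = 4,
                           latent_dim = 16L, seed = 54L)
  run <- run_screening_benchmark(lib$latents, lib$labels, n_queries = 10L,
                                 iterations = 25L, seed = 9L)
  expect_gt(run$summary$mean_ef, 5)
  expect_gt(run$summary$mean_auc, 0.8)
})

test_that("the Tanimoto baseline ranks identical fingerprints first", {
  fps <- morgan_fingerprints(c("CCO", "CCN", "c1ccccc1", "CCOC"))
  rk <- rank_by_max_tanimoto(fps[1, , drop = FALSE], fps)
  expect_equal(rk$scores[1], 1)
  expect_equal(rk$order[1], 1)
  expect_true(all(rk$scores >= 0 & rk$scores <= 1))
})
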