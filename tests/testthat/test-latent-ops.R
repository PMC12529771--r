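test_that("euclidean search sorts ascending with index tie-breaks", {
  lib <- rbind(c(0, 0), c(3, 4), c(1, 0))
  res <- euclidean_search(c(0, 0), lib, k = 3)
  expect_equal(res$index, c(1, 3, 2))
  expect_equal(res$distance, c(0, 1, 5))
  # k larger than the library returns everything
  expect_equal(nrow(euclidean_search(c(0, 0), lib, k = 10)), 3L)
  # exact ties resolve to the lower index
  tie <- rbind(c(1, 0), c(0, 1), c(1, 0))
  expect_equal(euclidean_search(c(0, 0), tie, k = 3)$index, c(1, 2, 3))
  expect_error(euclidean_search(c(0, 0), tie[0, ]), "empty")
  expect_error(euclidean_search(c(0, 0, 0), tie), "dimension")
})

test_that("perturbation is exact at delta 0 and unbiased otherwise", {
  xi <- rnorm(16)
  p0 <- perturb(xi, delta = 0, count = 5, seed = 2)
  expect_equal(p0, matrix(rep(xi, each = 5), 5), ignore_attr = TRUE)
  p <- perturb(xi, delta = 0.2, count = 10000, seed = 2)
  expect_equal(nrow(p), 10000L)
  # CLT bound: sample mean within 4 * delta / sqrt(n) per coordinate
  expect_true(all(abs(colMeans(p) - xi) < 4 * 0.2 / sqrt(10000)))
  expect_identical(p, perturb(xi, delta = 0.2, count = 10000, seed = 2))
})

test_that("interpolation endpoints are exact and steps equidistant", {
  x1 <- rep(0, 8); x2 <- rep(1, 8)
  path <- interpolate(x1, x2, 4)
  expect_equal(path[, 1], c(0, 0.25, 0.5, 0.75, 1))
  set.seed(61)
  a <- rnorm(32); b <- rnorm(32)
  for (n in c(1, 3, 7)) {
    p <- interpolate(a, b, n)
    expect_identical(p[1, ], a)
    expect_identical(p[n + 1, ], b)
    steps <- sqrt(rowSums(diff(p)^2))
    expect_equal(steps, rep(steps[1], n), tolerance = 1e-9)
  }
  expect_error(interpolate(a, b[1:5], 3), "differ")
})

test_that("blending reproduces members, interpolation and the simplex grid", {
  set.seed(62)
  L <- matrix(rnorm(3 * 12), 3)
  expect_equal(blend(L, c(0, 1, 0)), L[2, ])
  a <- L[1, ]; b <- L[2, ]
  for (i in 0:5) {
    expect_equal(blend(L[1:2, ], c(1 - i / 5, i / 5)),
                 interpolate(a, b, 5)[i + 1, ], tolerance = 1e-12)
  }
  expect_error(blend(L, c(0.5, 0.2, 0.2)), "sum to 1")
  # weight grid with step 1/6 over the 3-simplex: C(8, 2) = 28 points
  grid <- expand.grid(i = 0:6, j = 0:6)
  grid <- grid[grid$i + grid$j <= 6, ]
  expect_equal(nrow(grid), 28L)
  blended <- apply(grid, 1, function(g)
    blend(L, c(g[1], g[2], 6 - g[1] - g[2]) / 6))
  expect_equal(dim(blended), c(12L, 28L))
})

test_that("latent Gaussians are recovered within Monte-Carlo error", {
  set.seed(63)
  mu <- rnorm(12, 0, 2); sigma <- runif(12, 0.5, 2)
  corpus <- sweep(sweep(matrix(rnorm(10000 * 12), 10000), 2, sigma, "*"),
                  2, mu, "+")
  g <- fit_latent_gaussians(corpus)
  expect_true(all(abs(g$mean - mu) < 0.05 * pmax(sigma, 1)))
  expect_true(all(abs(g$sd - sigma) < 0.05 * pmax(sigma, 1)))
  s <- sample_semirandom(g, 2000, seed = 4)
  expect_true(all(abs(colMeans(s) - g$mean) < 4 * g$sd / sqrt(2000)))
  expect_identical(s, sample_semirandom(g, 2000, seed = 4))
  # constant dimension stays constant
  corpus[, 3] <- 7
  g2 <- fit_latent_gaussians(corpus)
  expect_true(all(sample_semirandom(g2, 50, seed = 1)[, 3] == 7))
  expect_error(fit_latent_gaussians(corpus[1, , drop = FALSE]), ">= 2")
})

test_that("descriptor directions recover planted linear structure", {
  set.seed(64)
  d <- 24
  pca_corpus <- matrix(rnorm(600 * d), 600)
  held_out <- matrix(rnorm(400 * d), 400)
  truth <- matrix(0, d, 2)
  truth[, 1] <- latentmol:::random_unit_vector(d)
  truth[, 2] <- latentmol:::random_unit_vector(d)
  desc <- data.frame(a = held_out %*% truth[, 1],
                     b = held_out %*% truth[, 2] + 5)
  pca <- latent_pca(pca_corpus)
  dd <- fit_descriptor_directions(pca, held_out, desc)
  for (j in 1:2) {
    ang <- acos(abs(sum(dd$directions[, j] * truth[, j]))) * 180 / pi
    expect_lt(ang, 1)
    expect_gte(dd$pearson_r[j], 0.999)
  }
  # angles: identical and opposite directions
  v <- dd$directions[, 1]
  ang <- pairwise_angles(cbind(v, v, -v))
  expect_equal(ang[1, 2], 0, tolerance = 1e-6)
  expect_equal(ang[1, 3], 180, tolerance = 1e-6)
  # unit norm
  expect_equal(colSums(dd$directions^2), c(a = 1, b = 1), tolerance = 1e-9)
})

test_that("walks move the planted descriptor monotonically", {
  set.seed(65)
  d <- 16
  w <- latentmol:::random_unit_vector(d)
  corpus <- matrix(rnorm(300 * d), 300)
  held <- matrix(rnorm(200 * d), 200)
  desc <- data.frame(y = held %*% w)
  dd <- fit_descriptor_directions(latent_pca(corpus), held, desc)
  ref <- rnorm(d)
  mags <- seq(-2, 2, by = 0.5)
  walked <- latent_walk(ref, dd, mags, descriptor = "y")
  expect_equal(walked[mags == 0, ], ref, ignore_attr = TRUE)
  vals <- as.numeric(walked %*% w)
  expect_true(all(diff(vals) > 0) || all(diff(vals) < 0))
  # positive magnitudes increase the modelled descriptor
  expect_gt(vals[length(vals)] * sign(sum(dd$directions[, 1] * w)),
            vals[1] * sign(sum(dd$directions[, 1] * w)))
})

test_that("PCA guards against unidentifiable components", {
  x <- matrix(rnorm(20 * 10), 20)
  expect_error(latent_pca(x, n_components = 25), "at most")
  p <- latent_pca(x)
  expect_equal(ncol(p$rotation), 10L)
  expect_error(fit_descriptor_directions(p, x[1:5, ], data.frame(a = 1:5)),
               "components")
})
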