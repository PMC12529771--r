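# Latent-space algebra on molecular descriptors: Euclidean similarity
# search, controlled Gaussian perturbation, two-point and weighted
# interpolation, semirandom sampling from fitted per-dimension Gaussians,
# and PCA-derived descriptor directions with pairwise angles and directed
# walks.

#' Euclidean nearest-neighbour search
#'
#' Sorts library items by Euclidean distance to the query, ascending, with
#' ties broken by ascending library index.
#'
#' @param query latent vector.
#' @param library latent matrix (rows = molecules).
#' @param k neighbours to return (clipped to the library size).
#' @return data.frame with `index` and `distance`, ascending.
#' @export
euclidean_search <- function(query, library, k = 10L) {
  library <- as.matrix(library)
  if (nrow(library) == 0L) stop("empty library")
  query <- as.numeric(query)
  if (length(query) != ncol(library))
    stop("query length ", length(query), " != library dimension ",
         ncol(library))
  d <- sqrt(colSums((t(library) - query)^2))
  ord <- order(d, seq_along(d))[seq_len(min(k, nrow(library)))]
  data.frame(index = ord, distance = d[ord])
}

#' Perturb a latent vector
#'
#' Draws `count` vectors `xi_i = xi + delta * r` with `r` standard normal,
#' the vicinity-sampling rule for generating close structural analogues of
#' a query molecule; `delta` (default 0.2, the case-study setting) controls
#' how far the analogues stray.
#'
#' @param xi query latent vector.
#' @param delta scaling factor (>= 0).
#' @param count number of perturbed vectors.
#' @param seed RNG seed.
#' @return matrix (count x length(xi)).
#' @export
perturb <- function(xi, delta = 0.2, count = 1L, seed = 1L) {
  stopifnot(is.finite(delta), delta >= 0, count >= 1)
  xi <- as.numeric(xi)
  set.seed(seed)
  r <- matrix(rnorm(count * length(xi)), count)
  sweep(delta * r, 2L, xi, "+")
}

#' Interpolate between two latent vectors
#'
#' Returns the n + 1 points `xi_1 + (i/n) (xi_2 - xi_1)`, i = 0..n:
#' equidistant samples along the straight path, endpoints exact.
#'
#' @param xi1,xi2 endpoint latent vectors.
#' @param n number of equidistant steps (>= 1).
#' @return matrix ((n + 1) x d), first row `xi1`, last row `xi2`.
#' @export
interpolate <- function(xi1, xi2, n) {
  xi1 <- as.numeric(xi1); xi2 <- as.numeric(xi2)
  if (length(xi1) != length(xi2)) stop("endpoint dimensions differ")
  stopifnot(n >= 1)
  tgrid <- seq(0, 1, length.out = n + 1)
  out <- outer(1 - tgrid, xi1) + outer(tgrid, xi2)
  out[1, ] <- xi1; out[n + 1, ] <- xi2
  out
}

#' Weighted blend of several latent vectors
#'
#' `xi_new = sum_j w_j xi_j` with the weights summing to 1; with two
#' vectors and weights (1 - i/n, i/n) this reproduces the interpolation
#' path.
#'
#' @param latents matrix (rows = input vectors).
#' @param weights numeric weights, `sum(weights) == 1` within 1e-9.
#' @return the blended latent vector.
#' @export
blend <- function(latents, weights) {
  latents <- as.matrix(latents)
  stopifnot(nrow(latents) == length(weights))
  if (abs(sum(weights) - 1) > 1e-9)
    stop("weights must sum to 1 (got ", format(sum(weights)), ")")
  as.numeric(crossprod(latents, weights))
}

#' Fit per-dimension Gaussians to a latent corpus
#'
#' The latent distribution of valid molecules is near-Gaussian per
#' dimension, so new "semirandom" vectors can be sampled from the fitted
#' independent per-dimension normals.
#'
#' @param latents latent corpus matrix (>= 2 rows).
#' @return a `latent_gaussian_model` with `mean` and `sd` vectors.
#' @export
fit_latent_gaussians <- function(latents) {
  latents <- as.matrix(latents)
  if (nrow(latents) < 2L) stop("need >= 2 vectors to fit dispersions")
  structure(list(mean = colMeans(latents), sd = apply(latents, 2L, sd)),
            class = "latent_gaussian_model")
}

#' @rdname fit_latent_gaussians
#' @param model a `latent_gaussian_model`.
#' @param count vectors to sample.
#' @param seed RNG seed.
#' @return matrix (count x latent dimension).
#' @export
sample_semirandom <- function(model, count, seed = 1L) {
  stopifnot(inherits(model, "latent_gaussian_model"), count >= 1)
  set.seed(seed)
  d <- length(model$mean)
  m <- matrix(rnorm(count * d), count, d)
  sweep(sweep(m, 2L, model$sd, "*"), 2L, model$mean, "+")
}

#' Principal components of a latent corpus
#'
#' @param latents latent corpus matrix.
#' @param n_components components to keep; default
#'   `min(latent dim, rows - 1)`.
#' @return a `latent_pca` with `rotation` (d x n_components), `center` and
#'   `sdev`.
#' @export
latent_pca <- function(latents, n_components = NULL) {
  latents <- as.matrix(latents)
  max_comp <- min(ncol(latents), nrow(latents) - 1L)
  if (is.null(n_components)) n_components <- max_comp
  if (n_components > max_comp)
    stop("at most ", max_comp, " components are identifiable from ",
         nrow(latents), " samples; reduce n_components")
  p <- prcomp(latents, center = TRUE, scale. = FALSE)
  structure(list(rotation = p$rotation[, seq_len(n_components), drop = FALSE],
                 center = p$center,
                 sdev = p$sdev[seq_len(n_components)]),
            class = "latent_pca")
}

#' Descriptor directions in latent space
#'
#' For each descriptor column, ordinary least squares of the descriptor on
#' the PC scores of a held-out latent set yields per-component weights; the
#' direction is the unit-normalized weighted sum of the PC loading vectors,
#' expressed in latent coordinates so directions can be compared
#' geometrically and walked along.  The held-out set should be disjoint
#' from the PCA corpus.
#'
#' @param pca a [latent_pca()] fit.
#' @param latents held-out latent matrix (rows align with `descriptors`).
#' @param descriptors data.frame/matrix of descriptor values.
#' @return a `descriptor_directions` object: `directions` (unit columns,
#'   one per descriptor), `weights` (per-PC regression weights),
#'   `pearson_r` and `p_value` per descriptor.
#' @export
fit_descriptor_directions <- function(pca, latents, descriptors) {
  stopifnot(inherits(pca, "latent_pca"))
  latents <- as.matrix(latents)
  descriptors <- as.matrix(descriptors)
  stopifnot(nrow(latents) == nrow(descriptors))
  ncomp <- ncol(pca$rotation)
  if (nrow(latents) <= ncomp)
    stop("need more held-out samples (", nrow(latents),
         ") than PCA components (", ncomp, "); reduce the component count")
  scores <- sweep(latents, 2L, pca$center, "-") %*% pca$rotation
  dn <- colnames(descriptors)
  if (is.null(dn)) dn <- paste0("descriptor", seq_len(ncol(descriptors)))
  directions <- matrix(NA_real_, ncol(latents), ncol(descriptors),
                       dimnames = list(NULL, dn))
  weights <- matrix(NA_real_, ncomp, ncol(descriptors),
                    dimnames = list(colnames(pca$rotation), dn))
  r <- pv <- setNames(numeric(ncol(descriptors)), dn)
  for (j in seq_len(ncol(descriptors))) {
    fit <- lm(descriptors[, j] ~ scores)
    beta <- coef(fit)[-1L]
    beta[is.na(beta)] <- 0
    v <- pca$rotation %*% beta
    nv <- sqrt(sum(v^2))
    if (nv == 0) stop("descriptor '", dn[j], "' has a null direction")
    directions[, j] <- v / nv
    weights[, j] <- beta
    ct <- cor.test(fitted(fit), descriptors[, j])
    r[j] <- unname(ct$estimate)
    pv[j] <- ct$p.value
  }
  structure(list(directions = directions, weights = weights,
                 pearson_r = r, p_value = pv),
            class = "descriptor_directions")
}

#' Pairwise angles between descriptor directions
#'
#' @param directions a `descriptor_directions` object or a matrix of unit
#'   column vectors.
#' @return symmetric matrix of angles in degrees.
#' @export
pairwise_angles <- function(directions) {
  v <- if (inherits(directions, "descriptor_directions"))
    directions$directions else as.matrix(directions)
  cosine <- crossprod(v) / tcrossprod(sqrt(colSums(v^2)))
  acos(pmin(pmax(cosine, -1), 1)) * 180 / pi
}

#' Walk along a descriptor direction
#'
#' Returns `xi_ref + m * direction` for each magnitude `m`; walking in the
#' positive direction increases the modelled descriptor.
#'
#' @param xi_ref reference latent vector.
#' @param direction unit direction vector (or a `descriptor_directions`
#'   plus `descriptor` name).
#' @param magnitudes numeric vector of step sizes (may be negative).
#' @param descriptor descriptor name when `direction` is a fitted object.
#' @return matrix (length(magnitudes) x d).
#' @export
latent_walk <- function(xi_ref, direction, magnitudes, descriptor = NULL) {
  if (inherits(direction, "descriptor_directions")) {
    stopifnot(!is.null(descriptor))
    direction <- direction$directions[, descriptor]
  }
  xi_ref <- as.numeric(xi_ref)
  direction <- as.numeric(direction)
  stopifnot(length(xi_ref) == length(direction))
  sweep(outer(magnitudes, direction), 2L, xi_ref, "+")
}
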