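# Synthetic-data generators that make every pipeline stage testable offline:
# grammar-built toy SMILES corpora, planted protonation-state penalty tables,
# planted ADMET endpoints, and screening libraries with controllable signal.
# All generators are pure functions of their parameters and seed.

random_unit_vector <- function(d) {
  v <- rnorm(d)
  v / sqrt(sum(v^2))
}

# Random acyclic molecular tree over C/N/O (valences 4/3/2), optionally
# grafted onto a benzene core, emitted as a SMILES string.  Always valid by
# construction; canonicalization and curation happen downstream.
random_molecule_smiles <- function(n_heavy, ring_prob = 0.35) {
  atoms <- c("C", "N", "O")
  free <- c(C = 3L, N = 2L, O = 1L)  # open slots beyond the parent bond
  grow_tree <- function(n) {
    # returns a SMILES fragment rooted at its first atom
    el <- sample(atoms, 1L, prob = c(0.72, 0.14, 0.14))
    n <- n - 1L
    slots <- free[[el]]
    children <- character(0)
    while (n > 0L && slots > 0L) {
      take <- sample.int(n, 1L)
      children <- c(children, grow_tree(take))
      n <- n - take
      slots <- slots - 1L
    }
    if (length(children) == 0L) return(el)
    last <- children[length(children)]
    branches <- children[-length(children)]
    wrapped <- if (length(branches) > 0L)
      paste0("(", branches, ")", collapse = "") else ""
    paste0(el, wrapped, last)
  }
  if (n_heavy >= 7L && runif(1) < ring_prob) {
    n_sub <- n_heavy - 6L
    subs <- character(0)
    while (n_sub > 0L) {
      take <- sample.int(min(n_sub, 6L), 1L)
      subs <- c(subs, grow_tree(take))
      n_sub <- n_sub - take
    }
    positions <- c("", "", "", "", "")  # 5 substitutable ring carbons
    positions[seq_len(min(length(subs), 5L))] <- paste0("(", head(subs, 5L), ")")
    paste0("c1c", positions[1], "c", positions[2], "c", positions[3],
           "c", positions[4], "c", positions[5], "1")
  } else {
    grow_tree(n_heavy)
  }
}

#' Generate a curated toy SMILES corpus
#'
#' Draws branched alkane/ether/amine trees and simple aromatics from a
#' constrained generative grammar, canonicalizes them with the chemistry
#' toolkit, passes them through [curate()] and keeps the accepted, unique
#' canonical SMILES.  Every returned molecule therefore satisfies the full
#' curation contract unchanged.
#'
#' @param n number of molecules.
#' @param max_heavy_atoms heavy-atom cap (>= 4 so the curation heavy-atom
#'   filter can pass).
#' @param min_heavy_atoms heavy-atom floor (> 3 by curation).
#' @param seed RNG seed; same seed, same corpus.
#' @return character vector of `n` unique canonical SMILES.
#' @export
toy_corpus <- function(n, max_heavy_atoms = 15L, min_heavy_atoms = 4L,
                       seed = 1L) {
  stopifnot(n >= 1, max_heavy_atoms >= 4, min_heavy_atoms > 3,
            min_heavy_atoms <= max_heavy_atoms)
  set.seed(seed)
  out <- character(0)
  tries <- 0L
  while (length(out) < n) {
    tries <- tries + 1L
    if (tries > 60L)
      stop("grammar space exhausted: cannot generate ", n,
           " unique molecules with at most ", max_heavy_atoms, " heavy atoms")
    batch <- vapply(sample(min_heavy_atoms:max_heavy_atoms,
                           2L * (n - length(out)) + 8L, replace = TRUE),
                    random_molecule_smiles, "")
    cur <- curate(batch)
    out <- unique(c(out, cur$accepted$canonical_smiles))
  }
  out[seq_len(n)]
}

#' Planted protonation-state penalty table
#'
#' Emulates an enumerated protonation-state table: each parent has several
#' states with latent features, and the state penalty follows a planted
#' linear rule `penalty = softplus(signal * w . latent + noise)` with a
#' shared hidden direction `w`.  Larger `signal` makes the minimum-penalty
#' state predictable from the latent alone; `signal = 0` reduces recovery to
#' chance.
#'
#' @param n_parents number of parent compounds.
#' @param states_range integer range (min, max) of states per parent
#'   (capped at 64).
#' @param latent_dim latent feature dimension.
#' @param signal signal strength of the planted rule.
#' @param seed RNG seed.
#' @return list with `table` (data.frame: parent_id, state_id, penalty),
#'   `latents` (matrix, one row per state) and `direction` (the planted w).
#' @export
penalty_table <- function(n_parents, states_range = c(2L, 16L),
                          latent_dim = 16L, signal = 10, seed = 1L) {
  stopifnot(n_parents >= 1, states_range[1] >= 1, states_range[2] <= 64,
            states_range[1] <= states_range[2], signal >= 0)
  set.seed(seed)
  w <- random_unit_vector(latent_dim)
  ks <- sample(states_range[1]:states_range[2], n_parents, replace = TRUE)
  total <- sum(ks)
  latents <- matrix(rnorm(total * latent_dim), total, latent_dim)
  score <- as.numeric(latents %*% w)
  penalty <- log1p(exp(signal * score + rnorm(total)))
  tab <- data.frame(parent_id = rep(seq_len(n_parents), ks),
                    state_id = unlist(lapply(ks, seq_len)),
                    penalty = penalty)
  list(table = tab, latents = latents, direction = w)
}

#' Planted ADMET endpoint table
#'
#' Latent features with a linear planted target: regression targets are
#' `effect * w . latent + noise`; classification labels threshold the same
#' latent score so that the positive-class prevalence matches `imbalance`
#' in expectation.
#'
#' @param n number of samples.
#' @param kind `"regression"` or `"classification"`.
#' @param effect linear effect size (signal sd).
#' @param noise noise sd; the signal-to-noise (amplitude) ratio is
#'   `effect/noise`.
#' @param imbalance positive-class prevalence (classification only).
#' @param latent_dim latent feature dimension.
#' @param seed RNG seed.
#' @return list with `latents`, `target` (numeric or 0/1), `direction`.
#' @export
admet_table <- function(n, kind = c("regression", "classification"),
                        effect = 1, noise = 0.316, imbalance = 0.5,
                        latent_dim = 32L, seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(n >= 1, effect >= 0, noise >= 0)
  if (kind == "classification")
    stopifnot(imbalance > 0, imbalance < 1)
  set.seed(seed)
  w <- random_unit_vector(latent_dim)
  latents <- matrix(rnorm(n * latent_dim), n, latent_dim)
  score <- effect * as.numeric(latents %*% w) + rnorm(n, 0, noise)
  target <- if (kind == "regression") score else
    as.numeric(score > qnorm(1 - imbalance, 0, sqrt(effect^2 + noise^2)))
  list(latents = latents, target = target, direction = w)
}

#' Synthetic screening library
#'
#' Actives are drawn from a compact cluster displaced by `signal` along a
#' random direction with spread `cluster_spread`; decoys come from the
#' standard-normal background.  `signal = 0` with `cluster_spread = 1`
#' collapses both to one distribution (the null case where enrichment is 1
#' in expectation).
#'
#' @param n_actives,n_decoys class sizes.
#' @param cluster_spread sd of the active cluster.
#' @param signal displacement of the active cluster centre.
#' @param latent_dim latent dimension.
#' @param seed RNG seed.
#' @return list with `latents` ((n_actives + n_decoys) x latent_dim) and
#'   `labels` (1 = active first, then 0 = decoy).
#' @export
screening_library <- function(n_actives, n_decoys, cluster_spread = 1,
                              signal = 0, latent_dim = 32L, seed = 1L) {
  stopifnot(n_actives >= 1, n_decoys >= 1)
  set.seed(seed)
  centre <- signal * random_unit_vector(latent_dim)
  actives <- matrix(rnorm(n_actives * latent_dim, 0, cluster_spread),
                    n_actives, latent_dim)
  actives <- sweep(actives, 2L, centre, "+")
  decoys <- matrix(rnorm(n_decoys * latent_dim), n_decoys, latent_dim)
  list(latents = rbind(actives, decoys),
       labels = rep(c(1L, 0L), c(n_actives, n_decoys)))
}
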