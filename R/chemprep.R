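# Curation of raw SMILES corpora into the canonical training representation.
#
# A molecule is accepted when, after salt/solvent stripping (largest organic
# fragment) and stereochemistry removal, it is a single organic fragment and
# satisfies the strict bounds 12 < MolWt < 600, HeavyAtomCount > 3 and
# -7 < MolLogP < 5.  "Organic" means: contains at least one carbon and only
# elements from {H, B, C, N, O, F, P, S, Cl, Br, I}.

#' Names of the 13 molecular properties, in canonical order
#'
#' The fixed order of the auxiliary regression targets computed for every
#' curated molecule: MolWt (g/mol), MolLogP, QED, MinPartialCharge,
#' MaxPartialCharge, NumValenceElectrons, HeavyAtomCount, NumHAcceptors,
#' NumHDonors, LabuteASA, BalabanJ, MolMR, TPSA (A^2).
#'
#' @return character vector of length 13.
#' @export
property_names <- function() {
  c("MolWt", "MolLogP", "QED", "MinPartialCharge", "MaxPartialCharge",
    "NumValenceElectrons", "HeavyAtomCount", "NumHAcceptors", "NumHDonors",
    "LabuteASA", "BalabanJ", "MolMR", "TPSA")
}

#' Curation filter bounds
#'
#' Strict (exclusive) bounds applied during curation.
#' @return named list with `mw`, `heavy_atoms` and `logp` entries.
#' @export
curation_bounds <- function() {
  list(mw = c(12, 600), heavy_atoms = 3, logp = c(-7, 5))
}

#' Curate a raw SMILES corpus
#'
#' Canonicalizes each record (largest organic fragment, stereochemistry
#' stripped), computes the 13 molecular properties, applies the curation
#' bounds strictly, and removes duplicates by canonical SMILES (first seen
#' kept).  Empty lines are skipped.  Per-record failures never abort the run;
#' each rejected record carries exactly one machine-readable reason code from
#' `parse_error`, `no_organic_fragment`, `descriptor_error`, `mw_range`,
#' `heavy_atoms`, `logp_range`, `duplicate`.
#'
#' @param smiles character vector of raw SMILES (one record per element).
#' @return list with components
#'   * `accepted`: data.frame `raw_smiles`, `canonical_smiles` + 13 property
#'     columns in [property_names()] order,
#'   * `rejected`: data.frame `raw_smiles`, `reason`,
#'   * `report`: named integer vector of counts (input, skipped_empty,
#'     accepted, rejected).
#' @export
curate <- function(smiles) {
  if (!is.character(smiles)) stop("`smiles` must be a character vector")
  n_input <- length(smiles)
  smiles <- trimws(smiles)
  keep <- nzchar(smiles)
  n_empty <- sum(!keep)
  smiles <- smiles[keep]

  rec <- rdkit_process(smiles)
  b <- curation_bounds()
  reason <- rep(NA_character_, length(smiles))
  reason[rec$status != "ok"] <- rec$status[rec$status != "ok"]
  ok <- is.na(reason)
  bad_mw <- ok & !(rec$MolWt > b$mw[1] & rec$MolWt < b$mw[2])
  reason[bad_mw] <- "mw_range"
  ok <- is.na(reason)
  bad_ha <- ok & !(rec$HeavyAtomCount > b$heavy_atoms)
  reason[bad_ha] <- "heavy_atoms"
  ok <- is.na(reason)
  bad_lp <- ok & !(rec$MolLogP > b$logp[1] & rec$MolLogP < b$logp[2])
  reason[bad_lp] <- "logp_range"
  ok <- is.na(reason)
  dup <- ok & duplicated(ifelse(ok, rec$canonical, paste0("\r", seq_along(ok))))
  reason[dup] <- "duplicate"
  ok <- is.na(reason)

  accepted <- cbind(
    data.frame(raw_smiles = smiles[ok],
               canonical_smiles = rec$canonical[ok],
               stringsAsFactors = FALSE),
    rec[ok, property_names(), drop = FALSE])
  rownames(accepted) <- NULL
  rejected <- data.frame(raw_smiles = smiles[!ok], reason = reason[!ok],
                         stringsAsFactors = FALSE)
  list(accepted = accepted, rejected = rejected,
       report = c(input = n_input, skipped_empty = n_empty,
                  accepted = nrow(accepted), rejected = nrow(rejected)))
}

#' Compute the 13-property vector for curated SMILES
#'
#' @param smiles character vector of curated (canonical) SMILES.
#' @return data.frame of 13 named columns in [property_names()] order.
#' @export
compute_properties <- function(smiles) {
  rec <- rdkit_process(smiles)
  bad <- rec$status != "ok"
  if (any(bad))
    stop("property computation failed for: ",
         paste(smiles[bad], collapse = ", "))
  rec[, property_names(), drop = FALSE]
}

#' Fit a per-property standardizing scaler
#'
#' Fits per-column mean and standard deviation on a training property table.
#' Targets are z-scored for model training and inverse-transformed for
#' reporting.
#'
#' @param props data.frame or matrix of property columns (rows = molecules).
#' @return an object of class `property_scaler`.
#' @export
fit_scaler <- function(props) {
  props <- as.matrix(props)
  if (nrow(props) < 2L) stop("need at least two rows to fit a scaler")
  mu <- colMeans(props)
  sigma <- apply(props, 2L, sd)
  zero <- sigma <= 0 | !is.finite(sigma)
  if (any(zero))
    stop("constant property column(s): ",
         paste(colnames(props)[zero], collapse = ", "))
  structure(list(mean = mu, sd = sigma), class = "property_scaler")
}

#' @rdname fit_scaler
#' @param scaler a fitted `property_scaler`.
#' @param x matrix/data.frame to transform (columns as in the fit).
#' @export
scaler_transform <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaler$mean, "-"), 2L, scaler$sd, "/")
}

#' @rdname fit_scaler
#' @export
scaler_inverse <- function(scaler, x) {
  x <- as.matrix(x)
  sweep(sweep(x, 2L, scaler$sd, "*"), 2L, scaler$mean, "+")
}
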