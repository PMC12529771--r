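#' @useDynLib latentmol, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats rnorm runif sd prcomp lm cor pnorm qnorm quantile median
#' @importFrom stats setNames dist cor.test coef fitted predict complete.cases
#' @importFrom utils read.csv write.csv head adist
NULL

# Batched bridge to the RDKit toolkit through the system `python`.
# All chemistry (parsing, canonicalization, descriptors, fingerprints)
# funnels through here so the rest of the package is toolkit-agnostic.

the <- new.env(parent = emptyenv())

bridge_script <- function() {
  p <- system.file("python", "rdkit_bridge.py", package = "latentmol")
  if (!nzchar(p)) stop("rdkit_bridge.py not found in the installed package")
  p
}

#' Is the RDKit python bridge available?
#'
#' Checks once per session that a `python` interpreter with RDKit is on the
#' PATH; the result is cached.
#' @return `TRUE` or `FALSE`.
#' @export
rdkit_available <- function() {
  if (is.null(the$rdkit_ok)) {
    ok <- FALSE
    python <- Sys.which("python")
    if (nzchar(python)) {
      res <- tryCatch(
        system2(python, c("-c", shQuote("import rdkit")),
                stdout = TRUE, stderr = TRUE),
        warning = function(w) "fail", error = function(e) "fail")
      ok <- !identical(res, "fail") && length(res) == 0L
    }
    the$rdkit_ok <- ok
  }
  the$rdkit_ok
}

rdkit_call <- function(smiles, mode) {
  if (!rdkit_available())
    stop("the RDKit python bridge is unavailable: `python` with the rdkit ",
         "package must be on the PATH")
  infile <- tempfile("smiles_", fileext = ".txt")
  outfile <- tempfile("rdkit_", fileext = ".tsv")
  on.exit(unlink(c(infile, outfile)), add = TRUE)
  writeLines(smiles, infile)
  status <- system2(Sys.which("python"),
                    c(bridge_script(), mode, infile, outfile),
                    stdout = NULL, stderr = NULL)
  if (status != 0L || !file.exists(outfile))
    stop("RDKit bridge call failed (mode = ", mode, ")")
  out <- readLines(outfile)
  if (length(out) != length(smiles))
    stop("RDKit bridge returned ", length(out), " records for ",
         length(smiles), " inputs")
  out
}

#' Canonicalize SMILES strings
#'
#' Strips stereochemistry and returns the toolkit-canonical SMILES for each
#' input; unparseable strings map to `NA`.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of the same length; `NA` where parsing failed.
#' @export
canonicalize_smiles <- function(smiles) {
  if (length(smiles) == 0L) return(character(0))
  out <- rdkit_call(smiles, "canon")
  out[!nzchar(out)] <- NA_character_
  out
}

# Raw per-record curation fields: status, canonical, 13 properties.
rdkit_process <- function(smiles) {
  if (length(smiles) == 0L) {
    return(data.frame(status = character(0), canonical = character(0)))
  }
  rec <- strsplit(rdkit_call(smiles, "process"), "\t", fixed = TRUE)
  status <- vapply(rec, `[`, "", 1L)
  canonical <- vapply(rec, `[`, "", 2L)
  props <- matrix(NA_real_, length(rec), length(property_names()),
                  dimnames = list(NULL, property_names()))
  ok <- status == "ok"
  if (any(ok)) {
    vals <- t(vapply(rec[ok], function(r) as.numeric(r[-(1:2)]),
                     numeric(length(property_names()))))
    props[ok, ] <- vals
  }
  cbind(data.frame(status = status, canonical = canonical,
                   stringsAsFactors = FALSE),
        as.data.frame(props))
}

#' Morgan fingerprints (radius 2, 2048 bits)
#'
#' @param smiles character vector of SMILES.
#' @return a logical matrix with one row per molecule and 2048 columns;
#'   rows of unparseable SMILES are all-`NA`.
#' @export
morgan_fingerprints <- function(smiles) {
  out <- rdkit_call(smiles, "fp")
  fp <- matrix(FALSE, length(smiles), 2048L)
  for (i in seq_along(out)) {
    if (identical(out[i], "NA")) {
      fp[i, ] <- NA
    } else if (nzchar(out[i])) {
      fp[i, as.integer(strsplit(out[i], ",", fixed = TRUE)[[1L]]) + 1L] <- TRUE
    }
  }
  fp
}

#' Pairwise Tanimoto distance summary
#'
#' Mean pairwise Tanimoto distance (1 - similarity) over Morgan
#' fingerprints, the conventional diversity measure for generated sets.
#'
#' @param fp logical fingerprint matrix (rows = molecules).
#' @return mean pairwise distance in \[0, 1\].
#' @export
tanimoto_diversity <- function(fp) {
  fp <- fp[stats::complete.cases(fp), , drop = FALSE]
  n <- nrow(fp)
  if (n < 2L) stop("need at least two valid fingerprints")
  m <- fp %*% t(fp)                      # intersections
  pop <- rowSums(fp)
  union <- outer(pop, pop, "+") - m
  sim <- ifelse(union == 0, 1, m / union)
  mean(1 - sim[upper.tri(sim)])
}
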