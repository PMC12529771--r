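# I/O and glue: .smi and latent-matrix readers/writers, seed fan-out, and
# the command-line interface binding the modules into reproducible commands.

#' Read / write .smi files
#'
#' One record per line: a SMILES string optionally followed by
#' whitespace-separated identifier text.  Blank lines are skipped on read.
#'
#' @param path file path.
#' @return data.frame with `smiles` and `id` (`NA` when absent).
#' @export
read_smi <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  parts <- regmatches(lines, regexpr("\\s+", lines), invert = TRUE)
  data.frame(smiles = vapply(parts, `[`, "", 1L),
             id = vapply(parts, function(p) if (length(p) > 1L) p[2L]
                         else NA_character_, ""),
             stringsAsFactors = FALSE)
}

#' @rdname read_smi
#' @param smiles character vector of SMILES.
#' @param id optional identifiers.
#' @export
write_smi <- function(smiles, path, id = NULL) {
  lines <- if (is.null(id)) smiles else paste(smiles, id)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write latent matrices as CSV
#'
#' Column 1 is the identifier, the remaining columns the latent
#' coordinates.  Reals survive the round trip to at least 1e-12.
#'
#' @param latents numeric matrix.
#' @param path file path.
#' @param id row identifiers (default 1..n).
#' @export
write_latent_csv <- function(latents, path, id = NULL) {
  latents <- as.matrix(latents)
  if (is.null(id)) id <- seq_len(nrow(latents))
  df <- data.frame(id = id, latents)
  colnames(df) <- c("id", paste0("z", seq_len(ncol(latents))))
  # full precision so the round trip is lossless at double resolution
  write.csv(format(df, digits = 17, trim = TRUE, scientific = TRUE),
            path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_latent_csv
#' @return for `read_latent_csv`: a numeric matrix with `id` row names.
#' @export
read_latent_csv <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  m
}

#' Derive a component seed from a global seed
#'
#' One global seed fans out to per-component seeds so stochastic stages are
#' isolated: `derive_seed(s, "x")` hashes the component name into
#' `(s * 2654435761 + hash) mod (2^31 - 1)`.
#'
#' @param global_seed integer master seed.
#' @param component component name.
#' @return an integer seed in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(global_seed, component) {
  h <- sum(utf8ToInt(component) * (31^(seq_len(nchar(component)) %% 7)))
  val <- (as.numeric(global_seed) * 2654435761 + h) %% (2^31 - 1)
  as.integer(val) + 1L
}

cli_usage <- function() {
  paste(
    "latentmol <command> [--flag value ...]",
    "",
    "Commands:",
    "  curate       --in FILE.smi|FILE.csv [--smiles-col NAME]",
    "               --out-prefix PREFIX",
    "  train        --in FILE.smi --checkpoint FILE [--layers N --units N",
    "               --latent N --epochs N --batch N --lr X --noise X",
    "               --properties 0|13 --seed N]",
    "  encode       --checkpoint FILE --in FILE.smi --out FILE.csv",
    "  decode       --checkpoint FILE --in latents.csv --out FILE.smi",
    "  validate     --checkpoint FILE --in FILE.smi",
    "  similar      --query-latents FILE.csv --library FILE.csv [--k N]",
    "  perturb      --in latents.csv --row N --delta X --count N --seed N",
    "               --out FILE.csv",
    "  interpolate  --in latents.csv --from N --to N --steps N --out FILE.csv",
    "  blend        --in latents.csv --weights w1,w2,... --out FILE.csv",
    "  sample       --in latents.csv --count N --seed N --out FILE.csv",
    "  directions   --pca-latents FILE.csv --latents FILE.csv",
    "               --descriptors FILE.csv --out FILE.csv",
    "  ilp-train    --latents FILE.csv --states FILE.csv --model FILE",
    "               [--seed N]",
    "  ilp-predict  --model FILE --latents FILE.csv --states FILE.csv",
    "               --out FILE.csv",
    "  admet-train  --latents FILE.csv --targets FILE.csv --endpoint NAME",
    "               --model FILE [--resampling none|undersample|smote]",
    "  admet-predict --model FILE --latents FILE.csv --out FILE.csv",
    "  screen       --latents FILE.csv --labels FILE.csv [--queries N",
    "               --iterations N --seed N] --out FILE.csv",
    "  fixtures     --kind corpus|penalties|admet|screening --n N --seed N",
    "               --out PREFIX",
    "",
    "Global: --help on any command prints this text.",
    sep = "\n")
}

parse_flags <- function(args) {
  flags <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!startsWith(a, "--"))
      stop("unexpected argument '", a, "'", call. = FALSE)
    key <- substring(a, 3L)
    if (identical(key, "help")) {
      flags$help <- TRUE
      i <- i + 1L
    } else {
      if (i == length(args)) stop("flag --", key, " needs a value",
                                  call. = FALSE)
      flags[[key]] <- args[i + 1L]
      i <- i + 2L
    }
  }
  flags
}

flag <- function(flags, key, default = NULL, required = FALSE) {
  if (!is.null(flags[[key]])) return(flags[[key]])
  if (required) stop("missing required flag --", key, call. = FALSE)
  default
}

cli_log <- function(...) {
  message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
}

#' Command-line entry point
#'
#' Thin dispatcher used by the installed `latentmol` script
#' (`system.file("cli", "latentmol", package = "latentmol")`); every
#' subcommand wraps an exported function.  Returns the process exit code: 0
#' on success, 1 on domain errors, 2 on usage errors.
#'
#' @param args character vector of command-line arguments.
#' @return integer exit code, invisibly.
#' @export
cli_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  code <- tryCatch({
    if (length(args) == 0L || args[1L] %in% c("--help", "help")) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    cmd <- args[1L]
    flags <- parse_flags(args[-1L])
    if (isTRUE(flags$help)) {
      cat(cli_usage(), "\n")
      return(invisible(0L))
    }
    handler <- switch(cmd,
      curate = cli_curate, train = cli_train, encode = cli_encode,
      decode = cli_decode, validate = cli_validate, similar = cli_similar,
      perturb = cli_perturb, interpolate = cli_interpolate,
      blend = cli_blend, sample = cli_sample, directions = cli_directions,
      `ilp-train` = cli_ilp_train, `ilp-predict` = cli_ilp_predict,
      `admet-train` = cli_admet_train, `admet-predict` = cli_admet_predict,
      screen = cli_screen, fixtures = cli_fixtures,
      {
        message("unknown command '", cmd, "'\n", cli_usage())
        return(invisible(2L))
      })
    handler(flags)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(code)
}

cli_curate <- function(flags) {
  input <- flag(flags, "in", required = TRUE)
  prefix <- flag(flags, "out-prefix", required = TRUE)
  smiles <- if (grepl("\\.csv$", input, ignore.case = TRUE)) {
    df <- read.csv(input, stringsAsFactors = FALSE)
    col <- flag(flags, "smiles-col", "smiles")
    if (!col %in% names(df))
      stop("column '", col, "' not found in ", input,
           "; use --smiles-col to name it")
    df[[col]]
  } else {
    read_smi(input)$smiles
  }
  cur <- curate(smiles)
  write_smi(cur$accepted$canonical_smiles, paste0(prefix, "_curated.smi"))
  write.csv(cur$accepted[, c("canonical_smiles", property_names())],
            paste0(prefix, "_properties.csv"), row.names = FALSE)
  write.csv(cur$rejected, paste0(prefix, "_rejected.csv"), row.names = FALSE)
  cli_log("curated ", cur$report[["accepted"]], "/", cur$report[["input"]],
          " molecules -> ", prefix, "_curated.smi")
}

cli_train <- function(flags) {
  corpus <- read_smi(flag(flags, "in", required = TRUE))$smiles
  ckpt <- flag(flags, "checkpoint", required = TRUE)
  n_prop <- as.integer(flag(flags, "properties", 0L))
  cfg <- ae_config(
    lstm_layers = as.integer(flag(flags, "layers", 2L)),
    lstm_units = as.integer(flag(flags, "units", 256L)),
    latent_dim = as.integer(flag(flags, "latent", 64L)),
    epochs = as.integer(flag(flags, "epochs", 50L)),
    batch_size = as.integer(flag(flags, "batch", 64L)),
    learning_rate = as.numeric(flag(flags, "lr", 1e-3)),
    noise_sd = as.numeric(flag(flags, "noise", 0.05)),
    n_properties = n_prop,
    seed = as.integer(flag(flags, "seed", 1L)))
  vocab <- build_vocabulary(corpus)
  scaler <- NULL
  targets <- NULL
  if (n_prop > 0L) {
    props <- compute_properties(corpus)
    scaler <- fit_scaler(props)
    targets <- scaler_transform(scaler, props)
  }
  model <- build_model(cfg, vocab, scaler = scaler)
  model <- ae_train(model, corpus, targets = targets, verbose = TRUE)
  save_checkpoint(model, ckpt)
  cli_log("checkpoint written to ", ckpt)
}

cli_encode <- function(flags) {
  ckpt <- flag(flags, "checkpoint", required = TRUE)
  if (!file.exists(ckpt)) stop("checkpoint not found: ", ckpt)
  model <- load_checkpoint(ckpt)
  smi <- read_smi(flag(flags, "in", required = TRUE))
  z <- ae_encode(model, smi$smiles)
  write_latent_csv(z, flag(flags, "out", required = TRUE),
                   id = ifelse(is.na(smi$id), smi$smiles, smi$id))
  cli_log("encoded ", nrow(z), " molecules")
}

cli_decode <- function(flags) {
  model <- load_checkpoint(flag(flags, "checkpoint", required = TRUE))
  z <- read_latent_csv(flag(flags, "in", required = TRUE))
  out <- ae_decode(model, z, check_validity = rdkit_available())
  write_smi(out$smiles, flag(flags, "out", required = TRUE))
  cli_log("decoded ", nrow(out), " latents",
          if (!is.null(out$valid))
            paste0(" (", sum(out$valid), " valid)"))
}

cli_validate <- function(flags) {
  model <- load_checkpoint(flag(flags, "checkpoint", required = TRUE))
  corpus <- read_smi(flag(flags, "in", required = TRUE))$smiles
  rr <- reconstruction_rate(model, corpus)
  cat(sprintf("reconstruction rate: %.4f (%d/%d)\n", rr$rate,
              rr$n - nrow(rr$failures), rr$n))
}

cli_similar <- function(flags) {
  q <- read_latent_csv(flag(flags, "query-latents", required = TRUE))
  lib <- read_latent_csv(flag(flags, "library", required = TRUE))
  res <- euclidean_search(q[1L, ], lib, k = as.integer(flag(flags, "k", 10L)))
  res$id <- rownames(lib)[res$index]
  write.csv(res, stdout(), row.names = FALSE)
}

cli_perturb <- function(flags) {
  z <- read_latent_csv(flag(flags, "in", required = TRUE))
  row <- as.integer(flag(flags, "row", 1L))
  out <- perturb(z[row, ], delta = as.numeric(flag(flags, "delta", 0.2)),
                 count = as.integer(flag(flags, "count", 10L)),
                 seed = as.integer(flag(flags, "seed", 1L)))
  write_latent_csv(out, flag(flags, "out", required = TRUE))
}

cli_interpolate <- function(flags) {
  z <- read_latent_csv(flag(flags, "in", required = TRUE))
  out <- interpolate(z[as.integer(flag(flags, "from", 1L)), ],
                     z[as.integer(flag(flags, "to", 2L)), ],
                     n = as.integer(flag(flags, "steps", 10L)))
  write_latent_csv(out, flag(flags, "out", required = TRUE))
}

cli_blend <- function(flags) {
  z <- read_latent_csv(flag(flags, "in", required = TRUE))
  w <- as.numeric(strsplit(flag(flags, "weights", required = TRUE),
                           ",")[[1L]])
  out <- matrix(blend(z[seq_along(w), , drop = FALSE], w), 1)
  write_latent_csv(out, flag(flags, "out", required = TRUE))
}

cli_sample <- function(flags) {
  z <- read_latent_csv(flag(flags, "in", required = TRUE))
  g <- fit_latent_gaussians(z)
  out <- sample_semirandom(g, count = as.integer(flag(flags, "count", 100L)),
                           seed = as.integer(flag(flags, "seed", 1L)))
  write_latent_csv(out, flag(flags, "out", required = TRUE))
}

cli_directions <- function(flags) {
  zp <- read_latent_csv(flag(flags, "pca-latents", required = TRUE))
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  desc <- read.csv(flag(flags, "descriptors", required = TRUE))
  pca <- latent_pca(zp)
  dd <- fit_descriptor_directions(pca, z, desc)
  out <- data.frame(descriptor = colnames(dd$directions),
                    pearson_r = dd$pearson_r, p_value = dd$p_value,
                    t(dd$directions))
  write.csv(out, flag(flags, "out", required = TRUE), row.names = FALSE)
}

cli_ilp_train <- function(flags) {
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  states <- read.csv(flag(flags, "states", required = TRUE))
  tab <- binarize_states(states)
  model <- train_protonation(z, tab,
                             seed = as.integer(flag(flags, "seed", 1L)))
  saveRDS(model, flag(flags, "model", required = TRUE))
  acc <- vapply(model$fold_metrics, `[[`, 0, "accuracy")
  cli_log("cross-validated accuracy: ", sprintf("%.3f", mean(acc)))
}

cli_ilp_predict <- function(flags) {
  model <- readRDS(flag(flags, "model", required = TRUE))
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  states <- read.csv(flag(flags, "states", required = TRUE))
  out <- do.call(rbind, lapply(split(seq_len(nrow(states)),
                                     states$parent_id), function(rows) {
    rk <- rank_states(model, z[rows, , drop = FALSE])
    data.frame(states[rows, , drop = FALSE],
               probability = rk$probabilities,
               is_predominant = seq_along(rows) == rk$predominant)
  }))
  write.csv(out, flag(flags, "out", required = TRUE), row.names = FALSE)
}

cli_admet_train <- function(flags) {
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  targets <- read.csv(flag(flags, "targets", required = TRUE))
  endpoint <- flag(flags, "endpoint", required = TRUE)
  task <- admet_task(endpoint,
                     resampling = flag(flags, "resampling", "none"))
  model <- train_admet(z, targets[[endpoint]], task,
                       seed = as.integer(flag(flags, "seed", 1L)))
  saveRDS(model, flag(flags, "model", required = TRUE))
  cli_log("trained ", endpoint, " (", task$kind, ")")
}

cli_admet_predict <- function(flags) {
  model <- readRDS(flag(flags, "model", required = TRUE))
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  out <- data.frame(id = rownames(z), prediction = predict(model, z))
  write.csv(out, flag(flags, "out", required = TRUE), row.names = FALSE)
}

cli_screen <- function(flags) {
  z <- read_latent_csv(flag(flags, "latents", required = TRUE))
  labels <- read.csv(flag(flags, "labels", required = TRUE))[[1L]]
  run <- run_screening_benchmark(
    z, labels, n_queries = as.integer(flag(flags, "queries", 5L)),
    iterations = as.integer(flag(flags, "iterations", 100L)),
    seed = as.integer(flag(flags, "seed", 1L)))
  print(run)
  write.csv(run$per_iteration, flag(flags, "out", required = TRUE),
            row.names = FALSE)
}

cli_fixtures <- function(flags) {
  kind <- flag(flags, "kind", required = TRUE)
  n <- as.integer(flag(flags, "n", 100L))
  seed <- as.integer(flag(flags, "seed", 1L))
  prefix <- flag(flags, "out", required = TRUE)
  switch(kind,
    corpus = write_smi(toy_corpus(n, seed = seed), paste0(prefix, ".smi")),
    penalties = {
      pt <- penalty_table(n, seed = seed)
      write.csv(pt$table, paste0(prefix, "_states.csv"), row.names = FALSE)
      write_latent_csv(pt$latents, paste0(prefix, "_latents.csv"))
    },
    admet = {
      at <- admet_table(n, seed = seed)
      write_latent_csv(at$latents, paste0(prefix, "_latents.csv"))
      write.csv(data.frame(target = at$target),
                paste0(prefix, "_targets.csv"), row.names = FALSE)
    },
    screening = {
      sl <- screening_library(max(2L, n %/% 50L), n, seed = seed)
      write_latent_csv(sl$latents, paste0(prefix, "_latents.csv"))
      write.csv(data.frame(label = sl$labels),
                paste0(prefix, "_labels.csv"), row.names = FALSE)
    },
    stop("unknown fixture kind '", kind, "'"))
  cli_log("fixtures written with prefix ", prefix)
}
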