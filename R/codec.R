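# Character-level SMILES tokenization with two-character halogen tokens
# ("Cl", "Br"), special start/end/pad tokens, padding to a fixed width and
# one-hot encoding/decoding.

TOKEN_START <- "^"
TOKEN_END <- "$"
TOKEN_PAD <- " "

# Longest-match split: try "Cl"/"Br" first, then single characters.
split_tokens <- function(smiles) {
  out <- character(0)
  chars <- strsplit(smiles, "", fixed = TRUE)[[1L]]
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    two <- if (i < n) paste0(chars[i], chars[i + 1L]) else ""
    if (two %in% c("Cl", "Br")) {
      out <- c(out, two)
      i <- i + 2L
    } else {
      out <- c(out, chars[i])
      i <- i + 1L
    }
  }
  out
}

#' Build a token vocabulary from a curated corpus
#'
#' Tokenizes every SMILES at character level (except the two-character
#' halogens "Cl" and "Br"), collects the sorted unique content tokens, and
#' appends the three special tokens (start, end, pad).
#' `max_sequence_length` is the longest tokenized length including the added
#' start/end tokens (i.e. the padded width), unless overridden.
#'
#' @param corpus character vector of canonical SMILES.
#' @param max_length optional fixed padded width overriding the corpus
#'   maximum.
#' @return an object of class `token_vocabulary` with fields `tokens`
#'   (ordered token list), `start`, `end`, `pad` (1-based indices) and
#'   `max_sequence_length`.
#' @export
build_vocabulary <- function(corpus, max_length = NULL) {
  if (length(corpus) == 0L) stop("cannot build a vocabulary from an empty corpus")
  token_lists <- lapply(corpus, split_tokens)
  content <- sort(unique(unlist(token_lists)), method = "radix")
  if (any(content %in% c(TOKEN_START, TOKEN_END, TOKEN_PAD)))
    stop("corpus contains reserved special-token characters")
  tokens <- c(content, TOKEN_START, TOKEN_END, TOKEN_PAD)
  longest <- max(lengths(token_lists)) + 2L  # + start and end
  vocab <- structure(
    list(tokens = tokens,
         start = length(content) + 1L,
         end = length(content) + 2L,
         pad = length(content) + 3L,
         max_sequence_length = if (is.null(max_length)) longest
                               else as.integer(max_length)),
    class = "token_vocabulary")
  if (vocab$max_sequence_length < longest)
    stop("max_length ", vocab$max_sequence_length,
         " is shorter than the longest tokenized sequence (", longest, ")")
  vocab
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat("Token vocabulary:", length(x$tokens), "tokens (",
      length(x$tokens) - 3L, "content + 3 special ), padded width",
      x$max_sequence_length, "\n")
  invisible(x)
}

#' Tokenize a SMILES string to padded index form
#'
#' Adds start/end tokens and pads to the vocabulary width.  Fails loudly on
#' out-of-vocabulary characters and over-length sequences.
#'
#' @param smiles a single SMILES string.
#' @param vocab a `token_vocabulary`.
#' @return integer vector of length `vocab$max_sequence_length` (1-based
#'   token indices) with attribute `n_tokens`, the count before padding.
#' @export
tokenize <- function(smiles, vocab) {
  toks <- split_tokens(smiles)
  idx <- match(toks, vocab$tokens)
  if (anyNA(idx)) {
    at <- which(is.na(idx))[1L]
    stop("out-of-vocabulary token '", toks[at], "' at token position ", at,
         " in '", smiles, "'")
  }
  n <- length(idx) + 2L
  if (n > vocab$max_sequence_length)
    stop("sequence of ", n, " tokens exceeds the padded width ",
         vocab$max_sequence_length)
  out <- c(vocab$start, idx, vocab$end,
           rep(vocab$pad, vocab$max_sequence_length - n))
  attr(out, "n_tokens") <- n
  out
}

#' Invert tokenization
#'
#' Drops start/pad tokens, truncates at the first end token and concatenates
#' the remaining tokens back into a SMILES string.
#'
#' @param indices integer vector of token indices.
#' @param vocab a `token_vocabulary`.
#' @return the SMILES string.
#' @export
detokenize <- function(indices, vocab) {
  end_at <- which(indices == vocab$end)[1L]
  if (!is.na(end_at)) indices <- indices[seq_len(end_at - 1L)]
  indices <- indices[indices != vocab$start & indices != vocab$pad]
  paste(vocab$tokens[indices], collapse = "")
}

#' Tokenize a corpus into an index matrix
#'
#' @param corpus character vector of SMILES.
#' @param vocab a `token_vocabulary`.
#' @return list with `tokens` (n x max_sequence_length integer matrix) and
#'   `lengths` (true token counts before padding).
#' @export
encode_corpus <- function(corpus, vocab) {
  rows <- lapply(corpus, tokenize, vocab = vocab)
  list(tokens = do.call(rbind, rows),
       lengths = vapply(rows, attr, 1L, "n_tokens"))
}

#' One-hot encode a token index sequence
#'
#' @param indices integer token indices (padded).
#' @param vocab a `token_vocabulary`.
#' @return a `length(indices)` x `length(vocab$tokens)` 0/1 matrix with one 1
#'   per row.
#' @export
one_hot <- function(indices, vocab) {
  m <- matrix(0, length(indices), length(vocab$tokens))
  m[cbind(seq_along(indices), indices)] <- 1
  m
}

#' Decode a probability matrix to a SMILES string
#'
#' Takes the row-wise argmax (first maximum on ties), truncates at the first
#' end token and never emits start/pad tokens.  Rows that do not sum to ~1
#' trigger a warning but are still decoded.
#'
#' @param probs numeric matrix (time steps x vocabulary size).
#' @param vocab a `token_vocabulary`.
#' @return the decoded SMILES string.
#' @export
decode_argmax <- function(probs, vocab) {
  probs <- as.matrix(probs)
  if (ncol(probs) != length(vocab$tokens))
    stop("probability matrix has ", ncol(probs), " columns; vocabulary has ",
         length(vocab$tokens), " tokens")
  if (any(abs(rowSums(probs) - 1) > 1e-6))
    warning("probability rows do not sum to 1; taking argmax anyway")
  detokenize(apply(probs, 1L, which.max), vocab)
}

#' Export / import a vocabulary as JSON
#'
#' Serialization round-trips bit-exactly (token order preserved).
#' @param vocab a `token_vocabulary`.
#' @param path file path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(tokens = as.character(x$tokens), start = as.integer(x$start),
                 end = as.integer(x$end), pad = as.integer(x$pad),
                 max_sequence_length = as.integer(x$max_sequence_length)),
            class = "token_vocabulary")
}
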