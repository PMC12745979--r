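# Tokenization and numeric encoding of compounds and sequences, exactly as
# the transformer consumes them.

# Atom-level SMILES tokenization pattern (Schwaller-style): bracket atoms,
# two-letter organic-subset halogens, aromatic/aliphatic atoms, bonds, ring
# closures including %nn, branches.
SMILES_TOKEN_REGEX <- "(\\[[^\\]]+]|Br?|Cl?|N|O|S|P|F|I|b|c|n|o|s|p|\\(|\\)|\\.|=|#|-|\\+|\\\\|\\/|:|~|@|\\?|>|\\*|\\$|%[0-9]{2}|[0-9])"

#' Tokenize a SMILES string
#'
#' Applies the atom-level regular expression left to right. Tokenization is
#' lossless: concatenating the returned tokens reproduces the input exactly.
#' Characters the pattern cannot consume raise an error naming the first
#' offending position.
#'
#' @param smiles a single SMILES string.
#' @return character vector of tokens.
#' @examples
#' \dontrun{
#' tokenize_smiles("c1ccccc1")
#' tokenize_smiles("CCl")  # c("C", "Cl"), not c("C", "C", "l")
#' }
#' @export
tokenize_smiles <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, !is.na(smiles))
  if (!nzchar(smiles)) return(character(0))
  m <- gregexpr(SMILES_TOKEN_REGEX, smiles, perl = TRUE)[[1]]
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  if (starts[1] == -1L) starts <- integer(0)
  # matches must tile the string contiguously from position 1
  expected <- 1L
  for (i in seq_along(starts)) {
    if (starts[i] != expected) {
      stop(sprintf("cannot tokenize SMILES %s at position %d (character '%s')",
                   sQuote(smiles), expected, substr(smiles, expected, expected)))
    }
    expected <- expected + lens[i]
  }
  if (expected != nchar(smiles) + 1L) {
    stop(sprintf("cannot tokenize SMILES %s at position %d (character '%s')",
                 sQuote(smiles), expected, substr(smiles, expected, expected)))
  }
  substring(smiles, starts, starts + lens - 1L)
}

# Special tokens occupy the first three indices of every vocabulary.
PAD_TOKEN <- "[pad]"; START_TOKEN <- "[start]"; END_TOKEN <- "[end]"

# The 20 standard IUPAC one-letter amino-acid codes.
IUPAC_AA <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

new_token_vocabulary <- function(content_tokens, max_length, kind) {
  stopifnot(!anyDuplicated(content_tokens),
            !any(c(PAD_TOKEN, START_TOKEN, END_TOKEN) %in% content_tokens))
  structure(list(
    tokens = c(PAD_TOKEN, START_TOKEN, END_TOKEN, content_tokens),
    pad = 1L, start = 2L, end = 3L,
    max_length = as.integer(max_length),
    kind = kind
  ), class = "token_vocabulary")
}

#' @export
print.token_vocabulary <- function(x, ...) {
  cat(sprintf("<token_vocabulary (%s): %d tokens (incl. 3 specials), max_length %d>\n",
              x$kind, length(x$tokens), x$max_length))
  invisible(x)
}

#' Build a SMILES token vocabulary from a corpus
#'
#' The vocabulary is corpus-derived: it holds exactly the tokens observed in
#' the given strings (sorted for determinism) plus the \code{[pad]},
#' \code{[start]} and \code{[end]} specials at fixed indices 1..3. Strings
#' containing tokens absent from the vocabulary later fail encoding; there
#' is no UNK token.
#'
#' @param corpus character vector of SMILES strings.
#' @param max_length maximum encoded length; default is the longest
#'   tokenized corpus item plus 2 (room for \code{[start]}/\code{[end]}).
#' @return a \code{token_vocabulary}.
#' @export
smiles_vocabulary <- function(corpus, max_length = NULL) {
  stopifnot(length(corpus) > 0)
  toks <- lapply(corpus, tokenize_smiles)
  if (is.null(max_length)) max_length <- max(lengths(toks)) + 2L
  new_token_vocabulary(sort(unique(unlist(toks))), max_length, "smiles")
}

#' Build the amino-acid vocabulary
#'
#' Fixed 20-letter IUPAC alphabet plus specials. Extended codes
#' (B, Z, X, U, O) are rejected by \code{encode_protein} unless the
#' vocabulary is built with \code{permissive = TRUE}, which adds X and maps
#' extended codes onto it.
#'
#' @param max_length maximum encoded residue length (pad target).
#' @param permissive add X and accept extended codes by mapping them to X.
#' @return a \code{token_vocabulary}.
#' @export
protein_vocabulary <- function(max_length, permissive = FALSE) {
  content <- IUPAC_AA
  if (permissive) content <- c(content, "X")
  v <- new_token_vocabulary(content, max_length, "protein")
  v$permissive <- permissive
  v
}

token_index <- function(vocab, tokens, what = "token") {
  idx <- match(tokens, vocab$tokens)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unknown %s %s at position %d", what, sQuote(tokens[bad]), bad))
  }
  idx
}

#' Encode a protein sequence as residue indices
#'
#' One index per residue (the one-hot rows of the encoder input), padded
#' with \code{[pad]} to the vocabulary's \code{max_length}. Inverse of
#' \code{decode_protein} up to padding.
#'
#' @param vocab protein \code{token_vocabulary}.
#' @param residues amino-acid string.
#' @return integer vector of length \code{vocab$max_length}.
#' @export
encode_protein <- function(vocab, residues) {
  stopifnot(inherits(vocab, "token_vocabulary"), vocab$kind == "protein")
  chars <- strsplit(residues, "")[[1]]
  if (isTRUE(vocab$permissive)) chars[chars %in% c("B", "Z", "U", "O")] <- "X"
  if (length(chars) > vocab$max_length) {
    stop(sprintf("sequence of %d residues exceeds max_length %d",
                 length(chars), vocab$max_length))
  }
  idx <- token_index(vocab, chars, "residue")
  c(idx, rep(vocab$pad, vocab$max_length - length(idx)))
}

#' @rdname encode_protein
#' @param indices integer vector produced by \code{encode_protein}.
#' @export
decode_protein <- function(vocab, indices) {
  stopifnot(vocab$kind == "protein")
  paste(vocab$tokens[indices[indices != vocab$pad]], collapse = "")
}

#' Encode a SMILES string as decoder token indices
#'
#' \code{[start]} + content tokens + \code{[end]}, padded to
#' \code{max_length}. Padding only ever follows \code{[end]}.
#'
#' @param vocab SMILES \code{token_vocabulary}.
#' @param smiles SMILES string.
#' @return integer vector of length \code{vocab$max_length}.
#' @export
encode_smiles <- function(vocab, smiles) {
  stopifnot(inherits(vocab, "token_vocabulary"), vocab$kind == "smiles")
  toks <- tokenize_smiles(smiles)
  if (length(toks) + 2L > vocab$max_length) {
    stop(sprintf("SMILES of %d tokens exceeds max_length %d", length(toks), vocab$max_length))
  }
  idx <- c(vocab$start, token_index(vocab, toks), vocab$end)
  c(idx, rep(vocab$pad, vocab$max_length - length(idx)))
}

#' @rdname encode_smiles
#' @param indices integer vector of token indices.
#' @export
decode_smiles <- function(vocab, indices) {
  stopifnot(vocab$kind == "smiles")
  keep <- !(indices %in% c(vocab$pad, vocab$start, vocab$end))
  paste(vocab$tokens[indices[keep]], collapse = "")
}

#' Sinusoidal positional encoding
#'
#' Fixed sin/cos encoding at geometrically spaced frequencies with base
#' 10,000: entry 2i is sin(position / 10000^(2i/d)) and entry 2i+1 the
#' matching cosine (i counted from 0).
#'
#' @param positions integer vector of 0-based positions.
#' @param dimension even model dimension.
#' @return matrix with one row per position and \code{dimension} columns.
#' @export
positional_encoding <- function(positions, dimension) {
  if (dimension %% 2 != 0) stop("positional encoding dimension must be even")
  i <- seq(0L, dimension - 2L, by = 2L)
  freq <- 1 / 10000^(i / dimension)
  arg <- outer(positions, freq)            # n x d/2
  pe <- matrix(0, length(positions), dimension)
  pe[, i + 1L] <- sin(arg)
  pe[, i + 2L] <- cos(arg)
  pe
}

#' Serialize a vocabulary to JSON
#'
#' @param vocab a \code{token_vocabulary}.
#' @param path output JSON path.
#' @export
write_vocabulary <- function(vocab, path) {
  jsonlite::write_json(unclass(vocab), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_vocabulary
#' @export
read_vocabulary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$pad <- as.integer(x$pad); x$start <- as.integer(x$start); x$end <- as.integer(x$end)
  x$max_length <- as.integer(x$max_length)
  structure(x, class = "token_vocabulary")
}
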