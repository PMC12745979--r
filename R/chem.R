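# Cheminformatics primitives, backed by RDKit through a batched helper
# process. Every function deduplicates its input so a call with 10,000
# sampled strings costs one subprocess round trip.

.chem_env <- new.env(parent = emptyenv())

.chem_python <- function() {
  if (!is.null(.chem_env$python)) return(.chem_env$python)
  py <- Sys.getenv("CLMPROBE_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) stop("no python interpreter found for the RDKit backend")
  .chem_env$python <- py
  py
}

.chem_script <- function() {
  path <- system.file("python", "chemtool.py", package = "clmprobe")
  if (!nzchar(path)) {
    # during development the package may be loaded from source
    path <- file.path("inst", "python", "chemtool.py")
  }
  if (!file.exists(path)) stop("chemtool.py helper not found")
  path
}

# One subprocess call for a unique set of SMILES; returns a data.frame with
# one column per op, rows aligned with `smiles`.
.chem_batch <- function(smiles, ops) {
  stopifnot(is.character(smiles), length(ops) >= 1)
  if (length(smiles) == 0) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(ops)), ops))
    return(out)
  }
  uniq <- unique(smiles)
  fin <- tempfile("chem_in_"); fout <- tempfile("chem_out_")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(uniq, fin)
  status <- system2(.chem_python(), c(shQuote(.chem_script()), shQuote(fin), shQuote(fout), ops),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0L || !file.exists(fout)) stop("RDKit helper process failed")
  lines <- readLines(fout)
  if (length(lines) != length(uniq)) stop("RDKit helper returned wrong row count")
  # split manually: rows for invalid molecules may be all-empty fields
  parts <- strsplit(lines, "\t", fixed = TRUE)
  res <- as.data.frame(setNames(lapply(seq_along(ops), function(j)
    vapply(parts, function(p) if (j <= length(p)) p[j] else "", character(1))),
    ops), stringsAsFactors = FALSE)
  res[match(smiles, uniq), , drop = FALSE]
}

#' Check SMILES validity
#'
#' A string is valid when RDKit can parse and sanitize it.
#'
#' @param smiles character vector of SMILES strings.
#' @return logical vector.
#' @export
smiles_is_valid <- function(smiles) {
  .chem_batch(smiles, "valid")$valid == "1"
}

#' Canonical nonisomeric SMILES
#'
#' Canonicalizes molecules to a unique nonisomeric form: stereochemistry
#' and isotope labels are dropped before writing the canonical string, so
#' \code{"C[C@@H](N)O"} and \code{"CC(N)O"} map to the same output.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict error on unparseable input (default) instead of returning NA.
#' @return character vector of canonical SMILES (NA for invalid input when
#'   \code{strict = FALSE}).
#' @export
canonical_smiles <- function(smiles, strict = TRUE) {
  out <- .chem_batch(smiles, "canonical")$canonical
  bad <- !nzchar(out) | !nzchar(smiles)
  if (any(bad)) {
    if (strict) {
      stop(sprintf("unparseable SMILES: %s",
                   paste(sQuote(utils::head(smiles[bad], 3)), collapse = ", ")))
    }
    out[bad] <- NA_character_
  }
  out
}

#' Average molecular weight
#'
#' Average (not monoisotopic) molecular weight including implicit
#' hydrogens, in Da.
#'
#' @param smiles character vector of SMILES strings.
#' @return numeric vector of masses in Da.
#' @export
molecular_weight <- function(smiles) {
  out <- .chem_batch(smiles, c("valid", "mw"))
  if (any(out$valid != "1")) {
    stop(sprintf("unparseable SMILES: %s",
                 paste(sQuote(utils::head(smiles[out$valid != "1"], 3)), collapse = ", ")))
  }
  as.numeric(out$mw)
}

#' Murcko scaffold
#'
#' Ring systems plus linkers with side chains removed, as canonical
#' nonisomeric SMILES. Acyclic molecules have no ring scaffold and fall
#' back to the molecule itself.
#'
#' @param smiles character vector of SMILES strings.
#' @param strict error on unparseable input (default) instead of NA.
#' @return character vector of scaffold SMILES.
#' @export
murcko_scaffold <- function(smiles, strict = TRUE) {
  out <- .chem_batch(smiles, "scaffold")$scaffold
  bad <- !nzchar(out) | !nzchar(smiles)
  if (any(bad)) {
    if (strict) stop("unparseable SMILES in scaffold extraction")
    out[bad] <- NA_character_
  }
  out
}

#' Morgan fingerprint on-bit indices
#'
#' Binary Morgan (circular) fingerprints with radius 2 hashed to 2,048
#' bits; returned as 0-based on-bit index vectors.
#'
#' @param smiles character vector of SMILES strings.
#' @return list of integer vectors (one per molecule).
#' @export
morgan_bits <- function(smiles) {
  out <- .chem_batch(smiles, c("valid", "morgan"))
  if (any(out$valid != "1")) stop("unparseable SMILES in fingerprint computation")
  lapply(strsplit(out$morgan, " ", fixed = TRUE), function(x) as.integer(x[nzchar(x)]))
}

# Validity + canonical form in one helper round trip; NA for invalid.
canonical_or_na <- function(smiles) {
  if (length(smiles) == 0) return(character(0))
  out <- .chem_batch(smiles, c("valid", "canonical"))
  ifelse(out$valid == "1" & nzchar(smiles), out$canonical, NA_character_)
}

.tanimoto_bits <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(1)  # two empty fingerprints (e.g. methane vs methane)
  length(intersect(a, b)) / u
}

#' Tanimoto similarity of Morgan fingerprints
#'
#' Computes |bits(a) AND bits(b)| / |bits(a) OR bits(b)| on 2,048-bit
#' radius-2 Morgan fingerprints.
#'
#' @param a,b SMILES strings (vectors are paired elementwise, recycling
#'   the shorter).
#' @return numeric vector of similarities in [0, 1].
#' @export
morgan_tanimoto <- function(a, b) {
  n <- max(length(a), length(b))
  a <- rep_len(a, n); b <- rep_len(b, n)
  bits <- morgan_bits(c(a, b))
  vapply(seq_len(n), function(i) .tanimoto_bits(bits[[i]], bits[[n + i]]), numeric(1))
}
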