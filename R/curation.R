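# Record-level curation of ChEMBL-style activity tables and construction
# of the deduplicated sequence-compound pair dataset.

#' Construct a pair dataset
#'
#' The central data container: unique (sequence, compound) pairs with the
#' sequence metadata needed downstream. Compound strings are expected in
#' canonical nonisomeric form (as produced by \code{build_pairs} or
#' \code{as_pair_dataset}).
#'
#' @param pairs data.frame with columns \code{sequence_id}, \code{smiles}.
#' @param sequences data.frame with columns \code{sequence_id},
#'   \code{family}, \code{residues}.
#' @return a \code{pair_dataset}.
#' @export
pair_dataset <- function(pairs, sequences) {
  stopifnot(all(c("sequence_id", "smiles") %in% names(pairs)),
            all(c("sequence_id", "family", "residues") %in% names(sequences)))
  pairs <- unique(pairs[c("sequence_id", "smiles")])
  if (!all(pairs$sequence_id %in% sequences$sequence_id))
    stop("pairs reference sequences missing from the metadata table")
  sequences <- sequences[sequences$sequence_id %in% pairs$sequence_id, , drop = FALSE]
  rownames(pairs) <- rownames(sequences) <- NULL
  structure(list(pairs = pairs, sequences = sequences), class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  m <- compound_multiplicity(x)
  cat(sprintf("<pair_dataset: %d pairs, %d sequences, %d unique compounds (%.1f%% MT)>\n",
              nrow(x$pairs), nrow(x$sequences), length(m),
              100 * mean(m >= 2)))
  invisible(x)
}

#' @export
summary.pair_dataset <- function(object, ...) {
  m <- compound_multiplicity(object)
  out <- list(n_pairs = nrow(object$pairs),
              n_sequences = nrow(object$sequences),
              n_compounds = length(m),
              n_families = length(unique(object$sequences$family)),
              mt_fraction = mean(m >= 2),
              mean_multiplicity = mean(m),
              mt_mean_multiplicity = if (any(m >= 2)) mean(m[m >= 2]) else NA_real_)
  class(out) <- "summary.pair_dataset"
  out
}

#' @export
print.summary.pair_dataset <- function(x, ...) {
  cat(sprintf(paste0("pair dataset: %d pairs | %d sequences in %d families | ",
                     "%d unique compounds\n",
                     "mean targets per compound %.2f | MT fraction %.3f | ",
                     "mean multiplicity of MT compounds %.2f\n"),
              x$n_pairs, x$n_sequences, x$n_families, x$n_compounds,
              x$mean_multiplicity, x$mt_fraction, x$mt_mean_multiplicity))
  invisible(x)
}

#' Per-compound target multiplicity
#'
#' Number of distinct sequences each unique compound is paired with.
#' Compounds with multiplicity 2 or more are the MT compounds.
#'
#' @param dataset a \code{pair_dataset}.
#' @return named integer vector (names are canonical SMILES).
#' @export
compound_multiplicity <- function(dataset) {
  tab <- table(dataset$pairs$smiles)
  out <- as.integer(tab); names(out) <- names(tab)
  out
}

#' @rdname compound_multiplicity
#' @export
mt_compounds <- function(dataset) {
  m <- compound_multiplicity(dataset)
  names(m)[m >= 2]
}

#' Convert a synthetic universe to a pair dataset
#'
#' @param universe a \code{synthetic_universe}.
#' @return a \code{pair_dataset} (compound strings are the universe's
#'   canonical SMILES).
#' @export
as_pair_dataset <- function(universe) {
  stopifnot(inherits(universe, "synthetic_universe"))
  pairs <- data.frame(
    sequence_id = universe$pairs$sequence_id,
    smiles = universe$compounds$smiles[match(universe$pairs$compound_id,
                                             universe$compounds$compound_id)],
    stringsAsFactors = FALSE)
  pair_dataset(pairs, universe$sequences)
}

#' Read a ChEMBL-style activity record table
#'
#' TSV with header \code{compound_smiles}, \code{target_id},
#' \code{activity_value_nm}, \code{confidence_score}, \code{direct_binding},
#' \code{excluded_by_public_filters}.
#'
#' @param path TSV path.
#' @return data.frame of activity records.
#' @export
read_activity_records <- function(path) {
  rec <- utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                           comment.char = "", stringsAsFactors = FALSE)
  needed <- c("compound_smiles", "target_id", "activity_value_nm",
              "confidence_score", "direct_binding", "excluded_by_public_filters")
  missing <- setdiff(needed, names(rec))
  if (length(missing)) stop("activity table lacks columns: ", paste(missing, collapse = ", "))
  rec$direct_binding <- as.logical(rec$direct_binding)
  rec$excluded_by_public_filters <- as.logical(rec$excluded_by_public_filters)
  rec
}

#' Filter activity records
#'
#' Applies the record-level curation rules: assay confidence score 9,
#' direct binding, not flagged by the public anti-target/interference/
#' aggregator filters, compound molecular weight at most 1,000 Da, target
#' sequence length at most 1,000 residues. Then, per (compound, target)
#' group with two or more activity values, the whole group is dropped when
#' its values do not fall into the same order of magnitude.
#'
#' @param records activity record data.frame (see
#'   \code{\link{read_activity_records}}).
#' @param sequences named character vector or data.frame mapping
#'   \code{target_id} to residue strings.
#' @param magnitude_rule "ratio" (default): a group spans one order of
#'   magnitude when max/min is at most 10; "log10": all values share the
#'   same floor(log10) bin.
#' @return filtered records (same columns, subset of rows). Records
#'   referencing unknown targets are dropped with a warning.
#' @export
filter_records <- function(records, sequences,
                           magnitude_rule = c("ratio", "log10")) {
  magnitude_rule <- match.arg(magnitude_rule)
  if (is.data.frame(sequences)) {
    sequences <- setNames(sequences$residues, sequences$sequence_id)
  }
  unknown <- !(records$target_id %in% names(sequences))
  if (any(unknown)) {
    warning(sprintf("dropping %d records referencing unknown targets", sum(unknown)))
    records <- records[!unknown, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)

  parseable <- smiles_is_valid(records$compound_smiles)
  if (any(!parseable)) {
    warning(sprintf("dropping %d records with unparseable SMILES", sum(!parseable)))
    records <- records[parseable, , drop = FALSE]
  }
  if (nrow(records) == 0) return(records)

  keep <- records$confidence_score == 9 &
    records$direct_binding &
    !records$excluded_by_public_filters &
    molecular_weight(records$compound_smiles) <= 1000 &
    nchar(sequences[records$target_id]) <= 1000
  records <- records[keep, , drop = FALSE]
  if (nrow(records) == 0) return(records)

  # order-of-magnitude consistency per (compound, target) group, on
  # canonical compound identity
  canon <- canonical_smiles(records$compound_smiles)
  grp <- paste(canon, records$target_id, sep = "\r")
  vals <- split(records$activity_value_nm, grp)
  bad_grp <- vapply(vals, function(v) {
    v <- v[!is.na(v)]
    if (length(v) < 2) return(FALSE)
    if (magnitude_rule == "ratio") max(v) / min(v) > 10
    else length(unique(floor(log10(v)))) > 1
  }, logical(1))
  records <- records[!bad_grp[grp], , drop = FALSE]
  rownames(records) <- NULL
  records
}

#' Build the deduplicated pair dataset from filtered records
#'
#' Canonicalizes compounds to nonisomeric form, collapses duplicate
#' (sequence, compound) pairs, and records per-compound multiplicity.
#'
#' @param records filtered activity records.
#' @param sequences data.frame with \code{sequence_id}, \code{family},
#'   \code{residues} (a \code{family} of NA is allowed when family labels
#'   are unknown).
#' @return a \code{pair_dataset}.
#' @export
build_pairs <- function(records, sequences) {
  if (!is.data.frame(sequences)) {
    sequences <- data.frame(sequence_id = names(sequences), family = NA_character_,
                            residues = unname(sequences), stringsAsFactors = FALSE)
  }
  pairs <- data.frame(sequence_id = records$target_id,
                      smiles = canonical_smiles(records$compound_smiles),
                      stringsAsFactors = FALSE)
  pair_dataset(pairs, sequences)
}

#' Write a pair dataset and its JSON summary
#'
#' @param dataset a \code{pair_dataset}.
#' @param path output TSV path (columns sequence_id, canonical_smiles,
#'   multiplicity); a JSON summary is written next to it.
#' @export
write_pair_dataset <- function(dataset, path) {
  m <- compound_multiplicity(dataset)
  out <- data.frame(sequence_id = dataset$pairs$sequence_id,
                    canonical_smiles = dataset$pairs$smiles,
                    multiplicity = as.integer(m[dataset$pairs$smiles]))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- summary(dataset)
  jsonlite::write_json(unclass(s), paste0(tools::file_path_sans_ext(path), "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
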