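# Train/test partitioning (by sequence or by protein family) and the
# multi-target dilution series.

#' Describe a train/test split
#'
#' @param scheme "sequence" or "family".
#' @param train_fraction fraction of data assigned to training (0.7 as in
#'   the 70\%/30\% design).
#' @param seed integer seed.
#' @return a \code{split_plan}.
#' @export
split_plan <- function(scheme = c("sequence", "family"), train_fraction = 0.7,
                       seed = 1) {
  scheme <- match.arg(scheme)
  if (train_fraction <= 0 || train_fraction >= 1)
    stop("train_fraction must lie strictly between 0 and 1")
  structure(list(scheme = scheme, train_fraction = train_fraction,
                 seed = as.integer(seed)), class = "split_plan")
}

.split_result <- function(dataset, train_ids, plan, by = "sequence_id") {
  keep <- dataset$sequences[[by]] %in% train_ids
  train_seq <- dataset$sequences$sequence_id[keep]
  tr_pairs <- dataset$pairs[dataset$pairs$sequence_id %in% train_seq, , drop = FALSE]
  te_pairs <- dataset$pairs[!(dataset$pairs$sequence_id %in% train_seq), , drop = FALSE]
  train <- pair_dataset(tr_pairs, dataset$sequences)
  test <- pair_dataset(te_pairs, dataset$sequences)
  manifest <- list(scheme = plan$scheme, seed = plan$seed,
                   train_fraction = plan$train_fraction,
                   n_train_pairs = nrow(train$pairs), n_test_pairs = nrow(test$pairs),
                   n_train_sequences = nrow(train$sequences),
                   n_test_sequences = nrow(test$sequences),
                   mt_overlap = length(intersect(unique(train$pairs$smiles),
                                                 unique(test$pairs$smiles))))
  attr(train, "manifest") <- attr(test, "manifest") <- manifest
  list(train = train, test = test, manifest = manifest)
}

#' Sequence-based partitioning
#'
#' Sequences (with all their pairs) are divided at random:
#' round(train_fraction x n) sequences form the training side. Sequence id
#' sets are disjoint between sides, but an MT compound may appear on both
#' sides through different sequences — the leakage channel under study.
#'
#' @param dataset a \code{pair_dataset}.
#' @param plan a \code{split_plan} with scheme "sequence".
#' @return list with \code{train}, \code{test} (pair_datasets) and
#'   \code{manifest}.
#' @export
split_by_sequence <- function(dataset, plan) {
  stopifnot(inherits(dataset, "pair_dataset"), plan$scheme == "sequence")
  ids <- sort(unique(dataset$sequences$sequence_id))
  if (length(ids) < 2) stop("sequence split needs at least 2 sequences")
  n_train <- round(plan$train_fraction * length(ids))
  n_train <- min(max(n_train, 1L), length(ids) - 1L)
  train_ids <- with_seed(plan$seed, sample(ids, n_train))
  .split_result(dataset, train_ids, plan)
}

# Exact closest-subset packing of family pair counts toward `target`;
# tie-break: fewer train families, then lexicographically first id set.
.family_pack_exhaustive <- function(counts, target) {
  fams <- names(counts)
  best <- NULL
  for (mask in 1:(2^length(fams) - 2)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_along(fams) - 1)))
    tot <- sum(counts[sel])
    cand <- list(dist = abs(tot - target), k = sum(sel), ids = sort(fams[sel]))
    if (is.null(best) || cand$dist < best$dist ||
        (cand$dist == best$dist && (cand$k < best$k ||
          (cand$k == best$k && paste(cand$ids, collapse = ",") <
                               paste(best$ids, collapse = ","))))) {
      best <- cand
    }
  }
  best$ids
}

# Greedy descending packing used beyond the exact-search size limit.
.family_pack_greedy <- function(counts, target) {
  ord <- order(-counts, names(counts))
  train <- character(0); tot <- 0
  for (i in ord) {
    if (abs(tot + counts[i] - target) <= abs(tot - target)) {
      train <- c(train, names(counts)[i]); tot <- tot + counts[i]
    }
  }
  if (length(train) == 0) train <- names(counts)[ord[1]]
  if (length(train) == length(counts)) train <- train[-length(train)]
  sort(train)
}

#' Family-based partitioning
#'
#' Whole protein families are assigned to one side; the training side's
#' pair count is packed as close to the target fraction as whole families
#' allow (exact subset search up to 12 families, greedy above), yielding
#' non-overlapping training and test sets at family granularity.
#'
#' @param dataset a \code{pair_dataset}; every sequence needs a family label.
#' @param plan a \code{split_plan} with scheme "family".
#' @return list with \code{train}, \code{test}, \code{manifest}.
#' @export
split_by_family <- function(dataset, plan) {
  stopifnot(inherits(dataset, "pair_dataset"), plan$scheme == "family")
  fam <- dataset$sequences$family
  if (anyNA(fam)) stop("family split requires a family label on every sequence")
  fam_of_pair <- fam[match(dataset$pairs$sequence_id, dataset$sequences$sequence_id)]
  counts <- table(fam_of_pair)
  if (length(counts) < 2) stop("family split needs at least 2 families")
  counts <- setNames(as.numeric(counts), names(counts))
  target <- plan$train_fraction * sum(counts)
  train_fams <- if (length(counts) <= 12) .family_pack_exhaustive(counts, target)
                else .family_pack_greedy(counts, target)
  train_ids <- dataset$sequences$sequence_id[fam %in% train_fams]
  out <- .split_result(dataset, train_ids, plan)
  out$manifest$train_families <- train_fams
  out
}

#' Multi-target dilution
#'
#' Converts a fraction (1 - retain) of the MT compounds into single-target
#' compounds: for each selected compound one pair is kept (chosen uniformly
#' at random) and all others are removed. Selection order and kept pairs
#' are derived from the seed alone, so conversion sets are nested across
#' retain levels: every compound converted at retain 0.75 is also converted
#' at 0.5, 0.25 and 0. At retain 0 every compound has multiplicity 1.
#' Single-target pairs are never touched.
#'
#' @param dataset a \code{pair_dataset}.
#' @param retain fraction of MT compounds keeping their full multiplicity,
#'   in [0, 1].
#' @param seed integer seed owning the conversion order and kept-pair draws.
#' @return a diluted \code{pair_dataset}.
#' @export
dilute_mt <- function(dataset, retain, seed = 1) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (retain < 0 || retain > 1) stop("retain must lie in [0, 1]")
  if (retain == 1) return(dataset)
  mt <- sort(mt_compounds(dataset))
  if (length(mt) == 0) return(dataset)
  plan <- with_seed(seed, {
    order_mt <- sample(mt)
    kept <- vapply(order_mt, function(cmp) {
      rows <- which(dataset$pairs$smiles == cmp)
      rows[sample.int(length(rows), 1)]
    }, integer(1))
    list(order_mt = order_mt, kept = kept)
  })
  n_convert <- round((1 - retain) * length(mt))
  if (n_convert == 0) return(dataset)
  convert <- plan$order_mt[seq_len(n_convert)]
  kept_rows <- plan$kept[seq_len(n_convert)]
  drop <- which(dataset$pairs$smiles %in% convert)
  drop <- setdiff(drop, kept_rows)
  out <- pair_dataset(dataset$pairs[-drop, , drop = FALSE], dataset$sequences)
  attr(out, "dilution") <- list(retain = retain, seed = seed,
                                n_mt = length(mt), n_converted = n_convert)
  out
}

#' Dilution schedule
#'
#' Validates and returns the ordered retain levels used for the dilution
#' series (default 1.0, 0.75, 0.5, 0.25, 0.0).
#'
#' @param retain_levels strictly decreasing fractions starting at 1.0.
#' @param seed integer seed shared across levels (nesting guarantee).
#' @return list with \code{retain_levels} and \code{seed}.
#' @export
dilution_schedule <- function(retain_levels = c(1, 0.75, 0.5, 0.25, 0), seed = 1) {
  if (retain_levels[1] != 1) stop("the first retain level must be 1.0")
  if (any(diff(retain_levels) >= 0)) stop("retain levels must be strictly decreasing")
  if (any(retain_levels < 0 | retain_levels > 1)) stop("retain levels must lie in [0, 1]")
  list(retain_levels = retain_levels, seed = as.integer(seed))
}

#' Write split manifest and side TSVs
#'
#' @param split result of \code{split_by_sequence} or \code{split_by_family}.
#' @param dir output directory.
#' @export
write_split <- function(split, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_pair_dataset(split$train, file.path(dir, "train_pairs.tsv"))
  write_pair_dataset(split$test, file.path(dir, "test_pairs.tsv"))
  jsonlite::write_json(split$manifest, file.path(dir, "split_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
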