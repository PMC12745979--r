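# Sampling-based evaluation: exact compound/core reproduction counts,
# memorization fraction, and nearest-neighbor similarity.

#' Count exactly reproduced test compounds
#'
#' Canonicalizes every valid sampled string and counts the distinct
#' members of the test-compound set that occur among them. Invalid strings
#' are ignored; duplicates count once; sample order is irrelevant.
#'
#' @param samples a \code{sample_set} (from \code{\link{clm_sample}}) or a
#'   character vector of canonical SMILES.
#' @param test_compounds character vector of canonical nonisomeric SMILES.
#' @return integer count.
#' @export
count_reproduced <- function(samples, test_compounds) {
  got <- if (inherits(samples, "sample_set")) samples$valid_canonical else samples
  length(intersect(unique(got), unique(test_compounds)))
}

#' Extract core structures
#'
#' Maps each compound to its core via Murcko scaffold extraction (ring
#' systems plus linkers, side chains removed); all members of one analog
#' series share a core by construction of the synthetic grammar. Acyclic
#' compounds fall back to the molecule itself as their core. Unparseable
#' strings are skipped with a warning.
#'
#' @param compounds character vector of SMILES.
#' @return named character vector mapping compound to core SMILES
#'   (unparseable compounds are absent).
#' @export
extract_cores <- function(compounds) {
  compounds <- unique(compounds)
  if (length(compounds) == 0) return(setNames(character(0), character(0)))
  cores <- murcko_scaffold(compounds, strict = FALSE)
  if (anyNA(cores)) {
    warning(sprintf("skipping %d unparseable compounds in core extraction", sum(is.na(cores))))
  }
  setNames(cores, compounds)[!is.na(cores)]
}

#' Memorization analysis of reproduced compounds
#'
#' The memorization fraction is the share of reproduced compounds present
#' verbatim (canonical string identity) among the training-pair compounds.
#' Each reproduced compound is also assigned its nearest training neighbor
#' by Morgan/Tanimoto similarity and the mean is reported. An empty
#' reproduced set yields both statistics as NA (absent), not 0.
#'
#' @param reproduced character vector of reproduced canonical SMILES.
#' @param training character vector of training-pair canonical SMILES.
#' @return list with \code{fraction_in_training},
#'   \code{mean_nn_tanimoto}, \code{n_reproduced}.
#' @export
memorization_analysis <- function(reproduced, training) {
  reproduced <- unique(reproduced); training <- unique(training)
  if (length(reproduced) == 0) {
    return(list(fraction_in_training = NA_real_, mean_nn_tanimoto = NA_real_,
                n_reproduced = 0L))
  }
  if (length(training) == 0) stop("memorization analysis needs a non-empty training set")
  frac <- mean(reproduced %in% training)
  bits <- morgan_bits(c(reproduced, training))
  rb <- bits[seq_along(reproduced)]
  tb <- bits[-seq_along(reproduced)]
  nn <- vapply(rb, function(b) {
    max(vapply(tb, function(tbi) .tanimoto_bits(b, tbi), numeric(1)))
  }, numeric(1))
  list(fraction_in_training = frac, mean_nn_tanimoto = mean(nn),
       n_reproduced = length(reproduced))
}

#' Per-sequence reproduction report
#'
#' For each test sequence with more than \code{min_compounds} available
#' test compounds, samples \code{n} strings and reports the number of
#' unique exactly reproduced test compounds and cores, plus memorization
#' statistics against the training compounds.
#'
#' @param state a \code{clm_model}.
#' @param test a test-side \code{pair_dataset}.
#' @param train the matching training-side \code{pair_dataset} (for
#'   memorization statistics).
#' @param n samples per sequence (2,500 default).
#' @param temperature sampling temperature.
#' @param min_compounds inclusion threshold: only sequences with more than
#'   this many available test compounds are evaluated (20 by default;
#'   set to 0 to evaluate all).
#' @param seed integer seed (per-sequence seeds are derived from it).
#' @param sequences optional character vector restricting which test
#'   sequences to evaluate (intersected with the threshold rule).
#' @return a \code{reproduction_report}: data.frame with one row per
#'   evaluated sequence (\code{sequence_id}, \code{n_test_compounds},
#'   \code{n_uq_repro_compounds}, \code{n_uq_repro_cores},
#'   \code{validity_rate}, \code{memorization_fraction},
#'   \code{mean_nn_tanimoto}).
#' @export
reproduction_report <- function(state, test, train, n = 2500, temperature = 1,
                                min_compounds = 20, seed = 1, sequences = NULL) {
  stopifnot(inherits(test, "pair_dataset"), inherits(train, "pair_dataset"))
  counts <- table(test$pairs$sequence_id)
  eligible <- names(counts)[counts > min_compounds]
  if (!is.null(sequences)) eligible <- intersect(eligible, sequences)
  if (length(eligible) == 0) {
    warning("no test sequence passes the availability threshold")
    out <- data.frame(sequence_id = character(0), n_test_compounds = integer(0),
                      n_uq_repro_compounds = integer(0), n_uq_repro_cores = integer(0),
                      validity_rate = numeric(0), memorization_fraction = numeric(0),
                      mean_nn_tanimoto = numeric(0))
    class(out) <- c("reproduction_report", "data.frame")
    return(out)
  }
  train_cpds <- unique(train$pairs$smiles)
  rows <- lapply(eligible, function(sid) {
    res <- test$sequences$residues[match(sid, test$sequences$sequence_id)]
    test_cpds <- unique(test$pairs$smiles[test$pairs$sequence_id == sid])
    ss <- clm_sample(state, res, n = n, temperature = temperature,
                     seed = derive_seed(seed, sid))
    got <- unique(ss$valid_canonical)
    repro <- intersect(got, test_cpds)
    core_map <- extract_cores(test_cpds)
    got_cores <- unique(unname(extract_cores(got)))
    mem <- memorization_analysis(repro, train_cpds)
    data.frame(sequence_id = sid,
               n_test_compounds = length(test_cpds),
               n_uq_repro_compounds = length(repro),
               n_uq_repro_cores = length(intersect(got_cores, unique(unname(core_map)))),
               validity_rate = ss$validity_rate,
               memorization_fraction = mem$fraction_in_training,
               mean_nn_tanimoto = mem$mean_nn_tanimoto,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("reproduction_report", "data.frame")
  attr(out, "params") <- list(n = n, temperature = temperature,
                              min_compounds = min_compounds, seed = seed)
  out
}

#' @export
print.reproduction_report <- function(x, ...) {
  p <- attr(x, "params")
  cat(sprintf("reproduction report (%d sequences, %d samples each, T=%g):\n",
              nrow(x), p$n, p$temperature))
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Write a reproduction report
#'
#' TSV with one row per test sequence plus a JSON summary of totals.
#'
#' @param report a \code{reproduction_report}.
#' @param path output TSV path.
#' @export
write_reproduction_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  s <- list(n_sequences = nrow(report),
            total_repro_compounds = sum(report$n_uq_repro_compounds),
            total_repro_cores = sum(report$n_uq_repro_cores),
            mean_repro_compounds = mean(report$n_uq_repro_compounds),
            mean_repro_cores = mean(report$n_uq_repro_cores))
  jsonlite::write_json(s, paste0(tools::file_path_sans_ext(path), "_summary.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}
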