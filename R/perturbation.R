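# Sequence-modification protocols: frequency-weighted randomization,
# cumulative terminal randomization with positional controls, motif
# masking by randomization or computational alanine scanning.

#' Residue frequencies of a sequence corpus
#'
#' Relative frequency of occurrence of each amino acid over all positions
#' of all sequences; the sampling distribution used by every
#' randomization protocol.
#'
#' @param sequences character vector of residue strings (or a
#'   \code{pair_dataset}, whose sequence table is used).
#' @return named numeric vector over the observed residues, summing to 1.
#' @export
residue_frequencies <- function(sequences) {
  if (inherits(sequences, "pair_dataset")) sequences <- sequences$sequences$residues
  stopifnot(length(sequences) > 0, all(nzchar(sequences)))
  tab <- table(strsplit(paste(sequences, collapse = ""), "")[[1]])
  out <- as.numeric(tab) / sum(tab)
  names(out) <- names(tab)
  out
}

#' Randomize selected positions of a sequence
#'
#' Listed positions are independently resampled from the given residue
#' frequencies. Positions are "targeted", not "changed": the drawn residue
#' may equal the original (with probability equal to that residue's
#' frequency), matching frequency-weighted replacement. All other
#' positions, and the length, are untouched.
#'
#' @param sequence residue string.
#' @param positions integer vector of 1-based positions.
#' @param freqs named frequencies from \code{\link{residue_frequencies}}.
#' @param seed optional seed; by default the ambient RNG stream is used so
#'   callers can manage reproducibility at a higher level.
#' @return modified residue string.
#' @export
randomize_positions <- function(sequence, positions, freqs, seed = NULL) {
  L <- nchar(sequence)
  if (length(positions) == 0) return(sequence)
  if (any(positions < 1 | positions > L)) stop("position out of sequence range")
  draw <- function() sample(names(freqs), length(positions), replace = TRUE, prob = freqs)
  repl <- if (is.null(seed)) draw() else with_seed(seed, draw())
  chars <- strsplit(sequence, "")[[1]]
  chars[positions] <- repl
  paste(chars, collapse = "")
}

#' Cumulative terminal randomization variants
#'
#' Starting from the N terminus (or the C terminus), the first (last)
#' \code{segment} residues are randomized, then the next \code{segment},
#' and so on until the entire sequence is randomized. Variant k extends
#' variant k-1: earlier draws are kept and only the new segment is
#' resampled. The last segment may be shorter when the length is not a
#' multiple of \code{segment}.
#'
#' @param sequence residue string.
#' @param direction "n_to_c" or "c_to_n".
#' @param segment segment size in residues (15 by default).
#' @param freqs residue frequencies.
#' @param seed optional seed for the whole cumulative trajectory.
#' @return list with \code{variants} (character vector, one per step) and
#'   \code{n_randomized} (targeted position counts, strictly increasing to
#'   the sequence length).
#' @export
cumulative_variants <- function(sequence, direction = c("n_to_c", "c_to_n"),
                                segment = 15, freqs, seed = NULL) {
  direction <- match.arg(direction)
  stopifnot(segment >= 1)
  segment <- as.integer(segment)
  L <- nchar(sequence)
  steps <- as.integer(ceiling(L / segment))
  build <- function() {
    out <- character(steps)
    cur <- sequence
    for (k in seq_len(steps)) {
      upto <- min(k * segment, L)
      new_pos <- if (direction == "n_to_c") {
        ((k - 1) * segment + 1):upto
      } else {
        (L - upto + 1):(L - (k - 1) * segment)
      }
      cur <- randomize_positions(cur, new_pos, freqs)
      out[k] <- cur
    }
    out
  }
  variants <- if (is.null(seed)) build() else with_seed(seed, build())
  list(variants = variants, n_randomized = pmin(seq_len(steps) * segment, L))
}

#' Positional-control variants
#'
#' For each requested count c, targets c distinct positions selected
#' uniformly across the entire sequence and randomizes them. Position sets
#' are drawn fresh at each count (not cumulative), matching the
#' per-iteration control design.
#'
#' @param sequence residue string.
#' @param counts integer vector of targeted-position counts.
#' @param freqs residue frequencies.
#' @param seed optional seed.
#' @return character vector of variants, one per count.
#' @export
control_variants <- function(sequence, counts, freqs, seed = NULL) {
  L <- nchar(sequence)
  if (any(counts < 0 | counts > L)) stop("control count exceeds sequence length")
  build <- function() {
    vapply(counts, function(cc) {
      pos <- sample.int(L, cc)
      randomize_positions(sequence, pos, freqs)
    }, character(1))
  }
  if (is.null(seed)) build() else with_seed(seed, build())
}

.ranges_to_positions <- function(ranges, L) {
  if (is.numeric(ranges) && length(ranges) == 2) ranges <- list(ranges)
  if (is.matrix(ranges)) ranges <- lapply(seq_len(nrow(ranges)), function(i) ranges[i, ])
  pos <- unlist(lapply(ranges, function(r) {
    if (r[1] < 1 || r[2] > L || r[1] > r[2]) stop("motif range outside sequence")
    r[1]:r[2]
  }))
  if (anyDuplicated(pos)) {
    warning("overlapping motif ranges merged")
    pos <- unique(pos)
  }
  sort(pos)
}

#' Mask sequence motifs
#'
#' Replaces the residues of the given 1-based inclusive motif ranges
#' either with frequency-weighted random draws ("randomize") or uniformly
#' with alanine ("alanine"); everything else is untouched. Overlapping
#' ranges are merged with a warning.
#'
#' @param sequence residue string.
#' @param ranges list of c(start, end) vectors (or a single range, or a
#'   two-column matrix).
#' @param mode "randomize" or "alanine".
#' @param freqs residue frequencies (randomize mode only).
#' @param seed optional seed (randomize mode only).
#' @return modified residue string.
#' @export
mask_motif <- function(sequence, ranges, mode = c("randomize", "alanine"),
                       freqs = NULL, seed = NULL) {
  mode <- match.arg(mode)
  pos <- .ranges_to_positions(ranges, nchar(sequence))
  if (mode == "alanine") {
    chars <- strsplit(sequence, "")[[1]]
    chars[pos] <- "A"
    paste(chars, collapse = "")
  } else {
    if (is.null(freqs)) stop("randomize mode needs residue frequencies")
    randomize_positions(sequence, pos, freqs, seed = seed)
  }
}

.PERTURBATION_KINDS <- c("cumulative_n_to_c", "cumulative_c_to_n",
                         "cumulative_random_control",
                         "motif_randomize", "motif_alanine",
                         "motif_random_control_randomize",
                         "motif_random_control_alanine",
                         "full_randomization")

#' Declare a perturbation experiment
#'
#' @param kind one of the cumulative, motif-masking, control or full
#'   randomization protocols.
#' @param segment_size residues per cumulative segment (15 by default).
#' @param motif_ranges list of 1-based inclusive ranges (motif kinds).
#' @param repeats independent repetitions: 5 for cumulative protocols, 10
#'   for motif masking and its controls (the defaults adapt to the kind).
#' @param n_samples strings sampled per variant (5,000 by default).
#' @param temperature sampling temperature.
#' @param seed integer seed; every variant draw and sampling run derives
#'   its own stream from it.
#' @return a \code{perturbation_plan}.
#' @export
perturbation_plan <- function(kind = .PERTURBATION_KINDS, segment_size = 15,
                              motif_ranges = NULL, repeats = NULL,
                              n_samples = 5000, temperature = 1, seed = 1) {
  kind <- match.arg(kind)
  if (is.null(repeats)) {
    repeats <- if (startsWith(kind, "cumulative")) 5L else 10L
  }
  if (segment_size < 1) stop("segment_size must be at least 1")
  if (repeats < 1) stop("repeats must be at least 1")
  if (startsWith(kind, "motif") && is.null(motif_ranges))
    stop("motif kinds need motif_ranges")
  structure(list(kind = kind, segment_size = as.integer(segment_size),
                 motif_ranges = motif_ranges, repeats = as.integer(repeats),
                 n_samples = as.integer(n_samples), temperature = temperature,
                 seed = as.integer(seed)),
            class = "perturbation_plan")
}

# Two-phase evaluation of many variants: decode all sampling runs first,
# then canonicalize every distinct raw string in one cheminformatics
# round trip (one subprocess call instead of one per run).
.count_variants <- function(state, variants, labels, test_compounds, plan) {
  raws <- lapply(seq_along(variants), function(i)
    clm_sample(state, variants[[i]], n = plan$n_samples,
               temperature = plan$temperature,
               seed = derive_seed(plan$seed, labels[[i]]),
               canonicalize = FALSE)$raw)
  uniq <- unique(unlist(raws))
  canon <- canonical_or_na(uniq)
  lookup <- setNames(canon, uniq)
  test_compounds <- unique(test_compounds)
  vapply(raws, function(r) {
    got <- lookup[unique(r)]
    length(intersect(got[!is.na(got)], test_compounds))
  }, integer(1))
}

#' Run a perturbation experiment against a trained model
#'
#' For each sequence variant prescribed by the plan (and each repeat), the
#' model samples \code{n_samples} strings and the number of unique exactly
#' reproduced test compounds is recorded. Cumulative plans return a
#' \code{perturbation_curve} (step 0 is the unperturbed sequence); motif
#' and full-randomization plans return per-trial count distributions ready
#' for the Mann-Whitney comparison.
#'
#' @param state a \code{clm_model}.
#' @param residues the test sequence (residue string).
#' @param test_compounds canonical SMILES available for this sequence.
#' @param plan a \code{perturbation_plan}.
#' @param freqs residue frequencies of the training corpus.
#' @return data.frame: cumulative kinds give columns \code{step},
#'   \code{n_residues_randomized}, \code{rep}, \code{count} (class
#'   \code{perturbation_curve}); other kinds give \code{trial},
#'   \code{count}.
#' @export
run_experiment <- function(state, residues, test_compounds, plan, freqs) {
  stopifnot(inherits(plan, "perturbation_plan"))
  L <- nchar(residues)
  if (!is.null(plan$motif_ranges)) .ranges_to_positions(plan$motif_ranges, L)
  kind <- plan$kind

  if (startsWith(kind, "cumulative")) {
    rows <- list()
    for (r in seq_len(plan$repeats)) {
      if (kind == "cumulative_random_control") {
        steps <- ceiling(L / plan$segment_size)
        n_rand <- pmin(seq_len(steps) * plan$segment_size, L)
        variants <- control_variants(residues, n_rand, freqs,
                                     seed = derive_seed(plan$seed, paste0("ctl", r)))
      } else {
        dir <- if (kind == "cumulative_n_to_c") "n_to_c" else "c_to_n"
        cv <- cumulative_variants(residues, dir, plan$segment_size, freqs,
                                  seed = derive_seed(plan$seed, paste0("cum", r)))
        variants <- cv$variants; n_rand <- cv$n_randomized
      }
      variants <- c(residues, variants)   # step 0: unperturbed
      n_rand <- c(0L, n_rand)
      rows[[r]] <- data.frame(step = seq_along(variants) - 1L,
                              n_residues_randomized = n_rand, rep = r,
                              variant = variants, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    out$count <- .count_variants(state, as.list(out$variant),
                                 paste(kind, out$rep, out$step + 1L),
                                 test_compounds, plan)
    out$variant <- NULL
    class(out) <- c("perturbation_curve", "data.frame")
    attr(out, "plan") <- plan
    return(out)
  }

  n_motif <- if (!is.null(plan$motif_ranges))
    length(.ranges_to_positions(plan$motif_ranges, L)) else L
  variants <- lapply(seq_len(plan$repeats), function(tr) {
    switch(kind,
      full_randomization = randomize_positions(
        residues, seq_len(L), freqs, seed = derive_seed(plan$seed, paste0("full", tr))),
      motif_randomize = mask_motif(residues, plan$motif_ranges, "randomize", freqs,
                                   seed = derive_seed(plan$seed, paste0("mr", tr))),
      motif_alanine = mask_motif(residues, plan$motif_ranges, "alanine"),
      motif_random_control_randomize = control_variants(
        residues, n_motif, freqs, seed = derive_seed(plan$seed, paste0("cr", tr))),
      motif_random_control_alanine = with_seed(
        derive_seed(plan$seed, paste0("ca", tr)), {
          pos <- sample.int(L, n_motif)
          chars <- strsplit(residues, "")[[1]]; chars[pos] <- "A"
          paste(chars, collapse = "")
        }))
  })
  out <- data.frame(trial = seq_len(plan$repeats),
                    count = .count_variants(state, variants,
                                            paste(kind, seq_len(plan$repeats)),
                                            test_compounds, plan))
  attr(out, "plan") <- plan
  out
}

#' Compare motif masking against positional controls
#'
#' Runs the masked protocol and its matched control (same number of
#' modified positions at random locations, same mode), each for
#' \code{repeats} trials, and tests the two count distributions with a
#' two-sided Mann-Whitney U test.
#'
#' @param state a \code{clm_model}.
#' @param residues test sequence.
#' @param test_compounds canonical SMILES available for the sequence.
#' @param motif_ranges list of 1-based inclusive ranges.
#' @param mode "randomize" or "alanine".
#' @param freqs residue frequencies.
#' @param repeats trials per condition (10 by default).
#' @param n_samples strings sampled per trial.
#' @param temperature sampling temperature.
#' @param seed integer seed.
#' @return list with \code{masked}, \code{control} (trial data.frames) and
#'   \code{test} (a \code{stat_test_result}).
#' @export
motif_masking_comparison <- function(state, residues, test_compounds,
                                     motif_ranges, mode = c("randomize", "alanine"),
                                     freqs, repeats = 10, n_samples = 5000,
                                     temperature = 1, seed = 1) {
  mode <- match.arg(mode)
  masked_kind <- paste0("motif_", mode)
  control_kind <- paste0("motif_random_control_", mode)
  masked <- run_experiment(state, residues, test_compounds,
    perturbation_plan(masked_kind, motif_ranges = motif_ranges, repeats = repeats,
                      n_samples = n_samples, temperature = temperature,
                      seed = derive_seed(seed, "masked")), freqs)
  control <- run_experiment(state, residues, test_compounds,
    perturbation_plan(control_kind, motif_ranges = motif_ranges, repeats = repeats,
                      n_samples = n_samples, temperature = temperature,
                      seed = derive_seed(seed, "control")), freqs)
  list(masked = masked, control = control,
       test = mann_whitney_u(masked$count, control$count))
}

#' Write perturbation variants to FASTA
#'
#' Lets external models be probed with the same variants.
#'
#' @param variants named character vector of residue strings.
#' @param path output FASTA path.
#' @export
write_variants_fasta <- function(variants, path) {
  nm <- names(variants) %||% sprintf("variant_%d", seq_along(variants))
  writeLines(as.vector(rbind(paste0(">", nm), unname(variants))), path)
  invisible(path)
}
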