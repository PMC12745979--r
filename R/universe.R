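# Synthetic sequence-compound universes with known ground truth: protein
# families generated by mutating a common ancestor, embedded sequence
# motifs, analog series built as substituted ring scaffolds, and a
# controllable multi-target (MT) pairing structure.

# ---- compound grammar -------------------------------------------------
#
# A compound is host ring (3 substituent sites) + linker + terminal ring
# (1 substituent site). The scaffold (host + linker + bare terminal) is
# the series' invariant core; substituents are acyclic side chains that
# Murcko extraction removes. Each family owns one host ring, so scaffolds
# can never collide across families even though linkers and substituents
# are shared building blocks. With 32 substituents and 4 sites the analog
# space per scaffold is ~10^6: sampling a few thousand
# strings cannot hit a specific unseen analog by recombination, which is
# the sparse-chemistry regime the harness emulates.

# {a}/{b}/{c} are host substitution sites, {L} the linker+terminal
# attachment on the ring-closure atom. Ring digit 1 is the host, 9 the
# terminal.
.HOST_TEMPLATES <- c(
  benzene     = "c1c{a}c{b}cc{c}c1{L}",
  pyridine    = "c1c{a}c{b}nc{c}c1{L}",
  cyclohexane = "C1C{a}C{b}CC{c}C1{L}",
  oxane       = "C1OC{a}C{b}C{c}C1{L}"
)

# Terminal rings in branch-attachable form, each with one site {t}.
# Deliberately disjoint from the host ring types, and partitioned across
# families at generation time: a family-split model has then never seen
# either ring of a held-out family's scaffolds, so it cannot reproduce a
# test core by recombining building blocks (role-symmetric collisions
# like benzene-linker-pyridyl vs pyridine-linker-phenyl are impossible).
.TERMINAL_RINGS <- c(
  pyrimidinyl = "c9cnc{t}nc9",
  furanyl     = "c9cc{t}co9",
  thienyl     = "c9cc{t}cs9",
  pyrrolyl    = "c9cc{t}c[nH]9",
  pyrazolyl   = "c9cc{t}[nH]n9",
  thiazolyl   = "c9sc{t}nc9",
  oxazolyl    = "c9oc{t}nc9",
  piperidinyl = "N9CC{t}CCC9",
  morpholinyl = "N9CC{t}OCC9",
  cyclopentyl = "C9CC{t}CC9",
  oxolanyl    = "C9CC{t}OC9",
  pyridazinyl = "c9cc{t}cnn9"
)

.LINKERS <- c("-", "C", "CC", "O", "N")

# Acyclic substituents; "" encodes hydrogen (site left unsubstituted).
# Kept short (1-5 heavy atoms) so compound strings stay compact; with 32
# options over 4 sites the analog space per scaffold is still above 10^6.
.SUBSTITUENTS <- c("", "F", "Cl", "Br", "I", "C", "CC", "CCC", "C(C)C",
                   "O", "OC", "OCC", "N", "NC", "N(C)C", "C#N",
                   "C(F)(F)F", "CO", "CN", "C(=O)C", "C(=O)N", "C(=O)O",
                   "S", "SC", "CCO", "CCN", "COC", "CC#N", "NCC",
                   "NC=O", "C(F)F", "C(C)O")

.SITE_MARKERS <- c("{a}", "{b}", "{c}", "{t}")

# Full series template: host with {L} replaced by linker + terminal; the
# four site markers stay open for per-analog substitution.
.series_template <- function(host, linker, terminal) {
  link <- if (linker == "-") paste0("-", terminal) else paste0(linker, terminal)
  sub("{L}", link, .HOST_TEMPLATES[[host]], fixed = TRUE)
}

.fill_template <- function(template, subs) {
  out <- template
  for (i in seq_along(.SITE_MARKERS)) {
    marker <- .SITE_MARKERS[i]
    if (!grepl(marker, out, fixed = TRUE)) next
    frag <- if (i <= length(subs) && nzchar(subs[i])) paste0("(", subs[i], ")") else ""
    out <- sub(marker, frag, out, fixed = TRUE)
  }
  out
}

.template_n_sites <- function(template) {
  sum(vapply(.SITE_MARKERS, grepl, logical(1), x = template, fixed = TRUE))
}

# ---- configuration ----------------------------------------------------

#' Configure a synthetic sequence-compound universe
#'
#' The defaults describe the desk-scale study conditions used throughout
#' the package: 4 protein families of 10 sequences (length 80, within-family
#' identity 0.95) with one embedded 9-residue motif per family, 8 analog
#' series per family of 18 analogs each, 13 compounds per sequence, and a
#' multi-target structure calibrated to 29% MT compounds with a mean of
#' 2.91 sequences per MT compound.
#'
#' @param n_families number of protein families.
#' @param sequences_per_family sequences per family.
#' @param sequence_length residue count (at most 1,000).
#' @param within_family_identity target pairwise identity within a family,
#'   in [0, 1].
#' @param motif_spec optional data.frame with columns \code{family},
#'   \code{start}, \code{end}, \code{motif} (1-based inclusive range).
#'   \code{NULL} auto-places one motif per family at \code{motif_range}.
#' @param motif_range default 1-based inclusive range for auto-placed motifs.
#' @param n_series_per_family analog series per family.
#' @param analogs_per_series compounds per analog series.
#' @param compounds_per_sequence base compounds assigned to each sequence.
#' @param mt_fraction fraction of unique compounds paired with two or more
#'   sequences.
#' @param mt_mean_multiplicity mean sequences per MT compound (at least 2
#'   when \code{mt_fraction > 0}).
#' @param motif_coupled when TRUE, each family carries two motif variants
#'   and series ownership follows the variant, making the motif causally
#'   informative (positive control for motif masking). Default FALSE: series
#'   ownership follows the family as a whole.
#' @param seed integer seed owning all generator randomness.
#' @return a \code{universe_config} list.
#' @export
universe_config <- function(n_families = 4, sequences_per_family = 10,
                            sequence_length = 80, within_family_identity = 0.95,
                            motif_spec = NULL, motif_range = c(36, 44),
                            n_series_per_family = 8, analogs_per_series = 18,
                            compounds_per_sequence = 13,
                            mt_fraction = 0.29, mt_mean_multiplicity = 2.91,
                            motif_coupled = FALSE, seed = 42) {
  cfg <- list(n_families = as.integer(n_families),
              sequences_per_family = as.integer(sequences_per_family),
              sequence_length = as.integer(sequence_length),
              within_family_identity = within_family_identity,
              motif_spec = motif_spec, motif_range = as.integer(motif_range),
              n_series_per_family = as.integer(n_series_per_family),
              analogs_per_series = as.integer(analogs_per_series),
              compounds_per_sequence = as.integer(compounds_per_sequence),
              mt_fraction = mt_fraction,
              mt_mean_multiplicity = mt_mean_multiplicity,
              motif_coupled = isTRUE(motif_coupled),
              seed = as.integer(seed))
  class(cfg) <- "universe_config"
  validate_universe_config(cfg)
  cfg
}

validate_universe_config <- function(cfg) {
  counts <- c(cfg$n_families, cfg$sequences_per_family, cfg$sequence_length,
              cfg$n_series_per_family, cfg$analogs_per_series,
              cfg$compounds_per_sequence)
  if (any(counts <= 0)) stop("all universe counts must be positive")
  if (cfg$sequence_length > 1000) stop("sequence_length must be at most 1,000 residues")
  if (cfg$within_family_identity < 0 || cfg$within_family_identity > 1)
    stop("within_family_identity must lie in [0, 1]")
  if (cfg$mt_fraction < 0 || cfg$mt_fraction > 1) stop("mt_fraction must lie in [0, 1]")
  if (cfg$mt_fraction > 0 && cfg$mt_mean_multiplicity < 2)
    stop("mt_mean_multiplicity must be at least 2 when mt_fraction > 0")
  spec <- cfg$motif_spec
  if (!is.null(spec)) {
    stopifnot(is.data.frame(spec), all(c("family", "start", "end", "motif") %in% names(spec)))
    if (any(spec$start < 1 | spec$end > cfg$sequence_length | spec$start > spec$end))
      stop("motif range exceeds sequence length")
    if (any(nchar(spec$motif) != spec$end - spec$start + 1))
      stop("motif string length must match its range")
  } else {
    if (cfg$motif_range[2] > cfg$sequence_length || cfg$motif_range[1] < 1)
      stop("motif range exceeds sequence length")
  }
  invisible(cfg)
}

# ---- generation -------------------------------------------------------

.random_aa <- function(n) paste(sample(IUPAC_AA, n, replace = TRUE), collapse = "")

# Mutate `n_mut` distinct positions of `seq_chars` to a uniformly chosen
# different residue.
.mutate_sequence <- function(seq_chars, n_mut) {
  if (n_mut == 0) return(seq_chars)
  pos <- sample(length(seq_chars), n_mut)
  for (p in pos) {
    seq_chars[p] <- sample(setdiff(IUPAC_AA, seq_chars[p]), 1)
  }
  seq_chars
}

# Sample candidate analogs of one series template (without replacement
# over the substituent space); canonicalization happens in one batch at
# the caller. Substituent codes index the k-site space; slots beyond the
# template's sites are ignored by .fill_template.
.series_candidates <- function(template, n_candidates) {
  k <- .template_n_sites(template)
  S <- length(.SUBSTITUENTS)
  space <- S^k
  m <- min(space, n_candidates)
  idx <- if (space <= .Machine$integer.max) sample.int(space, m) - 1
         else floor(stats::runif(m) * space)   # space ~ 10^6+: collisions deduped later
  vapply(idx, function(code) {
    subs <- character(k)
    for (j in seq_len(k)) {
      subs[j] <- .SUBSTITUENTS[(code %% S) + 1L]
      code <- code %/% S
    }
    .fill_template(template, subs)
  }, character(1))
}

#' Generate a synthetic sequence-compound universe
#'
#' Families are derived from a random ancestor by point substitutions over
#' the 20-letter alphabet; motifs are written verbatim into their ranges
#' for every member of the owning family. Compounds are substituted ring
#' scaffolds (guaranteed valid, emitted in canonical nonisomeric form) and
#' analog series share a known ground-truth Murcko scaffold, disjoint
#' across series and hence across families. MT compounds are created by
#' pairing a compound with additional sequences, preferentially within the
#' owning family, with multiplicities drawn from a shifted geometric
#' distribution matched to the configured mean.
#'
#' @param config a \code{universe_config}.
#' @return a \code{synthetic_universe} with elements \code{sequences},
#'   \code{compounds}, \code{pairs} (data.frames) and \code{config}.
#' @export
generate_universe <- function(config) {
  validate_universe_config(config)
  with_seed(config$seed, .generate_universe_impl(config))
}

.generate_universe_impl <- function(cfg) {
  L <- cfg$sequence_length
  fam_ids <- paste0("FAM", seq_len(cfg$n_families))

  # motif table: one (or, when motif_coupled, two variants of one) motif
  # per family
  motifs <- cfg$motif_spec
  if (is.null(motifs)) {
    motifs <- data.frame(family = fam_ids,
                         start = cfg$motif_range[1], end = cfg$motif_range[2],
                         motif = vapply(fam_ids, function(f)
                           .random_aa(cfg$motif_range[2] - cfg$motif_range[1] + 1),
                           character(1)),
                         stringsAsFactors = FALSE)
  }
  alt_motifs <- NULL
  if (cfg$motif_coupled) {
    alt_motifs <- motifs
    alt_motifs$motif <- vapply(seq_len(nrow(motifs)), function(i)
      .random_aa(nchar(motifs$motif[i])), character(1))
  }

  # ---- sequences
  n_mut <- round((1 - cfg$within_family_identity) / 2 * L)
  seq_rows <- list()
  for (f in seq_along(fam_ids)) {
    ancestor <- strsplit(.random_aa(L), "")[[1]]
    mrow <- motifs[motifs$family == fam_ids[f], , drop = FALSE]
    for (s in seq_len(cfg$sequences_per_family)) {
      chars <- .mutate_sequence(ancestor, n_mut)
      variant <- if (cfg$motif_coupled) c("A", "B")[(s - 1) %% 2 + 1] else "A"
      if (nrow(mrow) > 0) {
        for (i in seq_len(nrow(mrow))) {
          mot <- if (variant == "B") alt_motifs$motif[alt_motifs$family == fam_ids[f]][i]
                 else mrow$motif[i]
          chars[mrow$start[i]:mrow$end[i]] <- strsplit(mot, "")[[1]]
        }
      }
      seq_rows[[length(seq_rows) + 1]] <- data.frame(
        sequence_id = sprintf("%s_S%02d", fam_ids[f], s),
        family = fam_ids[f],
        residues = paste(chars, collapse = ""),
        motif_start = if (nrow(mrow) > 0) mrow$start[1] else NA_integer_,
        motif_end = if (nrow(mrow) > 0) mrow$end[1] else NA_integer_,
        motif_variant = variant,
        stringsAsFactors = FALSE)
    }
  }
  sequences <- do.call(rbind, seq_rows)

  # ---- analog series / compounds: each family owns one host ring and a
  # private subset of terminal rings; series within a family differ by
  # (linker, terminal) pair
  if (cfg$n_families > length(.TERMINAL_RINGS)) {
    stop(sprintf("compound grammar capacity exceeded: %d terminal rings cannot be partitioned over %d families",
                 length(.TERMINAL_RINGS), cfg$n_families))
  }
  term_groups <- split(sample(unname(.TERMINAL_RINGS)),
                       rep_len(seq_along(fam_ids), length(.TERMINAL_RINGS)))
  series_rows <- list()
  for (f in seq_along(fam_ids)) {
    host <- names(.HOST_TEMPLATES)[(f - 1) %% length(.HOST_TEMPLATES) + 1]
    combos <- expand.grid(linker = .LINKERS, terminal = term_groups[[f]],
                          stringsAsFactors = FALSE)
    if (cfg$n_series_per_family > nrow(combos)) {
      stop(sprintf("compound grammar capacity exceeded: family %s has %d (linker, terminal) scaffolds, %d series requested",
                   fam_ids[f], nrow(combos), cfg$n_series_per_family))
    }
    pick <- combos[sample.int(nrow(combos), cfg$n_series_per_family), , drop = FALSE]
    series_rows[[f]] <- data.frame(
      family = fam_ids[f], host = host,
      template = vapply(seq_len(nrow(pick)), function(i)
        .series_template(host, pick$linker[i], pick$terminal[i]), character(1)),
      stringsAsFactors = FALSE)
  }
  series <- do.call(rbind, series_rows)
  series$series_id <- sprintf("SER%03d", seq_len(nrow(series)))
  series$scaffold <- canonical_smiles(vapply(series$template, .fill_template,
                                             character(1), subs = character(0)))
  if (anyDuplicated(series$scaffold)) {
    stop("compound grammar capacity exceeded: scaffold collision after canonicalization")
  }
  if (cfg$motif_coupled) {
    series$variant <- rep_len(c("A", "B"), nrow(series))
  } else series$variant <- "A"

  # candidate analogs for all series, canonicalized in one batch per round
  analogs <- vector("list", nrow(series))
  need <- rep(cfg$analogs_per_series, nrow(series))
  for (round in 1:6) {
    todo <- which(lengths(analogs) < cfg$analogs_per_series)
    if (length(todo) == 0) break
    cand <- lapply(todo, function(i) {
      unique(.series_candidates(series$template[i], n_candidates = 4L * need[i] * round))
    })
    canon <- canonical_smiles(unlist(cand), strict = FALSE)
    offsets <- cumsum(c(0, lengths(cand)))
    for (j in seq_along(todo)) {
      i <- todo[j]
      got <- canon[(offsets[j] + 1):offsets[j + 1]]
      got <- unique(got[!is.na(got)])
      analogs[[i]] <- utils::head(unique(c(analogs[[i]], got)), cfg$analogs_per_series)
    }
  }
  if (any(lengths(analogs) < cfg$analogs_per_series)) {
    stop("compound grammar capacity exceeded: substituent space cannot produce the requested number of distinct analogs")
  }

  compounds <- data.frame(
    compound_id = sprintf("CPD%05d", seq_len(nrow(series) * cfg$analogs_per_series)),
    smiles = unlist(analogs),
    series_id = rep(series$series_id, each = cfg$analogs_per_series),
    family = rep(series$family, each = cfg$analogs_per_series),
    variant = rep(series$variant, each = cfg$analogs_per_series),
    scaffold = rep(series$scaffold, each = cfg$analogs_per_series),
    stringsAsFactors = FALSE)

  # ---- base pairing: each compound used by at most one sequence
  pair_rows <- list()
  for (f in fam_ids) {
    fam_seq <- sequences[sequences$family == f, , drop = FALSE]
    for (v in unique(fam_seq$motif_variant)) {
      vseq <- fam_seq[fam_seq$motif_variant == v, , drop = FALSE]
      pool <- compounds$compound_id[compounds$family == f & compounds$variant == v]
      needed <- nrow(vseq) * cfg$compounds_per_sequence
      if (length(pool) < needed) {
        stop(sprintf("compound grammar capacity exceeded: family %s variant %s has %d compounds for %d assignments",
                     f, v, length(pool), needed))
      }
      pool <- sample(pool, needed)
      idx <- 0
      for (sid in vseq$sequence_id) {
        take <- pool[(idx + 1):(idx + cfg$compounds_per_sequence)]
        idx <- idx + cfg$compounds_per_sequence
        pair_rows[[length(pair_rows) + 1]] <- data.frame(
          sequence_id = sid, compound_id = take, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, pair_rows)

  # drop never-assigned compounds so the pair list covers the compound table
  compounds <- compounds[compounds$compound_id %in% pairs$compound_id, , drop = FALSE]
  rownames(compounds) <- NULL

  # ---- MT structure: shifted-geometric multiplicities, same-family first
  n_unique <- nrow(compounds)
  n_mt <- round(cfg$mt_fraction * n_unique)
  if (n_mt > 0) {
    mt_ids <- sample(compounds$compound_id, n_mt)
    p_geom <- 1 / (cfg$mt_mean_multiplicity - 1)
    mult <- 2L + stats::rgeom(n_mt, p_geom)
    mult <- pmin(mult, nrow(sequences))
    extra <- list()
    owner <- pairs$sequence_id[match(mt_ids, pairs$compound_id)]
    fam_of <- sequences$family[match(owner, sequences$sequence_id)]
    var_of <- compounds$variant[match(mt_ids, compounds$compound_id)]
    for (i in seq_len(n_mt)) {
      same_fam <- setdiff(sequences$sequence_id[sequences$family == fam_of[i]], owner[i])
      if (cfg$motif_coupled) {
        # keep the motif-compound coupling intact: extra assignments stay
        # within the owning variant; cross-family sequences come next and
        # never carry the wrong variant's motif
        same_var <- same_fam[sequences$motif_variant[match(same_fam, sequences$sequence_id)] == var_of[i]]
        other <- setdiff(sequences$sequence_id,
                         c(owner[i], sequences$sequence_id[sequences$family == fam_of[i]]))
        cand <- c(sample(same_var), sample(other))
      } else {
        other <- setdiff(sequences$sequence_id, c(owner[i], same_fam))
        cand <- c(sample(same_fam), sample(other))
      }
      take <- cand[seq_len(min(mult[i] - 1L, length(cand)))]
      extra[[i]] <- data.frame(sequence_id = take, compound_id = mt_ids[i],
                               stringsAsFactors = FALSE)
    }
    pairs <- rbind(pairs, do.call(rbind, extra))
  }
  pairs <- pairs[order(pairs$sequence_id, pairs$compound_id), , drop = FALSE]
  rownames(pairs) <- NULL

  structure(list(sequences = sequences, compounds = compounds, pairs = pairs,
                 config = cfg),
            class = "synthetic_universe")
}

#' @export
print.synthetic_universe <- function(x, ...) {
  st <- universe_mt_stats(x)
  cat(sprintf(paste0("<synthetic_universe: %d sequences in %d families, ",
                     "%d compounds, %d pairs>\n"),
              nrow(x$sequences), length(unique(x$sequences$family)),
              nrow(x$compounds), nrow(x$pairs)))
  cat(sprintf("  MT fraction %.3f, mean multiplicity of MT compounds %.2f\n",
              st$mt_fraction, st$mt_mean_multiplicity))
  invisible(x)
}

#' Empirical multi-target statistics of a universe or pair table
#'
#' Brute-force counts over the pair list: the fraction of unique compounds
#' paired with two or more sequences, and the mean number of sequences per
#' MT compound.
#'
#' @param x a \code{synthetic_universe} or a data.frame of pairs with
#'   columns \code{sequence_id}, \code{compound_id}.
#' @return list with \code{mt_fraction}, \code{mt_mean_multiplicity},
#'   \code{n_unique_compounds}, \code{n_pairs}.
#' @export
universe_mt_stats <- function(x) {
  pairs <- if (inherits(x, "synthetic_universe")) x$pairs else x
  mult <- table(pairs$compound_id)
  mt <- mult[mult >= 2]
  list(mt_fraction = length(mt) / length(mult),
       mt_mean_multiplicity = if (length(mt)) mean(as.numeric(mt)) else NA_real_,
       n_unique_compounds = length(mult),
       n_pairs = nrow(pairs))
}

# ---- validation -------------------------------------------------------

.pairwise_identity <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  mean(ca == cb)
}

#' Validate a synthetic universe
#'
#' Always returns a report (a character vector of violation messages,
#' empty when the universe satisfies every invariant): dangling pair
#' references, duplicate pairs, invalid or non-canonical SMILES, motif
#' mismatches, within-family identity below the configured level (with
#' tolerance), and analog series whose members do not share the stored
#' ground-truth scaffold.
#'
#' @param universe a \code{synthetic_universe}.
#' @param identity_tolerance slack allowed below the configured
#'   within-family identity (point substitutions can coincide).
#' @return character vector of violations (length 0 when valid).
#' @export
validate_universe <- function(universe, identity_tolerance = 0.08) {
  v <- character(0)
  seqs <- universe$sequences; cpds <- universe$compounds; pairs <- universe$pairs

  dangle_s <- setdiff(pairs$sequence_id, seqs$sequence_id)
  dangle_c <- setdiff(pairs$compound_id, cpds$compound_id)
  for (d in dangle_s) v <- c(v, sprintf("pair references unknown sequence %s", d))
  for (d in dangle_c) v <- c(v, sprintf("pair references unknown compound %s", d))
  dup <- duplicated(pairs[c("sequence_id", "compound_id")])
  if (any(dup)) v <- c(v, sprintf("%d duplicate (sequence, compound) pairs", sum(dup)))

  canon <- canonical_smiles(cpds$smiles, strict = FALSE)
  bad <- is.na(canon)
  for (i in which(bad)) v <- c(v, sprintf("invalid SMILES for %s", cpds$compound_id[i]))
  noncanon <- which(!bad & canon != cpds$smiles)
  for (i in noncanon) v <- c(v, sprintf("non-canonical SMILES for %s", cpds$compound_id[i]))

  # motif placement (variant A sequences carry the configured motif; the
  # generator stores coordinates per sequence)
  cfg <- universe$config
  if (!is.null(cfg)) {
    motifs <- cfg$motif_spec
    if (is.null(motifs) && !is.na(seqs$motif_start[1])) {
      # auto-generated motifs: check family-internal consistency instead
      for (f in unique(seqs$family)) {
        fs <- seqs[seqs$family == f & seqs$motif_variant == "A", , drop = FALSE]
        if (nrow(fs) < 2 || is.na(fs$motif_start[1])) next
        segs <- substr(fs$residues, fs$motif_start, fs$motif_end)
        if (length(unique(segs)) != 1)
          v <- c(v, sprintf("family %s motif not identical across members", f))
      }
    } else if (!is.null(motifs)) {
      for (i in seq_len(nrow(motifs))) {
        fs <- seqs[seqs$family == motifs$family[i] & seqs$motif_variant == "A", , drop = FALSE]
        segs <- substr(fs$residues, motifs$start[i], motifs$end[i])
        if (any(segs != motifs$motif[i]))
          v <- c(v, sprintf("motif mismatch in family %s", motifs$family[i]))
      }
    }
    # within-family pairwise identity; in motif-coupled universes the two
    # motif variants differ by design, so identity is scored outside the
    # motif range there
    for (f in unique(seqs$family)) {
      fs <- seqs[seqs$family == f, , drop = FALSE]
      fam <- fs$residues
      if (isTRUE(cfg$motif_coupled) && !is.na(fs$motif_start[1])) {
        fam <- paste0(substr(fam, 1, fs$motif_start[1] - 1),
                      substr(fam, fs$motif_end[1] + 1, nchar(fam)))
      }
      if (length(fam) < 2) next
      idx <- utils::combn(length(fam), 2)
      idents <- apply(idx, 2, function(k) .pairwise_identity(fam[k[1]], fam[k[2]]))
      if (min(idents) < cfg$within_family_identity - identity_tolerance)
        v <- c(v, sprintf("family %s pairwise identity %.3f below configured %.2f",
                          f, min(idents), cfg$within_family_identity))
    }
  }

  # series scaffold ground truth
  if (!any(bad)) {
    scaf <- murcko_scaffold(cpds$smiles, strict = FALSE)
    mismatch <- which(!is.na(scaf) & scaf != cpds$scaffold)
    for (i in mismatch) {
      v <- c(v, sprintf("compound %s scaffold %s differs from series ground truth %s",
                        cpds$compound_id[i], scaf[i], cpds$scaffold[i]))
    }
  }
  v
}

# ---- I/O --------------------------------------------------------------

#' Write a universe to plain-text files
#'
#' Sequences go to FASTA (family, motif range and variant encoded as
#' key=value tokens on the description line), compounds and pairs to TSV,
#' and the configuration to JSON.
#'
#' @param universe a \code{synthetic_universe}.
#' @param dir output directory (created if missing).
#' @return invisibly, the paths written.
#' @export
write_universe <- function(universe, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fasta <- file.path(dir, "sequences.fasta")
  s <- universe$sequences
  headers <- sprintf(">%s family=%s motif=%s-%s variant=%s",
                     s$sequence_id, s$family, s$motif_start, s$motif_end,
                     s$motif_variant)
  writeLines(as.vector(rbind(headers, s$residues)), fasta)
  cpd <- file.path(dir, "compounds.tsv")
  utils::write.table(universe$compounds, cpd, sep = "\t", quote = FALSE, row.names = FALSE)
  pr <- file.path(dir, "pairs.tsv")
  p <- universe$pairs
  p <- data.frame(pair_id = sprintf("PAIR%05d", seq_len(nrow(p))),
                  sequence_id = p$sequence_id, compound_id = p$compound_id,
                  smiles = universe$compounds$smiles[match(p$compound_id,
                                                           universe$compounds$compound_id)])
  utils::write.table(p, pr, sep = "\t", quote = FALSE, row.names = FALSE)
  cfgp <- file.path(dir, "config.json")
  jsonlite::write_json(universe$config[setdiff(names(universe$config), "motif_spec")],
                       cfgp, auto_unbox = TRUE, digits = NA)
  invisible(c(fasta = fasta, compounds = cpd, pairs = pr, config = cfgp))
}
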