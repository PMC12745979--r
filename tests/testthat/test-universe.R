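# Synthetic universe generator: determinism, MT calibration, validity.

test_that("generation is deterministic given the seed and differs across seeds", {
  cfg <- universe_config(n_families = 2, sequences_per_family = 3,
                         sequence_length = 40, motif_range = c(11, 20),
                         n_series_per_family = 2, analogs_per_series = 8,
                         compounds_per_sequence = 4, seed = 3)
  u1 <- generate_universe(cfg)
  u2 <- generate_universe(cfg)
  expect_identical(u1, u2)
  cfg2 <- cfg; cfg2$seed <- 4L
  expect_false(identical(u1$sequences$residues, generate_universe(cfg2)$sequences$residues))
})

test_that("mt_fraction = 0 gives every compound exactly one pair", {
  u <- generate_universe(universe_config(
    n_families = 2, sequences_per_family = 4, sequence_length = 40,
    motif_range = c(11, 20), n_series_per_family = 3, analogs_per_series = 10,
    compounds_per_sequence = 5, mt_fraction = 0, seed = 5))
  expect_identical(max(table(u$pairs$compound_id)), 1L)
})

test_that("empirical MT statistics hit the configured corpus shape", {
  u <- fix_universe()   # mt_fraction 0.29, mean multiplicity 2.91
  st <- universe_mt_stats(u)
  expect_gte(st$mt_fraction, 0.26); expect_lte(st$mt_fraction, 0.32)
  expect_gte(st$mt_mean_multiplicity, 2.6); expect_lte(st$mt_mean_multiplicity, 3.2)
  # brute-force recount over the raw pair list
  mult <- vapply(unique(u$pairs$compound_id), function(cid)
    length(unique(u$pairs$sequence_id[u$pairs$compound_id == cid])), integer(1))
  expect_equal(st$mt_fraction, mean(mult >= 2))
  expect_equal(st$mt_mean_multiplicity, mean(mult[mult >= 2]))
})

test_that("MT calibration tightens as the universe grows", {
  small <- generate_universe(universe_config(
    n_families = 2, sequences_per_family = 5, compounds_per_sequence = 8,
    n_series_per_family = 4, analogs_per_series = 12, seed = 21))
  big <- generate_universe(universe_config(
    n_families = 4, sequences_per_family = 10, compounds_per_sequence = 16,
    n_series_per_family = 8, analogs_per_series = 22, seed = 21))
  err <- function(u) abs(universe_mt_stats(u)$mt_fraction - 0.29)
  # 4x the pairs: the relative error should not blow up; both stay in band
  expect_lte(err(big), max(err(small), 0.03) + 1e-9)
})

test_that("generated universes pass validation and edits are caught", {
  u <- fix_small_universe()
  expect_no_violations(u)

  broken <- u
  broken$pairs$compound_id[1] <- "CPD99999"
  v <- validate_universe(broken)
  expect_length(grep("unknown compound", v), 1)

  corrupt <- u
  corrupt$compounds$smiles[3] <- "C1CC("   # unparseable
  v <- validate_universe(corrupt)
  expect_length(grep("invalid SMILES", v), 1)
})

test_that("compounds are emitted in canonical form and series share their scaffold", {
  u <- fix_small_universe()
  expect_identical(canonical_smiles(u$compounds$smiles), u$compounds$smiles)
  scaf <- murcko_scaffold(u$compounds$smiles)
  expect_identical(scaf, u$compounds$scaffold)
  per_series <- tapply(u$compounds$scaffold, u$compounds$series_id,
                       function(s) length(unique(s)))
  expect_true(all(per_series == 1))
})

test_that("cross-family scaffold sets are disjoint", {
  u <- fix_universe()
  fam_scafs <- tapply(u$compounds$scaffold, u$compounds$family, unique)
  for (i in seq_along(fam_scafs)) {
    for (j in seq_len(i - 1)) {
      expect_length(intersect(fam_scafs[[i]], fam_scafs[[j]]), 0)
    }
  }
})

test_that("capacity and validation errors are explicit", {
  expect_error(generate_universe(universe_config(
    n_families = 2, n_series_per_family = 60, sequences_per_family = 2,
    compounds_per_sequence = 2, analogs_per_series = 4, seed = 1)),
    "capacity")
  expect_error(universe_config(sequence_length = 50, motif_range = c(40, 60)),
               "motif range")
  expect_error(universe_config(mt_fraction = 0.3, mt_mean_multiplicity = 1.5),
               "mt_mean_multiplicity")
})

test_that("universe files round-trip through plain-text formats", {
  u <- fix_small_universe()
  d <- tempfile()
  write_universe(u, d)
  fasta <- readLines(file.path(d, "sequences.fasta"))
  expect_length(fasta, 2 * nrow(u$sequences))
  expect_match(fasta[1], "^>FAM1_S01 family=FAM1 motif=11-20")
  pairs <- utils::read.table(file.path(d, "pairs.tsv"), header = TRUE, sep = "\t")
  expect_identical(nrow(pairs), nrow(u$pairs))
  expect_true(all(c("pair_id", "sequence_id", "compound_id", "smiles") %in% names(pairs)))
})
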