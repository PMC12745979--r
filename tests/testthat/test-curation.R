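# Record filtering and pair-dataset construction.

make_records <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r) {
    data.frame(compound_smiles = r[[1]], target_id = r[[2]],
               activity_value_nm = as.numeric(r[[3]]),
               confidence_score = as.integer(r[[4]]),
               direct_binding = as.logical(r[[5]]),
               excluded_by_public_filters = as.logical(r[[6]]),
               stringsAsFactors = FALSE)
  }))
}

seqs <- c(T1 = "ACDEFGHIKL", T2 = "MNPQRSTVWY")

test_that("record-level filters drop low-confidence, indirect, flagged and heavy entries", {
  # a molecule above 1,000 Da: long saturated chain C75H152 ~ 1,054 Da
  heavy <- paste(rep("C", 75), collapse = "")
  rec <- make_records(
    list("CCO", "T1", 10, 9, TRUE, FALSE),
    list("CCO", "T1", 10, 8, TRUE, FALSE),    # confidence below 9
    list("CCN", "T1", 10, 9, FALSE, FALSE),   # not direct binding
    list("CCS", "T1", 10, 9, TRUE, TRUE),     # public-filter flag
    list(heavy, "T1", 10, 9, TRUE, FALSE))    # molecular weight > 1,000
  out <- filter_records(rec, seqs)
  expect_identical(nrow(out), 1L)
  expect_identical(out$compound_smiles, "CCO")
})

test_that("molecular weight boundary sits at 1,000 Da", {
  mw <- molecular_weight(paste(rep("C", 71), collapse = ""))  # C71H144
  expect_true(mw < 1000)
  mw_heavy <- molecular_weight(paste(rep("C", 72), collapse = ""))
  expect_true(mw_heavy > 1000)
  rec <- make_records(list(paste(rep("C", 72), collapse = ""), "T1", 10, 9, TRUE, FALSE))
  expect_identical(nrow(filter_records(rec, seqs)), 0L)
})

test_that("order-of-magnitude rule keeps 10/95 and drops 10/200 as a group", {
  rec <- make_records(
    list("CCO", "T1", 10, 9, TRUE, FALSE),
    list("CCO", "T1", 95, 9, TRUE, FALSE),
    list("CCN", "T1", 10, 9, TRUE, FALSE),
    list("CCN", "T1", 200, 9, TRUE, FALSE))
  out <- filter_records(rec, seqs)
  expect_identical(sort(unique(out$compound_smiles)), "CCO")
  expect_identical(nrow(out), 2L)
  # log10 binning differs exactly at decade boundaries: 9 and 11 nM pass
  # the ratio rule but straddle the 10 nM decade edge
  rec2 <- make_records(
    list("CCS", "T1", 9, 9, TRUE, FALSE),
    list("CCS", "T1", 11, 9, TRUE, FALSE))
  expect_identical(nrow(filter_records(rec2, seqs)), 2L)
  expect_identical(nrow(filter_records(rec2, seqs, magnitude_rule = "log10")), 0L)
})

test_that("records against unknown or overlong targets are dropped", {
  long_seqs <- c(seqs, TLONG = paste(rep("A", 1001), collapse = ""))
  rec <- make_records(
    list("CCO", "T1", 10, 9, TRUE, FALSE),
    list("CCO", "TX", 10, 9, TRUE, FALSE),
    list("CCO", "TLONG", 10, 9, TRUE, FALSE))
  expect_warning(out <- filter_records(rec, long_seqs), "unknown targets")
  expect_identical(out$target_id, "T1")
})

test_that("filtering is idempotent", {
  rec <- make_records(
    list("CCO", "T1", 10, 9, TRUE, FALSE),
    list("CCO", "T1", 95, 9, TRUE, FALSE),
    list("CCN", "T2", 5, 9, TRUE, FALSE),
    list("CCCC", "T2", 800, 9, TRUE, FALSE))
  once <- filter_records(rec, seqs)
  twice <- filter_records(once, seqs)
  expect_identical(once, twice)
})

test_that("build_pairs canonicalizes, deduplicates and counts multiplicity", {
  rec <- make_records(
    list("C[C@H](N)O", "T1", 12, 9, TRUE, FALSE),
    list("CC(N)O", "T1", 20, 9, TRUE, FALSE),    # same molecule, stereo stripped
    list("CC(N)O", "T2", 15, 9, TRUE, FALSE),
    list("CCO", "T2", 15, 9, TRUE, FALSE))
  ds <- build_pairs(filter_records(rec, seqs),
                    data.frame(sequence_id = names(seqs), family = c("F1", "F2"),
                               residues = unname(seqs)))
  expect_identical(nrow(ds$pairs), 3L)
  m <- compound_multiplicity(ds)
  expect_identical(unname(m[canonical_smiles("CC(N)O")]), 2L)
  expect_identical(mt_compounds(ds), canonical_smiles("CC(N)O"))
  # sum of multiplicities equals the pair count
  expect_identical(sum(m), nrow(ds$pairs))
})

test_that("dataset summary equals brute-force recount", {
  ds <- fix_small_dataset()
  s <- summary(ds)
  mult <- vapply(unique(ds$pairs$smiles), function(s)
    length(unique(ds$pairs$sequence_id[ds$pairs$smiles == s])), integer(1))
  expect_equal(s$mean_multiplicity, mean(mult))
  expect_equal(s$mt_fraction, mean(mult >= 2))
  expect_identical(s$n_pairs, nrow(ds$pairs))
})

test_that("activity tables round-trip through TSV", {
  rec <- make_records(list("CCO", "T1", 10, 9, TRUE, FALSE),
                      list("CCN", "T2", 5, 9, TRUE, FALSE))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(rec, f, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_activity_records(f)
  expect_identical(back$compound_smiles, rec$compound_smiles)
  expect_identical(back$direct_binding, rec$direct_binding)
  expect_error(read_activity_records(
    { g <- tempfile(); writeLines("a\tb", g); g }), "lacks columns")
})
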