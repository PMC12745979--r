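# Train/test partitioning and MT dilution.

test_that("sequence split is disjoint, size-correct and pair-preserving", {
  ds <- fix_dataset()
  sp <- split_by_sequence(ds, split_plan("sequence", seed = 4))
  tr_ids <- unique(sp$train$pairs$sequence_id)
  te_ids <- unique(sp$test$pairs$sequence_id)
  expect_length(intersect(tr_ids, te_ids), 0)
  n_seq <- length(unique(ds$sequences$sequence_id))
  expect_identical(length(unique(sp$train$sequences$sequence_id)),
                   as.integer(round(0.7 * n_seq)))
  expect_identical(nrow(sp$train$pairs) + nrow(sp$test$pairs), nrow(ds$pairs))
  # deterministic given seed
  sp2 <- split_by_sequence(ds, split_plan("sequence", seed = 4))
  expect_identical(sp$train$pairs, sp2$train$pairs)
})

test_that("an MT compound can sit on both sides of a sequence split", {
  seqs <- data.frame(sequence_id = c("s1", "s2", "s3"), family = "F",
                     residues = c("AAAA", "CCCC", "DDDD"))
  pairs <- data.frame(sequence_id = c("s1", "s2", "s3", "s1"),
                      smiles = c("X", "X", "Y", "Z"))
  ds <- pair_dataset(pairs, seqs)
  # with 3 sequences and fraction 0.7, 2 go to train; X pairs with s1 and s2
  sp <- split_by_sequence(ds, split_plan("sequence", seed = 1))
  both <- intersect(unique(sp$train$pairs$smiles), unique(sp$test$pairs$smiles))
  # across seeds placing s1/s2 apart, X leaks; find such a seed deterministically
  found <- FALSE
  for (s in 1:10) {
    spx <- split_by_sequence(ds, split_plan("sequence", seed = s))
    tr <- unique(spx$train$pairs$sequence_id)
    if (xor("s1" %in% tr, "s2" %in% tr)) {
      expect_true("X" %in% intersect(unique(spx$train$pairs$smiles),
                                     unique(spx$test$pairs$smiles)))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("family split keeps families whole and packs pairs toward 70%", {
  ds <- fix_dataset()
  sp <- split_by_family(ds, split_plan("family", seed = 2))
  tr_fams <- unique(ds$sequences$family[match(unique(sp$train$pairs$sequence_id),
                                              ds$sequences$sequence_id)])
  te_fams <- unique(ds$sequences$family[match(unique(sp$test$pairs$sequence_id),
                                              ds$sequences$sequence_id)])
  expect_length(intersect(tr_fams, te_fams), 0)
  frac <- nrow(sp$train$pairs) / nrow(ds$pairs)
  expect_gt(frac, 0.5); expect_lt(frac, 0.9)
})

test_that("family packing matches exhaustive search on the worked example", {
  counts <- c(A = 50, B = 20, C = 15, D = 10, E = 5)
  train <- clmprobe:::.family_pack_exhaustive(counts, 0.7 * sum(counts))
  expect_identical(sum(counts[train]), 70)
  greedy <- clmprobe:::.family_pack_greedy(counts, 0.7 * sum(counts))
  expect_identical(sum(counts[greedy]), 70)
})

test_that("greedy packing attains the exhaustive optimum on random small instances", {
  set.seed(42)
  for (i in 1:20) {
    k <- sample(3:9, 1)
    counts <- setNames(sample(5:60, k, replace = TRUE), paste0("F", seq_len(k)))
    target <- 0.7 * sum(counts)
    ex <- clmprobe:::.family_pack_exhaustive(counts, target)
    gr <- clmprobe:::.family_pack_greedy(counts, target)
    expect_lte(abs(sum(counts[gr]) - target) - abs(sum(counts[ex]) - target),
               max(counts) * 0.5)   # greedy is near-optimal; exact is the default
    expect_identical(abs(sum(counts[ex]) - target),
                     min(vapply(1:(2^k - 2), function(m) {
                       sel <- as.logical(bitwAnd(m, 2^(seq_len(k) - 1)))
                       abs(sum(counts[sel]) - target)
                     }, numeric(1))))
  }
})

test_that("single-side degenerate splits error", {
  seqs <- data.frame(sequence_id = "s1", family = "F", residues = "AAAA")
  ds <- pair_dataset(data.frame(sequence_id = "s1", smiles = "X"), seqs)
  expect_error(split_by_sequence(ds, split_plan("sequence")), "at least 2")
  expect_error(split_by_family(ds, split_plan("family")), "at least 2")
})

test_that("dilution converts the right number of MT compounds and nests across levels", {
  ds <- fix_dataset()
  mt <- mt_compounds(ds)
  d75 <- dilute_mt(ds, 0.75, seed = 9)
  d25 <- dilute_mt(ds, 0.25, seed = 9)
  d0 <- dilute_mt(ds, 0, seed = 9)

  conv <- function(dil) setdiff(mt, mt_compounds(dil))
  expect_identical(length(conv(d75)), as.integer(round(0.25 * length(mt))))
  expect_identical(length(conv(d25)), as.integer(round(0.75 * length(mt))))
  # nesting: compounds converted at 0.75 are converted at every lower level
  expect_true(all(conv(d75) %in% conv(d25)))
  expect_true(all(conv(d25) %in% conv(d0)))

  # retain 0: every compound single-target; single-target pairs untouched
  expect_true(all(compound_multiplicity(d0) == 1))
  st_pairs <- ds$pairs[!(ds$pairs$smiles %in% mt), ]
  expect_true(all(paste(st_pairs$sequence_id, st_pairs$smiles) %in%
                  paste(d0$pairs$sequence_id, d0$pairs$smiles)))
  # identity at retain 1
  expect_identical(dilute_mt(ds, 1, seed = 9)$pairs, ds$pairs)
})

test_that("an MT compound with three pairs keeps exactly one pair at retain 0", {
  seqs <- data.frame(sequence_id = paste0("s", 1:3), family = "F",
                     residues = c("AAAA", "CCCC", "DDDD"))
  ds <- pair_dataset(data.frame(sequence_id = paste0("s", 1:3), smiles = "X"), seqs)
  d0 <- dilute_mt(ds, 0, seed = 3)
  expect_identical(nrow(d0$pairs), 1L)
  expect_identical(unname(compound_multiplicity(d0)["X"]), 1L)
})

test_that("full dilution before a sequence split makes compound sets disjoint", {
  ds <- fix_dataset()
  d0 <- dilute_mt(ds, 0, seed = 5)
  sp <- split_by_sequence(d0, split_plan("sequence", seed = 5))
  expect_length(intersect(unique(sp$train$pairs$smiles),
                          unique(sp$test$pairs$smiles)), 0)
})

test_that("dilution schedules validate their levels", {
  expect_error(dilution_schedule(c(0.75, 0.5)), "first retain level")
  expect_error(dilution_schedule(c(1, 0.5, 0.5)), "strictly decreasing")
  s <- dilution_schedule()
  expect_identical(s$retain_levels, c(1, 0.75, 0.5, 0.25, 0))
})
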