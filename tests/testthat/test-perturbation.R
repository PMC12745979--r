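# Sequence-modification protocols.

test_that("residue frequencies are relative occurrence counts", {
  f <- residue_frequencies(c("AA", "CC"))
  expect_equal(unname(f[c("A", "C")]), c(0.5, 0.5))
  f4 <- residue_frequencies("ACDE")
  expect_equal(unname(f4[c("A", "C", "D", "E")]), rep(0.25, 4))
  u <- fix_small_universe()
  expect_equal(sum(residue_frequencies(u$sequences$residues)), 1)
})

test_that("randomize_positions targets exactly the listed positions", {
  seq <- paste(rep("M", 30), collapse = "")
  freqs <- c(G = 1.0)   # degenerate: forced outcome
  expect_identical(randomize_positions(seq, integer(0), freqs), seq)
  out <- randomize_positions(seq, 1:15, freqs, seed = 1)
  expect_identical(substr(out, 1, 15), paste(rep("G", 15), collapse = ""))
  expect_identical(substr(out, 16, 30), paste(rep("M", 15), collapse = ""))
  expect_error(randomize_positions(seq, 31, freqs), "out of sequence range")
})

test_that("cumulative variants nest and cover the sequence", {
  seq <- paste(sample(strsplit("ACDEFGHIKL", "")[[1]], 100, replace = TRUE),
               collapse = "")
  freqs <- residue_frequencies(seq)
  cv <- cumulative_variants(seq, "n_to_c", 15, freqs, seed = 4)
  expect_length(cv$variants, ceiling(100 / 15))
  expect_identical(cv$n_randomized, c(15L, 30L, 45L, 60L, 75L, 90L, 100L))
  # cumulative value nesting: the prefix randomized at step k is carried
  # unchanged into step k+1
  for (k in 1:(length(cv$variants) - 1)) {
    expect_identical(substr(cv$variants[k + 1], 1, cv$n_randomized[k]),
                     substr(cv$variants[k], 1, cv$n_randomized[k]))
  }
  # untouched suffix at step 1
  expect_identical(substr(cv$variants[1], 16, 100), substr(seq, 16, 100))
  # C -> N direction touches the tail first
  cc <- cumulative_variants(seq, "c_to_n", 15, freqs, seed = 4)
  expect_identical(substr(cc$variants[1], 1, 85), substr(seq, 1, 85))
})

test_that("control variants have the commanded cardinality", {
  seq <- paste(rep("M", 60), collapse = "")
  # leave-one-out frequencies force visible changes at targeted positions
  freqs <- setNames(rep(1 / 19, 19), setdiff(clmprobe:::IUPAC_AA, "M"))
  v <- control_variants(seq, c(15, 60), freqs, seed = 2)
  diffs <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
  expect_identical(diffs(v[1], seq), 15L)
  expect_identical(diffs(v[2], seq), 60L)
  # same seed reproduces, different seed moves the positions
  v2 <- control_variants(seq, c(15, 60), freqs, seed = 2)
  expect_identical(v, v2)
  v3 <- control_variants(seq, c(15, 60), freqs, seed = 3)
  expect_false(identical(v[1], v3[1]))
})

test_that("motif masking writes alanine exactly inside the ranges", {
  seq <- paste(rep("W", 200), collapse = "")
  # family-signature style range: 17 consecutive positions
  out <- mask_motif(seq, c(140, 156), mode = "alanine")
  expect_identical(substr(out, 140, 156), paste(rep("A", 17), collapse = ""))
  expect_identical(substr(out, 1, 139), paste(rep("W", 139), collapse = ""))
  expect_identical(substr(out, 157, 200), paste(rep("W", 44), collapse = ""))
  # split motif: kinase ATP-site style [32-40, 55] = 10 positions
  out2 <- mask_motif(seq, list(c(32, 40), c(55, 55)), mode = "alanine")
  ch <- strsplit(out2, "")[[1]]
  expect_identical(which(ch == "A"), c(32:40, 55L))
  # already poly-A motif: unchanged
  polyA <- paste(rep("A", 50), collapse = "")
  expect_identical(mask_motif(polyA, c(10, 20), mode = "alanine"), polyA)
  expect_warning(mask_motif(seq, list(c(10, 20), c(15, 25)), mode = "alanine"),
                 "merged")
  expect_error(mask_motif(seq, c(190, 210), mode = "alanine"), "outside")
})

test_that("perturbation plans validate their inputs", {
  expect_error(perturbation_plan("motif_alanine"), "motif_ranges")
  expect_identical(perturbation_plan("cumulative_n_to_c")$repeats, 5L)
  expect_identical(perturbation_plan("motif_alanine",
                                     motif_ranges = list(c(1, 5)))$repeats, 10L)
  expect_error(perturbation_plan("cumulative_n_to_c", segment_size = 0),
               "segment_size")
})

test_that("run_experiment produces curves anchored at the unperturbed count", {
  fx <- fix_tiny_model()
  ds <- fx$dataset
  sid <- ds$pairs$sequence_id[1]
  res <- ds$sequences$residues[match(sid, ds$sequences$sequence_id)]
  cpds <- unique(ds$pairs$smiles[ds$pairs$sequence_id == sid])
  freqs <- residue_frequencies(ds$sequences$residues)
  plan <- perturbation_plan("cumulative_n_to_c", segment_size = 15, repeats = 2,
                            n_samples = 60, seed = 3)
  curve <- run_experiment(fx$model, res, cpds, plan, freqs)
  expect_s3_class(curve, "perturbation_curve")
  steps <- as.integer(ceiling(nchar(res) / 15))
  expect_identical(nrow(curve), 2L * (steps + 1L))
  # step 0 is the identity variant: equals a direct unperturbed evaluation
  direct <- count_reproduced(
    clm_sample(fx$model, res, n = 60, temperature = 1,
               seed = derive_seed(3, paste("cumulative_n_to_c", 1, 1))), cpds)
  expect_identical(curve$count[curve$step == 0 & curve$rep == 1], direct)
  s <- summarize_curve(curve)
  expect_identical(s$n_residues_randomized, c(0L, pmin(seq_len(steps) * 15L, nchar(res))))
})

test_that("masking comparison returns paired distributions and a test", {
  fx <- fix_tiny_model()
  ds <- fx$dataset
  sid <- ds$pairs$sequence_id[1]
  res <- ds$sequences$residues[match(sid, ds$sequences$sequence_id)]
  cpds <- unique(ds$pairs$smiles[ds$pairs$sequence_id == sid])
  freqs <- residue_frequencies(ds$sequences$residues)
  cmp <- motif_masking_comparison(fx$model, res, cpds,
                                  motif_ranges = list(c(11, 20)),
                                  mode = "alanine", freqs = freqs,
                                  repeats = 3, n_samples = 40, seed = 5)
  expect_identical(nrow(cmp$masked), 3L)
  expect_identical(nrow(cmp$control), 3L)
  expect_s3_class(cmp$test, "stat_test_result")
  expect_gte(cmp$test$p_value, 0)
})
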