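# Sampling semantics and reproduction/memorization metrics.

test_that("reproduction counting is canonical, deduplicated and order-invariant", {
  expect_identical(count_reproduced(c("CCO", "CCO", "CCN"), "CCO"), 1L)
  expect_identical(count_reproduced(character(0), "CCO"), 0L)
  # canonicalization happens upstream in clm_sample; with raw canonical
  # input the equivalent spelling must be matched after canonicalization
  expect_identical(count_reproduced(canonical_smiles("OCC"), canonical_smiles("CCO")), 1L)
  s <- c("CCO", "CCN", "CCO", "c1ccccc1")
  expect_identical(count_reproduced(s, c("CCO", "c1ccccc1")),
                   count_reproduced(rev(s), c("c1ccccc1", "CCO")))
})

test_that("cores group analogs onto their series scaffold", {
  expect_identical(unname(extract_cores(c("Cc1ccccc1", "Clc1ccccc1"))[1]),
                   unname(extract_cores(c("Cc1ccccc1", "Clc1ccccc1"))[2]))
  # acyclic fallback
  expect_identical(unname(extract_cores("CCO")), canonical_smiles("CCO"))
  expect_warning(cores <- extract_cores(c("CCO", "C1CC(")), "unparseable")
  expect_length(cores, 1)

  u <- fix_small_universe()
  one_series <- u$compounds[u$compounds$series_id == u$compounds$series_id[1], ]
  cores <- extract_cores(one_series$smiles)
  expect_identical(unique(unname(cores)), one_series$scaffold[1])
})

test_that("memorization fraction and NN similarity match a brute-force oracle", {
  repro <- c("CCO", "CCN")
  train <- c("CCO", "CCCC", "c1ccccc1")
  m <- memorization_analysis(repro, train)
  expect_equal(m$fraction_in_training, 0.5)
  # NN of a compound identical to a training compound is 1
  expect_equal(max(morgan_tanimoto(rep("CCO", 3), train)), 1)
  # exhaustive double loop oracle on a 10-compound toy
  u <- fix_small_universe()
  repro10 <- u$compounds$smiles[1:4]
  train10 <- u$compounds$smiles[5:14]
  m10 <- memorization_analysis(repro10, train10)
  oracle <- mean(vapply(repro10, function(a)
    max(vapply(train10, function(b) morgan_tanimoto(a, b), numeric(1))),
    numeric(1)))
  expect_equal(m10$mean_nn_tanimoto, oracle, tolerance = 1e-12)
  # empty reproduced set: absent statistics
  m0 <- memorization_analysis(character(0), train)
  expect_true(is.na(m0$fraction_in_training))
  expect_true(is.na(m0$mean_nn_tanimoto))
})

test_that("sampling is seed-reproducible and respects the temperature contract", {
  fx <- fix_tiny_model()
  res <- fx$dataset$sequences$residues[
    match(fx$dataset$pairs$sequence_id[1], fx$dataset$sequences$sequence_id)]
  a <- clm_sample(fx$model, res, n = 50, temperature = 1, seed = 7)
  b <- clm_sample(fx$model, res, n = 50, temperature = 1, seed = 7)
  expect_identical(a$raw, b$raw)
  expect_error(clm_sample(fx$model, res, n = 10, temperature = 0), "positive")
  # temperature -> 0 approaches greedy argmax decoding
  cold <- clm_sample(fx$model, res, n = 20, temperature = 1e-6, seed = 1)
  expect_identical(unique(cold$raw), clm_greedy(fx$model, res))
})

test_that("multinomial frequencies match closed-form softmax on a fixed toy model", {
  # single-step model built by hand: all weights zero, so the first-step
  # logits equal the output bias. Bias fixes logits (2, 1, 0) on three
  # sampleable tokens ([end], C, N); pad/start are suppressed.
  cfg <- model_config(d_model = 8, n_heads = 2, n_encoder_layers = 1,
                      n_decoder_layers = 1, d_ff = 8, dropout = 0)
  params <- clmprobe:::.init_params(cfg, 4, 5)
  zero <- function(x) x * 0
  params <- clmprobe:::.tree_map(zero, params)
  # restore layer-norm gains (zeroed by the map above)
  params$enc[[1]]$ln1$g <- params$enc[[1]]$ln2$g <- rep(1, 8)
  params$dec[[1]]$ln1$g <- params$dec[[1]]$ln2$g <- params$dec[[1]]$ln3$g <- rep(1, 8)
  params$out$b <- c(-1e9, -1e9, 2, 1, 0)   # pad, start, end, C, N
  memory <- cpp_encode_memory(params, cfg, c(4L, 4L))
  n <- 10000
  toks <- with_seed(13, cpp_decode(params, cfg, memory, n, 1, 3,
                                   start_id = 2L, end_id = 3L, greedy = FALSE))
  first <- toks[, 1]
  probs <- exp(c(2, 1, 0)) / sum(exp(c(2, 1, 0)))   # over ids 3, 4, 5
  freq <- tabulate(first, 5)[3:5] / n
  se <- sqrt(probs * (1 - probs) / n)
  expect_true(all(abs(freq - probs) <= 3 * se))
  # different seeds give different draws from the same distribution
  fx <- fix_tiny_model()
  res <- fx$dataset$sequences$residues[1]
  s1 <- clm_sample(fx$model, res, n = 200, temperature = 1, seed = 3)
  s2 <- clm_sample(fx$model, res, n = 200, temperature = 1, seed = 4)
  expect_false(identical(s1$raw, s2$raw))
})

test_that("reproduction report applies the availability threshold", {
  fx <- fix_tiny_model()
  ds <- fx$dataset
  rep0 <- reproduction_report(fx$model, ds, ds, n = 30, min_compounds = 0, seed = 2)
  expect_true(all(rep0$n_uq_repro_compounds <= rep0$n_test_compounds))
  expect_true(all(rep0$validity_rate >= 0 & rep0$validity_rate <= 1))
  # threshold above the available counts excludes everything
  expect_warning(
    reproduction_report(fx$model, ds, ds, n = 10, min_compounds = 1000, seed = 2),
    "threshold")
})
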