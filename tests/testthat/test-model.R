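# Transformer correctness: gradients, loss semantics, reproducibility,
# memorization, and the R/C++ implementation equivalence.

tiny_cfg <- function() model_config(d_model = 8, n_heads = 2,
                                    n_encoder_layers = 2, n_decoder_layers = 2,
                                    d_ff = 12, dropout = 0)

tiny_batch <- function() {
  src <- clmprobe:::.stack_batch(list(c(4L, 5L, 6L, 4L), c(5L, 6L)))
  tgt <- list(c(2L, 4L, 5L, 3L), c(2L, 6L, 3L))
  list(src = src,
       tgt_in = clmprobe:::.stack_batch(lapply(tgt, function(x) x[-length(x)])),
       tgt_out = clmprobe:::.stack_batch(lapply(tgt, function(x) x[-1])))
}

# random parameters with a non-degenerate output head (the packaged init
# zeroes it, which would zero every upstream gradient at the test point)
tiny_params <- function(cfg, vs, vt) {
  p <- clmprobe:::.init_params(cfg, vs, vt)
  p$out$W <- matrix(rnorm(length(p$out$W), sd = 0.3), nrow(p$out$W))
  p$out$b <- rnorm(length(p$out$b), sd = 0.1)
  p
}

test_that("analytic gradients match finite differences", {
  set.seed(3)
  cfg <- tiny_cfg()
  params <- tiny_params(cfg, 6, 7)
  b <- tiny_batch()
  fw <- clmprobe:::.forward_batch(params, cfg, b$src, b$tgt_in, b$tgt_out, 0)
  gr <- clmprobe:::.backward_batch(params, cfg, fw)

  leaf_paths <- function(tree, cur = integer(0)) {
    if (is.list(tree)) do.call(c, lapply(seq_along(tree), function(i)
      leaf_paths(tree[[i]], c(cur, i))))
    else list(cur)
  }
  getl <- function(tree, path) { for (i in path) tree <- tree[[i]]; tree }
  setl <- function(tree, path, val) {
    if (length(path) == 1) { tree[[path]] <- val; tree }
    else { tree[[path[1]]] <- setl(tree[[path[1]]], path[-1], val); tree }
  }
  eps <- 1e-6
  set.seed(9)
  for (lp in sample(leaf_paths(params), 20)) {
    leaf <- getl(params, lp); gleaf <- getl(gr, lp)
    k <- which.max(abs(gleaf)); if (max(abs(gleaf)) < 1e-12) k <- 1
    p2 <- leaf; p2[k] <- p2[k] + eps
    up <- clmprobe:::.forward_batch(setl(params, lp, p2), cfg, b$src, b$tgt_in, b$tgt_out, 0)$loss
    p2[k] <- p2[k] - 2 * eps
    dn <- clmprobe:::.forward_batch(setl(params, lp, p2), cfg, b$src, b$tgt_in, b$tgt_out, 0)$loss
    num <- (up - dn) / (2 * eps)
    expect_lt(abs(num - gleaf[k]) / max(1e-6, abs(num) + abs(gleaf[k])), 1e-5)
  }
})

test_that("compiled kernels reproduce the reference implementation", {
  set.seed(3)
  cfg <- tiny_cfg()
  params <- tiny_params(cfg, 6, 7)
  b <- tiny_batch()
  fw <- clmprobe:::.forward_batch(params, cfg, b$src, b$tgt_in, b$tgt_out, 0)
  gr <- clmprobe:::.backward_batch(params, cfg, fw)
  cp <- cpp_train_batch(params, cfg, b$src$ids, b$src$off, b$src$len,
                        b$tgt_in$ids, b$tgt_in$off, b$tgt_in$len,
                        b$tgt_out$ids, 0, TRUE)
  expect_equal(cp$loss, fw$loss, tolerance = 1e-12)
  maxdiff <- 0
  walk <- function(a, b) {
    if (is.list(a)) {
      for (i in seq_along(a)) {
        key <- if (!is.null(names(a)) && nzchar(names(a)[i])) names(a)[i] else i
        walk(a[[i]], b[[key]])
      }
    } else maxdiff <<- max(maxdiff, max(abs(a - b)))
  }
  walk(gr, cp$grads)
  expect_lt(maxdiff, 1e-10)
  mem_r <- clmprobe:::.encode_memory(params, cfg, c(4L, 5L, 6L, 4L))
  mem_c <- cpp_encode_memory(params, cfg, c(4L, 5L, 6L, 4L))
  expect_equal(mem_r, mem_c, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("initial per-token loss is close to ln(vocabulary size)", {
  ds <- fix_small_dataset()
  src_vocab <- protein_vocabulary(max(nchar(ds$sequences$residues)))
  tgt_vocab <- smiles_vocabulary(unique(ds$pairs$smiles))
  V <- length(tgt_vocab$tokens)
  cfg <- model_config(d_model = 32, n_heads = 2, n_encoder_layers = 1,
                      n_decoder_layers = 1, d_ff = 64, dropout = 0)
  losses <- vapply(1:3, function(s) {
    state <- with_seed(s, list(params = clmprobe:::.init_params(
      cfg, length(src_vocab$tokens), V)))
    state <- structure(c(state, list(model_config = cfg, src_vocab = src_vocab,
                                     tgt_vocab = tgt_vocab)), class = "clm_model")
    clm_loss(state, ds)
  }, numeric(1))
  # near-uniform output at random init: loss about ln V (within 2%)
  expect_lt(abs(mean(losses) - log(V)) / log(V), 0.02)
})

test_that("training is reproducible given the seed and input order", {
  ds <- fix_small_dataset()
  keep <- ds$pairs[1:8, ]
  tiny <- pair_dataset(keep, ds$sequences)
  mcfg <- model_config(d_model = 16, n_heads = 2, n_encoder_layers = 1,
                       n_decoder_layers = 1, d_ff = 32, dropout = 0.1)
  tcfg <- train_config(epochs = 2, batch_size = 4, val_fraction = 0, seed = 21)
  m1 <- clm_pretrain(tiny, mcfg, tcfg)
  m2 <- clm_pretrain(tiny, mcfg, tcfg)
  expect_identical(m1$params, m2$params)
  # permuting the input pair order must not change the result: shuffling
  # is owned by the seed, not the presentation order
  perm <- pair_dataset(keep[sample(nrow(keep)), ], ds$sequences)
  m3 <- clm_pretrain(perm, mcfg, tcfg)
  expect_identical(m1$params, m3$params)
})

test_that("a converged model memorizes its toy corpus", {
  fx <- fix_tiny_model()
  loss <- clm_loss(fx$model, fx$dataset)
  expect_lt(loss, 0.05)
  # greedy decoding reproduces a trained pair's compound exactly
  sid <- fx$dataset$pairs$sequence_id[1]
  res <- fx$dataset$sequences$residues[match(sid, fx$dataset$sequences$sequence_id)]
  out <- clm_greedy(fx$model, res)
  expect_true(out %in% fx$dataset$pairs$smiles[fx$dataset$pairs$sequence_id == sid])
})

test_that("fine-tuning validates leakage and chains provenance", {
  fx <- fix_tiny_model()
  ds <- fx$dataset
  fam <- ds$sequences$family[match(ds$pairs$sequence_id, ds$sequences$sequence_id)]
  fam_ds <- pair_dataset(ds$pairs[fam == fam[1], ], ds$sequences)
  ft <- clm_finetune(fx$model, fam_ds,
                     train_config(epochs = 2, batch_size = 4, val_fraction = 0, seed = 2))
  expect_identical(ft$provenance$kind, "finetuned")
  expect_identical(ft$provenance$parent_hash, clmprobe:::.params_hash(fx$model))
  # pre-trained state untouched
  expect_lt(clm_loss(fx$model, ds), 0.05)

  outside <- pair_dataset(
    data.frame(sequence_id = ds$pairs$sequence_id[1], smiles = "CCCCCCCCCC"),
    ds$sequences)
  expect_error(clm_finetune(fx$model, outside), "leakage")
  empty <- ds$pairs[0, ]
  expect_error(clm_finetune(fx$model, pair_dataset(empty, ds$sequences)), "empty")
})

test_that("checkpoints round-trip with a JSON sidecar", {
  fx <- fix_tiny_model()
  f <- tempfile()
  clm_save(fx$model, f)
  back <- clm_load(f)
  expect_identical(back$params, fx$model$params)
  side <- jsonlite::read_json(paste0(f, ".json"))
  expect_identical(side$kind, "pretrained")
  expect_identical(side$tgt_vocab_size, length(fx$model$tgt_vocab$tokens))
})

test_that("vocabulary mismatches error before training", {
  ds <- fix_small_dataset()
  tiny <- pair_dataset(ds$pairs[1:4, ], ds$sequences)
  # vocabulary lacking ring/halogen tokens (ample max_length)
  bad_vocab <- smiles_vocabulary("CCO", max_length = 100)
  expect_error(
    clm_pretrain(tiny, tiny_cfg(), train_config(epochs = 1),
                 vocabs = list(src = protein_vocabulary(100), tgt = bad_vocab)),
    "unknown token")
})
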