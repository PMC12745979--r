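# User-facing model interface: configuration, pre-training, family
# fine-tuning, and sampling, wrapped in a classed model object.

#' Transformer architecture configuration
#'
#' Desk-scale defaults: model dimension 128, 4 attention heads, 3 encoder
#' and 3 decoder layers, feed-forward dimension 256, dropout 0.1 — the
#' smallest configuration that reliably memorizes the synthetic corpora.
#' Every value can be overridden.
#'
#' @param d_model model dimension (divisible by \code{n_heads}).
#' @param n_heads attention heads.
#' @param n_encoder_layers,n_decoder_layers layer counts.
#' @param d_ff feed-forward inner dimension.
#' @param dropout dropout rate applied to embeddings and sublayer outputs
#'   during training.
#' @return a \code{model_config}.
#' @export
model_config <- function(d_model = 128, n_heads = 4, n_encoder_layers = 3,
                         n_decoder_layers = 3, d_ff = 256, dropout = 0.1) {
  if (d_model %% n_heads != 0) stop("d_model must be divisible by n_heads")
  if (any(c(d_model, n_heads, n_encoder_layers, n_decoder_layers, d_ff) <= 0))
    stop("all architecture counts must be positive")
  structure(list(d_model = as.integer(d_model), n_heads = as.integer(n_heads),
                 n_encoder_layers = as.integer(n_encoder_layers),
                 n_decoder_layers = as.integer(n_decoder_layers),
                 d_ff = as.integer(d_ff), dropout = dropout),
            class = "model_config")
}

#' Training configuration
#'
#' Adam with a triangular cyclic learning-rate schedule (base 1e-4, max
#' 1e-3, cycle of 4 epochs), teacher-forced cross-entropy with padding
#' excluded, optional early stopping on validation loss.
#'
#' @param epochs training epochs.
#' @param batch_size pairs per optimizer step.
#' @param base_lr,max_lr cyclic learning-rate bounds.
#' @param cycle_epochs epochs per learning-rate cycle.
#' @param mode "triangular" or "triangular2" (halving amplitude).
#' @param beta1,beta2,eps Adam moment parameters.
#' @param val_fraction fraction of pairs held out for validation loss.
#' @param patience epochs without validation improvement before stopping
#'   (Inf disables early stopping).
#' @param seed integer seed owning initialization, shuffling and dropout.
#' @return a \code{train_config}.
#' @export
train_config <- function(epochs = 30, batch_size = 32, base_lr = 1e-4,
                         max_lr = 1e-3, cycle_epochs = 4,
                         mode = c("triangular", "triangular2"),
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         val_fraction = 0.1, patience = Inf, seed = 1) {
  mode <- match.arg(mode)
  if (base_lr > max_lr) stop("base_lr must not exceed max_lr")
  if (epochs <= 0 || batch_size <= 0 || cycle_epochs <= 0)
    stop("epochs, batch_size and cycle_epochs must be positive")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 base_lr = base_lr, max_lr = max_lr,
                 cycle_epochs = cycle_epochs, mode = mode,
                 beta1 = beta1, beta2 = beta2, eps = eps,
                 val_fraction = val_fraction, patience = patience,
                 seed = as.integer(seed)),
            class = "train_config")
}

# Deterministic key for a set of pairs (order-independent).
.pair_keys <- function(dataset) {
  sort(paste(dataset$pairs$sequence_id, dataset$pairs$smiles, sep = "\r"))
}

.dataset_hash <- function(dataset) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(.pair_keys(dataset), f)
  unname(tools::md5sum(f))
}

# Encode a dataset against frozen vocabularies; errors on unknown tokens.
.encode_dataset <- function(dataset, src_vocab, tgt_vocab) {
  # deterministic canonical order so results do not depend on input order
  ord <- order(dataset$pairs$sequence_id, dataset$pairs$smiles)
  pairs <- dataset$pairs[ord, , drop = FALSE]
  res <- dataset$sequences$residues[match(pairs$sequence_id,
                                          dataset$sequences$sequence_id)]
  uniq_res <- unique(res)
  enc_res <- lapply(uniq_res, function(r) {
    e <- encode_protein(src_vocab, r)
    e[e != src_vocab$pad]
  })
  uniq_smi <- unique(pairs$smiles)
  enc_smi <- lapply(uniq_smi, function(s) {
    e <- encode_smiles(tgt_vocab, s)
    e[e != tgt_vocab$pad]
  })
  list(src = enc_res[match(res, uniq_res)],
       tgt = enc_smi[match(pairs$smiles, uniq_smi)],
       pairs = pairs)
}

.train_loop <- function(params, mcfg, tcfg, enc, opt = NULL) {
  n <- length(enc$src)
  n_val <- floor(tcfg$val_fraction * n)
  val_idx <- if (n_val > 0) sample.int(n, n_val) else integer(0)
  fit_idx <- setdiff(seq_len(n), val_idx)
  steps_per_epoch <- max(1, ceiling(length(fit_idx) / tcfg$batch_size))
  cycle_steps <- tcfg$cycle_epochs * steps_per_epoch
  if (is.null(opt)) {
    opt <- list(m = .zero_like(params), v = .zero_like(params), t = 0,
                beta1 = tcfg$beta1, beta2 = tcfg$beta2, eps = tcfg$eps)
  }
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_val <- Inf; best_params <- params; stale <- 0; step <- 0

  val_batch <- if (n_val > 0) .make_batch(enc, val_idx) else NULL
  for (epoch in seq_len(tcfg$epochs)) {
    ord <- sample(fit_idx)
    tot_loss <- 0; tot_tok <- 0
    for (b in seq_len(steps_per_epoch)) {
      idx <- ord[((b - 1) * tcfg$batch_size + 1):min(b * tcfg$batch_size, length(ord))]
      idx <- idx[!is.na(idx)]
      if (length(idx) == 0) next
      batch <- .make_batch(enc, idx)
      step <- step + 1
      lr <- .cyclic_lr(step, tcfg$base_lr, tcfg$max_lr, cycle_steps, tcfg$mode)
      fw <- cpp_train_batch(params, mcfg,
                            batch$src$ids, batch$src$off, batch$src$len,
                            batch$tgt_in$ids, batch$tgt_in$off, batch$tgt_in$len,
                            batch$tgt_out$ids, mcfg$dropout, TRUE)
      st <- .adam_step(opt, params, fw$grads, lr)
      opt <- st$opt; params <- st$params
      tot_loss <- tot_loss + fw$loss * fw$n_tokens; tot_tok <- tot_tok + fw$n_tokens
    }
    val_loss <- NA_real_
    if (!is.null(val_batch)) {
      val_loss <- cpp_train_batch(params, mcfg,
                                  val_batch$src$ids, val_batch$src$off, val_batch$src$len,
                                  val_batch$tgt_in$ids, val_batch$tgt_in$off,
                                  val_batch$tgt_in$len, val_batch$tgt_out$ids,
                                  0, FALSE)$loss
      if (val_loss < best_val - 1e-6) {
        best_val <- val_loss; best_params <- params; stale <- 0
      } else stale <- stale + 1
    }
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tot_loss / tot_tok,
                                         val_loss = val_loss))
    if (!is.null(val_batch) && stale >= tcfg$patience) break
  }
  if (is.finite(best_val)) params <- best_params
  list(params = params, opt = opt, history = history)
}

.make_batch <- function(enc, idx) {
  src <- .stack_batch(enc$src[idx])
  tgt_in <- .stack_batch(lapply(enc$tgt[idx], function(x) x[-length(x)]))
  tgt_out <- .stack_batch(lapply(enc$tgt[idx], function(x) x[-1]))
  list(src = src, tgt_in = tgt_in, tgt_out = tgt_out)
}

#' Pre-train a sequence-to-compound transformer
#'
#' Teacher-forced training on sequence-compound pairs: the encoder consumes
#' residue tokens, the decoder SMILES tokens, and the loss is next-token
#' cross-entropy (padding never contributes; sequences are processed at
#' their true lengths). Vocabularies are corpus-derived here and frozen for
#' any later fine-tuning. Fully reproducible given the training seed.
#'
#' @param dataset a \code{pair_dataset} (the training side of a split).
#' @param mcfg a \code{model_config}.
#' @param tcfg a \code{train_config}.
#' @param vocabs optional list(src, tgt) of frozen vocabularies; by default
#'   built from \code{dataset}.
#' @return a \code{clm_model}: parameters, configs, vocabularies, training
#'   provenance (dataset hash, loss trajectory).
#' @export
clm_pretrain <- function(dataset, mcfg = model_config(), tcfg = train_config(),
                         vocabs = NULL) {
  stopifnot(inherits(dataset, "pair_dataset"))
  if (nrow(dataset$pairs) == 0) stop("cannot train on an empty dataset")
  if (is.null(vocabs)) {
    src_vocab <- protein_vocabulary(max(nchar(dataset$sequences$residues)))
    tgt_vocab <- smiles_vocabulary(unique(dataset$pairs$smiles))
  } else {
    src_vocab <- vocabs$src; tgt_vocab <- vocabs$tgt
  }
  # vocabulary mismatch surfaces before any training
  enc <- .encode_dataset(dataset, src_vocab, tgt_vocab)
  out <- with_seed(tcfg$seed, {
    params <- .init_params(mcfg, length(src_vocab$tokens), length(tgt_vocab$tokens))
    .train_loop(params, mcfg, tcfg, enc)
  })
  structure(list(params = out$params, model_config = mcfg, train_config = tcfg,
                 src_vocab = src_vocab, tgt_vocab = tgt_vocab,
                 provenance = list(kind = "pretrained",
                                   dataset_hash = .dataset_hash(dataset),
                                   train_keys = .pair_keys(dataset),
                                   history = out$history,
                                   parent_hash = NULL)),
            class = "clm_model")
}

#' Fine-tune on a protein family
#'
#' Continues training from a pre-trained model using only pairs from a
#' specific family extracted from the pre-training training set. Pairs not
#' contained in the parent's training side raise a leakage error. The
#' parent model is left intact; provenance chains to it.
#'
#' @param state a pre-trained \code{clm_model}.
#' @param family_pairs a \code{pair_dataset} restricted to one family,
#'   subset of the pre-training training set.
#' @param tcfg a \code{train_config} for the fine-tuning phase.
#' @return a new \code{clm_model}.
#' @export
clm_finetune <- function(state, family_pairs, tcfg = train_config(epochs = 10)) {
  stopifnot(inherits(state, "clm_model"), inherits(family_pairs, "pair_dataset"))
  if (nrow(family_pairs$pairs) == 0) stop("cannot fine-tune on an empty family set")
  leaked <- setdiff(.pair_keys(family_pairs), state$provenance$train_keys)
  if (length(leaked) > 0) {
    stop(sprintf("leakage error: %d fine-tuning pairs are not part of the pre-training training set",
                 length(leaked)))
  }
  enc <- .encode_dataset(family_pairs, state$src_vocab, state$tgt_vocab)
  out <- with_seed(tcfg$seed, .train_loop(state$params, state$model_config, tcfg, enc))
  structure(list(params = out$params, model_config = state$model_config,
                 train_config = tcfg,
                 src_vocab = state$src_vocab, tgt_vocab = state$tgt_vocab,
                 provenance = list(kind = "finetuned",
                                   dataset_hash = .dataset_hash(family_pairs),
                                   train_keys = state$provenance$train_keys,
                                   history = out$history,
                                   parent_hash = .params_hash(state))),
            class = "clm_model")
}

.params_hash <- function(state) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(state$params, f)
  unname(tools::md5sum(f))
}

#' @export
print.clm_model <- function(x, ...) {
  mc <- x$model_config
  h <- x$provenance$history
  cat(sprintf("<clm_model (%s): d=%d, %d heads, %d+%d layers, ff=%d | vocab %d/%d>\n",
              x$provenance$kind, mc$d_model, mc$n_heads, mc$n_encoder_layers,
              mc$n_decoder_layers, mc$d_ff,
              length(x$src_vocab$tokens), length(x$tgt_vocab$tokens)))
  if (nrow(h) > 0) {
    cat(sprintf("  %d epochs trained; final train loss %.4f, val loss %s\n",
                nrow(h), h$train_loss[nrow(h)],
                ifelse(is.na(h$val_loss[nrow(h)]), "-",
                       sprintf("%.4f", h$val_loss[nrow(h)]))))
  }
  invisible(x)
}

#' @export
summary.clm_model <- function(object, ...) {
  n_par <- 0
  .tree_map(function(x) { n_par <<- n_par + length(x); x }, object$params)
  cat(sprintf("clm_model with %s parameters\n", format(n_par, big.mark = ",")))
  print(object)
  invisible(object$provenance$history)
}

#' Teacher-forced cross-entropy loss of a model on a dataset
#'
#' Per-token loss in nats, padding excluded; inference mode (no dropout).
#'
#' @param state a \code{clm_model}.
#' @param dataset a \code{pair_dataset}.
#' @return scalar loss.
#' @export
clm_loss <- function(state, dataset) {
  enc <- .encode_dataset(dataset, state$src_vocab, state$tgt_vocab)
  batch <- .make_batch(enc, seq_along(enc$src))
  cpp_train_batch(state$params, state$model_config,
                  batch$src$ids, batch$src$off, batch$src$len,
                  batch$tgt_in$ids, batch$tgt_in$off, batch$tgt_in$len,
                  batch$tgt_out$ids, 0, FALSE)$loss
}

#' Sample compound strings for a sequence
#'
#' The decoder starts from \code{[start]} and recursively generates tokens
#' by multinomial sampling with the given temperature (logits are divided
#' by the temperature before the softmax); generation stops at \code{[end]}
#' or the vocabulary's maximum length. Seed-reproducible; duplicate draws
#' are expected and meaningful.
#'
#' @param state a \code{clm_model}.
#' @param residues amino-acid string (the test sequence).
#' @param n number of output strings (2,500 default; 5,000 extended).
#' @param temperature positive sampling temperature (1 = model
#'   distribution).
#' @param seed integer seed.
#' @param canonicalize validate and canonicalize the raw strings (default).
#'   \code{FALSE} skips the cheminformatics round trip and leaves
#'   \code{valid_canonical} empty — used by experiment drivers that batch
#'   canonicalization over many sampling runs.
#' @return a \code{sample_set}: raw output strings, the valid canonical
#'   subset, and sampling metadata.
#' @export
clm_sample <- function(state, residues, n = 2500, temperature = 1, seed = 1,
                       canonicalize = TRUE) {
  stopifnot(inherits(state, "clm_model"), n > 0)
  if (temperature <= 0) stop("temperature must be positive")
  src_ids <- encode_protein(state$src_vocab, residues)
  src_ids <- src_ids[src_ids != state$src_vocab$pad]
  cfg <- state$model_config
  raw <- with_seed(seed, {
    memory <- cpp_encode_memory(state$params, cfg, src_ids)
    toks <- cpp_decode(state$params, cfg, memory, n, temperature,
                       max_steps = state$tgt_vocab$max_length,
                       start_id = state$tgt_vocab$start,
                       end_id = state$tgt_vocab$end, greedy = FALSE)
    apply(toks, 1, function(row) {
      stop_at <- match(state$tgt_vocab$end, row)
      keep <- row[seq_len(if (is.na(stop_at)) length(row) else stop_at - 1)]
      paste(state$tgt_vocab$tokens[keep], collapse = "")
    })
  })
  if (!canonicalize) {
    return(structure(list(raw = raw, valid_canonical = character(0),
                          validity_rate = NA_real_, n = n,
                          temperature = temperature, seed = seed),
                     class = "sample_set"))
  }
  canon <- canonical_or_na(raw)
  structure(list(raw = raw, valid_canonical = canon[!is.na(canon)],
                 validity_rate = mean(!is.na(canon)),
                 n = n, temperature = temperature, seed = seed),
            class = "sample_set")
}

#' @export
print.sample_set <- function(x, ...) {
  cat(sprintf("<sample_set: %d draws, %.1f%% valid (%d unique canonical), T=%g>\n",
              x$n, 100 * x$validity_rate, length(unique(x$valid_canonical)),
              x$temperature))
  invisible(x)
}

#' Greedy decode (argmax at every step)
#'
#' Exposed mainly for memorization checks in tests; sampling semantics for
#' evaluation live in \code{\link{clm_sample}}.
#'
#' @param state a \code{clm_model}.
#' @param residues amino-acid string.
#' @return single decoded string.
#' @export
clm_greedy <- function(state, residues) {
  src_ids <- encode_protein(state$src_vocab, residues)
  src_ids <- src_ids[src_ids != state$src_vocab$pad]
  memory <- cpp_encode_memory(state$params, state$model_config, src_ids)
  toks <- cpp_decode(state$params, state$model_config, memory, 1, 1,
                     max_steps = state$tgt_vocab$max_length,
                     start_id = state$tgt_vocab$start,
                     end_id = state$tgt_vocab$end, greedy = TRUE)
  row <- toks[1, ]
  stop_at <- match(state$tgt_vocab$end, row)
  keep <- row[seq_len(if (is.na(stop_at)) length(row) else stop_at - 1)]
  paste(state$tgt_vocab$tokens[keep], collapse = "")
}

#' Save / load a model checkpoint
#'
#' Parameters go to an RDS file, configuration and provenance to a JSON
#' sidecar so checkpoints remain inspectable.
#'
#' @param state a \code{clm_model}.
#' @param path checkpoint path (".rds" appended if absent).
#' @export
clm_save <- function(state, path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  saveRDS(state, path)
  side <- list(model_config = unclass(state$model_config),
               train_config = unclass(state$train_config),
               kind = state$provenance$kind,
               dataset_hash = state$provenance$dataset_hash,
               parent_hash = state$provenance$parent_hash,
               src_vocab_size = length(state$src_vocab$tokens),
               tgt_vocab_size = length(state$tgt_vocab$tokens))
  jsonlite::write_json(side, sub("\\.rds$", ".json", path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname clm_save
#' @export
clm_load <- function(path) {
  if (!grepl("\\.rds$", path)) path <- paste0(path, ".rds")
  readRDS(path)
}
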