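# Heavy shared fixtures for the end-to-end control experiments: one study
# universe per regime and one trained model per partitioning scheme.
# Built lazily and memoised so every test block reuses the same models.

acc_seed <- 1L

acc_mcfg <- function() model_config(d_model = 64, n_heads = 4,
                                    n_encoder_layers = 2, n_decoder_layers = 2,
                                    d_ff = 128, dropout = 0)

acc_tcfg <- function(epochs, seed) {
  train_config(epochs = epochs, batch_size = 16, base_lr = 3e-4, max_lr = 3e-3,
               cycle_epochs = 4, val_fraction = 0.05, seed = seed)
}

acc_universe <- function() memo("acc_universe", function()
  generate_universe(universe_config(seed = 42)))

acc_coupled_universe <- function() memo("acc_coupled_universe", function()
  generate_universe(universe_config(motif_coupled = TRUE, seed = 43)))

acc_splits <- function() memo("acc_splits", function() {
  ds <- as_pair_dataset(acc_universe())
  d0 <- dilute_mt(ds, 0, seed = acc_seed)
  list(ds = ds,
       seq = split_by_sequence(ds, split_plan("sequence", seed = acc_seed)),
       fam = split_by_family(ds, split_plan("family", seed = acc_seed)),
       mt0 = split_by_sequence(d0, split_plan("sequence", seed = acc_seed)))
})

acc_model_seq <- function() memo("acc_model_seq", function()
  clm_pretrain(acc_splits()$seq$train, acc_mcfg(), acc_tcfg(30, 5)))

acc_model_fam <- function() memo("acc_model_fam", function()
  clm_pretrain(acc_splits()$fam$train, acc_mcfg(), acc_tcfg(30, 5)))

acc_model_mt0 <- function() memo("acc_model_mt0", function()
  clm_pretrain(acc_splits()$mt0$train, acc_mcfg(), acc_tcfg(30, 5)))

acc_coupled_split <- function() memo("acc_coupled_split", function() {
  ds <- as_pair_dataset(acc_coupled_universe())
  split_by_sequence(ds, split_plan("sequence", seed = acc_seed))
})

acc_model_coupled <- function() memo("acc_model_coupled", function()
  clm_pretrain(acc_coupled_split()$train, acc_mcfg(), acc_tcfg(30, 5)))

# The k most compound-rich test sequences, restricted to distinct families
# when families = TRUE (the perturbation experiments probe one sequence
# per family, mirroring the two-family design of the original figures).
acc_top_sequences <- function(split, k, families = FALSE) {
  tt <- sort(table(split$test$pairs$sequence_id), decreasing = TRUE)
  if (!families) return(names(tt)[seq_len(k)])
  sids <- character(0); fams <- character(0)
  for (sid in names(tt)) {
    f <- split$test$sequences$family[match(sid, split$test$sequences$sequence_id)]
    if (!(f %in% fams)) { sids <- c(sids, sid); fams <- c(fams, f) }
    if (length(sids) == k) break
  }
  sids
}

acc_family_train <- function(split, family) {
  fam_of_pair <- split$train$sequences$family[
    match(split$train$pairs$sequence_id, split$train$sequences$sequence_id)]
  pair_dataset(split$train$pairs[fam_of_pair == family, , drop = FALSE],
               split$train$sequences)
}

# Fine-tuned model for the family owning a given test sequence. Deep
# fine-tuning (40 epochs, small batches, decaying cyclic amplitude)
# drives the family corpus into the memorization regime the experiments
# probe: per-token loss ~0.15, where sampled strings are dominated by
# exact training compounds.
acc_finetune_for <- function(model, split, sid) {
  fam <- split$test$sequences$family[match(sid, split$test$sequences$sequence_id)]
  memo(paste0("ft_", substr(model$provenance$dataset_hash, 1, 8), "_", fam), function()
    clm_finetune(model, acc_family_train(split, fam),
                 train_config(epochs = 40, batch_size = 8, base_lr = 3e-4,
                              max_lr = 3e-3, cycle_epochs = 8,
                              mode = "triangular2", val_fraction = 0, seed = 6)))
}

# Probe sequences for the perturbation experiments: reproduction is
# carried by MT compounds leaked into training, so the strongest probes
# are the test sequences with the most leaked compounds — known exactly
# by construction, no model in the loop. One sequence per family for
# breadth, the two strongest overall.
acc_probe_sequences <- function(split, k = 2) {
  train_cpds <- unique(split$train$pairs$smiles)
  counts <- table(split$test$pairs$sequence_id[
    split$test$pairs$smiles %in% train_cpds])
  ranked <- names(sort(counts, decreasing = TRUE))
  sids <- character(0); fams <- character(0)
  for (sid in ranked) {
    f <- split$test$sequences$family[match(sid, split$test$sequences$sequence_id)]
    if (!(f %in% fams)) { sids <- c(sids, sid); fams <- c(fams, f) }
    if (length(sids) == k) break
  }
  sids
}

acc_probe_set <- function(model, split, key, k = 2) {
  memo(paste0("probe_", key), function() {
    lapply(acc_probe_sequences(split, k), function(sid)
      list(sid = sid, ft = acc_finetune_for(model, split, sid)))
  })
}

acc_test_compounds <- function(split, sid) {
  unique(split$test$pairs$smiles[split$test$pairs$sequence_id == sid])
}

acc_residues <- function(split, sid) {
  split$test$sequences$residues[match(sid, split$test$sequences$sequence_id)]
}

# Total unique exactly reproduced compounds (and cores) over a set of
# test sequences at 2,500 samples each.
acc_reproduction_total <- function(model, split, sids, n = 2500, with_cores = FALSE) {
  tot_c <- 0L; tot_k <- 0L
  for (sid in sids) {
    ss <- clm_sample(model, acc_residues(split, sid), n = n, temperature = 1,
                     seed = derive_seed(acc_seed, paste0("acc_", sid)))
    got <- unique(ss$valid_canonical)
    cpds <- acc_test_compounds(split, sid)
    tot_c <- tot_c + length(intersect(got, cpds))
    if (with_cores) {
      tot_k <- tot_k + length(intersect(unique(unname(extract_cores(got))),
                                        unique(unname(extract_cores(cpds)))))
    }
  }
  list(compounds = tot_c, cores = tot_k)
}
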