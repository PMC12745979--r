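# Shared fixtures, built once per test run and memoised. Everything is
# generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

# Default desk-scale universe (the study conditions).
fix_universe <- function() memo("universe", function() {
  generate_universe(universe_config())
})

fix_dataset <- function() memo("dataset", function() as_pair_dataset(fix_universe()))

# A small universe for cheap structural tests.
fix_small_universe <- function() memo("small_universe", function() {
  generate_universe(universe_config(
    n_families = 2, sequences_per_family = 4, sequence_length = 40,
    motif_range = c(11, 20), n_series_per_family = 3, analogs_per_series = 10,
    compounds_per_sequence = 5, mt_fraction = 0.3, mt_mean_multiplicity = 2.5,
    seed = 7))
})

fix_small_dataset <- function() memo("small_dataset", function() {
  as_pair_dataset(fix_small_universe())
})

# A tiny memorizable corpus and a model trained on it: used by sampling,
# loss and decoding semantics tests. One compound per sequence, so the
# conditional entropy is zero and a converged model drives the loss to
# the optimization floor.
fix_tiny_model <- function() memo("tiny_model", function() {
  ds <- fix_small_dataset()
  keep <- ds$pairs[!duplicated(ds$pairs$sequence_id), ]
  tiny <- pair_dataset(keep, ds$sequences)
  mcfg <- model_config(d_model = 48, n_heads = 4, n_encoder_layers = 1,
                       n_decoder_layers = 1, d_ff = 96, dropout = 0)
  tcfg <- train_config(epochs = 200, batch_size = 5, base_lr = 4e-4,
                       max_lr = 4e-3, cycle_epochs = 10, val_fraction = 0,
                       seed = 11)
  list(model = clm_pretrain(tiny, mcfg, tcfg), dataset = tiny)
})

expect_no_violations <- function(universe) {
  v <- validate_universe(universe)
  expect_length(v, 0)
}
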