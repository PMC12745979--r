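---
title: "Probing what sequence-conditioned chemical language models learn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Probing what sequence-conditioned chemical language models learn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The question this package answers

Sequence-to-compound transformers take a protein's amino-acid sequence and
generate SMILES strings of compounds predicted to be active against it.
Reported successes of such models — exact regeneration of held-out active
compounds — admit two very different explanations: the model has learned
something about how sequences determine ligand chemistry, or the model is a
Clever Hans predictor that exploits statistical regularities of the
training corpus, above all *multi-target (MT) compounds*: molecules active
against several proteins, which place the same compound string on both
sides of a train/test split through different sequences.

`clmprobe` is a desk-scale harness for separating those explanations. It
implements the full control-experiment loop — corpus curation, two
partitioning schemes, MT dilution, scaled-down transformer training,
sampling-based reproduction metrics, cumulative sequence randomization, and
motif masking with statistical evaluation — against a *synthetic*
sequence-compound universe whose ground truth is known by construction.
Every phenomenon the harness is meant to detect (leakage, memorization,
motif reliance) can therefore be switched on and off deliberately, which is
what makes the negative results interpretable.

## The synthetic universe

`generate_universe()` builds:

* **Families.** Each protein family descends from a random ancestor
  sequence; members are derived by point substitutions (uniform over the 19
  alternative residues) calibrated so that pairwise identity within a
  family is about the configured level (default 0.95 — tight families, so
  that a held-out member's compound set is learnable from its relatives
  and compound retrieval is a family-level association rather than a
  per-sequence lookup; with looser families the few variable positions
  dominate retrieval and positional controls acquire an outsized,
  unrealistic effect). Sequences default
  to 80 residues, which keeps transformer training on a single CPU in the
  minutes range while leaving 6 cumulative-randomization segments of 15
  residues; the corpus being emulated caps sequences at 1,000 residues.
* **Motifs.** A fixed 9-residue motif (default range 36–44) is written
  verbatim into every member of the owning family, mirroring ProSite-style
  family signatures with 1-based inclusive coordinates. The length is kept
  proportionate: real signatures span 9–17 residues of sequences 5–15x
  longer, and a motif that covered a fifth of the sequence would turn
  motif masking into large-segment randomization — a different
  experiment.
* **Compounds.** Analog series are substituted two-ring scaffolds: a host
  ring (benzene, pyridine, cyclohexane or oxane) with three substituent
  sites, a linker (bond, C, CC, O, N), and a terminal ring with one more
  site. The grammar guarantees chemical validity, canonical uniqueness,
  and a known Bemis–Murcko core per series. With 32 short substituents
  over 4 sites the analog space per scaffold exceeds 10^6, so sampling a
  few thousand strings cannot hit a specific unseen analog by substituent
  recombination — the sparse-chemistry regime that makes the
  zero-reproduction control meaningful. Each family owns one host ring
  and a private subset of the twelve terminal rings (which are
  deliberately different ring types from the hosts): a family-split model
  has then never seen either ring of a held-out family's scaffolds and
  cannot reproduce a test core by recombining building blocks, mirroring
  how real family-specific chemotypes are not reachable by trivial
  recombination of other families' fragments.
* **MT structure.** A configured fraction of unique compounds (default
  0.29) is paired with additional sequences, preferentially within the
  owning family; multiplicities are drawn from a geometric distribution
  shifted to support ≥ 2 and tuned to the configured mean (default 2.91).
  These defaults are the corpus shape reported for the curated
  ChEMBL-scale dataset the harness emulates (29% MT compounds, mean 2.91
  sequences per MT compound), and the generator is tested to match them
  within ±10% relative tolerance.
* **The `motif_coupled` switch.** By default, series ownership follows the
  family: the whole sequence carries the signal that selects the family's
  chemistry, and the motif is redundant — so motif masking *should not*
  matter, which is the negative result the harness must be able to
  confirm. With `motif_coupled = TRUE`, each family carries two motif
  variants and series ownership follows the variant: the motif is then the
  *only* discriminating signal and masking it *must* hurt. A harness that
  cannot detect the positive control would prove nothing with the negative
  one.

What the generator deliberately does not emulate: real protein evolution
(only the identity level matters for the questions asked), bioactivity
values beyond what curation needs, three-dimensional structure, and the
heavy-tailed compound-per-target distributions of real corpora. Passing
tests therefore demonstrate that the *pipeline logic* — leakage channels,
dilution arithmetic, perturbation protocols, statistics — behaves as
specified, not that any particular real model is or is not memorizing.

## Curation rules

`filter_records()` applies the record-level filters of ChEMBL-style
curation: confidence score 9, direct binding assays only, not flagged by
the public anti-target/interference/aggregator filters (reduced to a
boolean input flag, since those filters are external resources), compound
molecular weight at most 1,000 Da, and target length at most 1,000
residues. Records for the same (compound, target) whose activity values do
not fall into the same order of magnitude are dropped as a group. "Same
order of magnitude" is implemented as max/min ≤ 10 by default: the
alternative floor-log10 binning (also available, `magnitude_rule =
"log10"`) makes 9.9 nM and 10.1 nM "different orders", which is fragile at
decade boundaries, whereas the ratio rule is monotone and scale-free.
`build_pairs()` canonicalizes compounds to nonisomeric SMILES (stereo and
isotopes dropped — two stereoisomers are one compound at this resolution),
deduplicates pairs, and annotates per-compound multiplicity.

## Partitioning and MT dilution

Both schemes target a 70%/30% split. Sequence-based partitioning divides
sequences (with all their pairs) at random; MT compounds may then appear on
both sides through different sequences — this is the leakage channel under
study, left open on purpose. Family-based partitioning assigns whole
families to one side, packing the training side's *pair count* (pairs are
the training unit, so the 70/30 ratio is targeted on pairs, not family
counts) as close to 70% as whole families allow; an exact subset search is
used up to 12 families, a greedy descending heuristic beyond.

`dilute_mt()` converts a fraction of MT compounds into single-target
compounds by keeping one pair (uniformly chosen) and removing the rest —
for a compound with three targets, two pairs are removed. Conversion order
and kept pairs derive from the seed alone, so the converted sets are
*nested* across retain levels (every compound converted at 75% retained is
also converted at 50%, 25% and 0%), making the dilution trend monotone in
expectation and comparable across levels. Dilution is applied to the full
dataset before sequence splitting, which guarantees that a converted
compound survives in exactly one pair across train ∪ test; the default
schedule {100, 75, 50, 25, 0}% retained is anchored at its endpoints by the
design being emulated, with the interior levels an even grid.

## Encodings and the model

Compounds are tokenized with the published atom-level regular expression
(bracket atoms, `Cl`/`Br` two-letter tokens, `%nn` ring closures);
tokenization is lossless and unknown characters are a named error, not a
silent UNK — the vocabulary is corpus-derived and frozen at pre-training.
Sequences use the 20-letter IUPAC alphabet (extended codes B/Z/X/U/O are
rejected by default; a permissive switch maps them to X). Both channels get
`[start]`/`[end]`/`[pad]` specials at fixed indices and sinusoidal
positional encodings with base 10,000.

The model is the original encoder-decoder transformer, scaled down:
default dimension 128, 4 heads, 3+3 layers, feed-forward 256, dropout 0.1
— the smallest configuration that reliably memorizes synthetic corpora,
with every value overridable (the study runs in the test suite use
64/4/2+2/128 with dropout 0, since deliberate overfitting is the object of
study). Training is teacher-forced cross-entropy with padding excluded
(sequences are processed at their true lengths, so padding never reaches
the loss), Adam, and a triangular cyclic learning rate; the scheduler
class is inherited from the design being emulated, whose constants are not
public, so base 1e-4 / max 1e-3 / cycle 4 epochs were fixed once as
defaults. Shuffling is owned by the training seed, not the input order:
pairs are canonically sorted before the seeded shuffle, so permuting the
input yields bit-identical models. The numerical core (forward, backward,
autoregressive decoding) is compiled C++ (RcppArmadillo) validated against
a base-R reference implementation by exact-equality and finite-difference
gradient tests.

Sampling follows the evaluation protocol: the decoder starts from
`[start]` and draws tokens multinomially at temperature 1 (logits divided
by temperature before the softmax; the temperature → 0 limit reproduces
greedy decoding and is asserted in tests). 2,500 strings per test sequence
is the default, 5,000 the extended setting; invalid strings are counted
into a validity rate but never crash evaluation.

## Metrics

* `count_reproduced()`: unique exactly reproduced test compounds —
  canonical-string identity between sampled strings and the test
  compounds available for the sequence; duplicates count once.
* `extract_cores()`: compounds map to cores via Bemis–Murcko scaffolds
  (ring systems + linkers, side chains removed). The compound-core
  procedure this stands in for is algorithmically more elaborate, but the
  scaffold operator preserves its analytic role — grouping the members of
  an analog series onto one invariant core — and the generator's
  ground-truth scaffold doubles as the test oracle. Acyclic compounds fall
  back to themselves as core. A reproduced core is counted whenever any
  sampled compound maps onto a test core (no ≥2-analog threshold; the
  choice is configurable in spirit by filtering the core map).
* `memorization_analysis()`: the fraction of reproduced compounds present
  verbatim among training compounds, and the mean Tanimoto similarity
  (binary Morgan fingerprints, radius 2, 2,048 bits) to the nearest
  training neighbor. An empty reproduced set reports both as absent, not
  zero.
* Per-sequence reports apply the "more than 20 available compounds"
  inclusion rule (configurable threshold).

## Perturbation protocols

All randomization draws replacement residues from the corpus-wide residue
frequencies. A randomized position counts as targeted even when the draw
equals the original residue — frequency-weighted replacement does not
exclude the original, so the expected fraction of visibly changed residues
is 1 minus the mean squared residue frequency. Coordinates are 1-based
inclusive throughout.

* **Cumulative randomization**: 15-residue segments from the N or C
  terminus until the whole sequence is randomized; variant k keeps variant
  k−1's draws and resamples only the new segment; the last segment may be
  short. Five repeats; curves report mean ± sd per step, with step 0 the
  unperturbed sequence.
* **Positional controls**: the same number of residues randomized at fresh
  uniformly chosen positions at each step (not cumulative across steps —
  the controls absorb positional variance, so each iteration draws its own
  set; whether the original design reuses positions across steps is not
  documented, and fresh sets are recorded in the plan).
* **Motif masking**: randomization or consistent alanine replacement of
  motif ranges, against controls that modify the same number of positions
  at random locations; 10 trials per condition, compared with a two-sided
  Mann-Whitney U test (exact for small untied samples, normal
  approximation with tie and continuity corrections otherwise; stars at
  0.05/0.01/0.001).

## Problem sizes and numerical choices

The study conditions used by the test suite and the acceptance script are
a universe of 4 families × 10 sequences (length 80), 8 series × 18 analogs
per family, 13 base compounds per sequence (≈ 800 pairs). Pre-training
uses 2+2 layers at dimension 64 for 30 epochs; the perturbation and
masking experiments run on family fine-tuned models (40 further epochs on
~150 pairs, per-token loss ≈ 0.15–0.2 — the memorization regime in which
exact reproduction is strong). Reproduction counts sample 2,500 strings
per sequence. Perturbation experiments deliberately sample far fewer
strings per variant (150 for cumulative-randomization curves, 100 for
masking trials): the probe sequences have ~20-compound pools dominated by
multi-target compounds with 2–4× training mass, so at depths of a few
hundred draws every reachable compound is detected with probability ≈ 1,
the trial-to-trial fluctuation that the repeat-based statistics rely on
vanishes, and a halving of probability mass (the effect motif masking
produces in the coupled universe) becomes invisible. The chosen depths
keep per-compound detection probabilities in the informative middle
range. A known desk-scale limitation follows from the same arithmetic:
with 15-residue segments on an 80-residue sequence, each
cumulative-randomization step alters ~19% of the sequence, so
direction/position insensitivity — which at full scale emerges because
any single step is a small perturbation — holds only approximately, and
the mean±2sd bands of the three randomization protocols do not overlap
at the large majority of steps the way full-scale curves do. Ties in family packing
break toward fewer training families, then lexicographic ids; quartiles
use linear interpolation; layer norm uses ε = 1e-5.

Known limitations: the transformer is far below the scale at which
published sequence-conditioned generators operate, sequence length 80 is
an order of magnitude short of real kinases/GPCRs, and the synthetic
analog grammar has none of the long-tail structural diversity of ChEMBL —
so quantitative values (validity rates, reproduction counts) are not
comparable to paper-scale numbers; only the *contrasts* (sequence vs
family split, diluted vs undiluted, masked vs control, coupled vs
uncoupled) are the meaningful outputs, and those are what the acceptance
criteria check.
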