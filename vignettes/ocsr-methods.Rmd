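---
title: "Optical chemical structure recognition with an image-to-SELFIES transformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Optical chemical structure recognition with an image-to-SELFIES transformer}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Chemical structures in the older literature exist only as bitmap drawings.
Optical chemical structure recognition (OCSR) converts such a depiction
back into a machine-readable structure. `ocsr` implements a deep-learning
formulation of this task end to end at desk scale: a molecule's 2D
depiction is encoded by a CNN-style backbone into a spatial feature grid,
and a transformer decoder emits the molecule as a sequence of SELFIES-style
grammar tokens, which always decode into a valid structure. The package
covers the whole training data pipeline (corpus curation, depiction
rendering and augmentation, tokenization, sharded packing), the model
itself, and structure-aware evaluation.

## Corpus curation

Training corpora are curated from SMILES lists by a fixed rule set:
molecular weight under 1500 Da, a single fragment (no counter ions), only
the elements {C, H, O, N, P, S, F, Cl, Br, I, Se, B}, no isotopic labels,
3–40 heavy-atom bonds, a canonical SMILES shorter than 40 characters, and
— in the strict `dataset1` preset — no formal charges (including
zwitterions) and no stereocenters. The permissive `dataset2` preset
retains charges and stereochemistry. Rules are checked in a fixed order
(`mw`, `fragments`, `elements`, `isotopes`, `bonds`, `charge`,
`hydrogens`, `length`, `stereo`) and rejection statistics attribute each
molecule to the first rule it fails, which makes the statistics
deterministic.

Two readings of the rules deserve a note. The "no counter ions" rule is
implemented as *one connected fragment*: counter ions appear as
dot-separated fragments in SMILES. The "only implicit hydrogens, except in
functional groups" rule is not fully operational as stated anywhere we
know of; we implement the closest testable reading — a molecule is
rejected when its canonical SMILES needs a bracket atom that is *not*
explained by charge, stereochemistry, isotope labelling or a standard
aromatic N–H/S–H — i.e. when explicit hydrogen counts encode nonstandard
valence. The SMILES-length rule is measured on the canonical isomeric
SMILES, i.e. *after* stereo annotation; for the strict preset the two
readings coincide because stereo molecules are rejected anyway.

Bond counting follows the hydrogen-suppressed molecular graph (each
heavy-atom–heavy-atom connection once, implicit hydrogens excluded),
matching the convention of toolkits that strip explicit hydrogens before
processing.

All standard chemistry — canonicalization, Kekulé rewriting, InChI
generation, average molecular weight, 2D coordinates, and the FP2 path
fingerprint — is delegated to Open Babel (`obabel`), run in batch over
temporary files with per-record titles so that results realign with their
inputs even when individual records fail to parse.

## The molecular string grammar

Sequence models that emit raw SMILES produce syntactically invalid
strings at a non-negligible rate. The package therefore trains on a
SELFIES-style grammar implemented in `R/selfies.R`: every token is a
bracket symbol, and the decoder derives a molecular graph under valence
constraints, reducing any requested bond order to what both partner atoms
can still accept and skipping tokens that cannot be realized. As a result
*every* sequence over the token vocabulary decodes to a chemically valid,
parseable structure — the property that makes greedy decoding safe.

Design choices, all package-internal and documented here because the
grammar is written from scratch:

* **Token spellings** follow the modern convention (`[C]`, `[=C]`,
  `[Branch1]`, `[Ring2]`, `[C@H]`, `[N+]`, `[/C]`); branch lengths and
  ring distances are spelled in base 16 by an ordered 16-token index
  alphabet. Historically printed strings use 2020-era spellings
  (`[Branch1_1]`, `[C@Hexpl]`); bracket *tokenization* is purely lexical,
  so those strings tokenize identically, and the bundled
  `legacy_token_inventory()` / `legacy_selfies_examples()` provide them
  for tests and examples.
* **Valence model**: B 3, C 4, N 3, O 2, P 5, S 6, halogens 1, Se 2, with
  common charged-atom adjustments (N+ 4, O− 1, S+ 3, …). These caps match
  the implicit-valence conventions of SMILES readers, so a decoded plain
  atom receives the same implicit hydrogen count the encoder saw.
* **Stereochemistry** is carried on decorated atom tokens (`[C@H]`,
  `[C@@H]`) and directional-bond prefixes (`[/C]`, `[\C]`). Tetrahedral
  parity in SMILES is defined by neighbour order; both the encoder and
  the graph writer traverse atoms in creation order and emit ring-closure
  digits immediately after their atom, so neighbour order — and hence
  parity — survives the round trip. Correctness is asserted by canonical
  isomeric SMILES comparison, not by string identity.
* **Degenerate inputs**: a derivation that realizes no atom (e.g. a bare
  ring token) decodes to `"C"`, the grammar's identity molecule, so the
  "every sequence decodes to a parseable molecule" guarantee holds without
  exceptions. Aromatic input SMILES are Kekulé-rewritten by Open Babel
  before encoding; the encoder refuses multi-fragment and isotopic input
  (the curation rules exclude both).

Vocabularies order chemical tokens by descending corpus frequency with a
lexicographic tie-break; the specials `<pad>`, `<start>`, `<end>` take ids
0, 1, 2 (pad = 0 simplifies masking). Rare-token pruning removes whole
molecules *before* the vocabulary is frozen, mirroring the corpus
construction order of the original datasets; the frequency threshold is
exposed (`min_count`) rather than hard-coded, because no canonical value
exists. The printed historical rare-token list contains one duplicate and
is treated as a set.

## Depiction rendering and augmentation

Depictions are rendered from Open Babel 2D layouts as 8-bit grayscale
PNGs (default 299 × 299), black skeleton on white, heteroatom labels in a
small built-in bitmap typeface, wedge/hash bonds for drawn stereocenters
and charge signs for ions. Rotation (uniform 0–360°, continuous) is
applied to the *coordinates* before rasterization, so rotated structures
are never cropped. Rasterization is pure integer arithmetic: a given
(configuration, seed) pair reproduces identical bytes. Whether
augmentation should precede or follow resizing is unspecified in the
original protocol; images here are augmented at their final resolution.

Exactly one of ten photometric augmentations is applied per image, drawn
uniformly, with its parameter drawn uniformly from the published ranges
(Gaussian blur σ ∈ [0, 1.8]; average blur k ∈ [0, 3]; additive Gaussian
noise scale ∈ [0, 25.5]; salt / pepper / salt-and-pepper rate ∈ [0,
0.05]; coarse dropout rate ∈ [0, 0.01] at size-percent 0.9; gamma ∈ [0.5,
2]; sharpen α ∈ [0, 1] at lightness 1; brightness factor ∈ [0.95, 1.5]).
The average-blur kernel is sampled as an odd size in {1, 3} because even
or zero kernels are undefined for convolution. Augmented images remain
8-bit; model input is normalized to [−1, 1] as `pixel / 127.5 − 1`.

## Diversity splitting

Test sets are carved by MaxMin (farthest-point) selection over Tanimoto
distance (1 − Tanimoto on FP2 fingerprints): the first pick is seeded
random — the original protocol does not state whether the first pick was
random or fixed — and each subsequent pick maximizes the minimum distance
to the already-picked set, ties broken by lowest index. The
implementation caches minimum distances and updates them incrementally,
which is behaviourally identical to re-evaluating the greedy criterion
from scratch (asserted against a brute-force oracle in the tests). Which
fingerprint the original split used is unstated; the package uses the
evaluation module's default backend.

## Dataset container

Feature grids and padded id sequences are packed into fixed-count binary
shards (default 128 datapoints per shard, the historical constant; the
75 MB size target of the original TFRecord packing was
infrastructure-specific and is not enforced). Each shard carries a typed
header and little-endian float32 features plus int32 ids; a JSON manifest
records paths, counts and shapes. Reading streams one shard at a time and
validates exact byte lengths, so truncation is detected and named.

## Model

The model is the standard image-captioning transformer: the flattened
backbone feature grid (positions × channels) is projected to `d_model`,
position information is added (sinusoidal by default; learned embeddings
are a configuration switch, since the original description does not
specify the positional treatment of image features), and N encoder layers
(self-attention + FFN) produce the memory attended by N decoder layers
(causal self-attention, cross-attention, FFN). Defaults follow the
reference architecture: 4 layers, 8 heads, d_model 512, FFN 2048, dropout
0.1, post-layer-norm residual blocks, sparse categorical cross-entropy
over non-pad target positions, Adam (β₂ = 0.98, ε = 1e−9, following the
cited schedule's convention) under the warmup schedule
`d_model^-0.5 · min(step^-0.5, step · warmup^-1.5)` with warmup 4000 (the
schedule's canonical default; the original warmup count is not printed).

The numerical core (forward, backpropagation, greedy decoding) is
implemented in RcppArmadillo. The whole batch is stacked into single
matrices so projections and FFNs run as one BLAS call each; attention
softmax/context runs per (sample, head). Decoder sequences are
right-padded to the batch maximum; pad positions are excluded from
attention keys and from the loss, so they contribute nothing to loss or
gradients (asserted by an invariance test). Gradients are verified
against central finite differences in the test suite. Training is
bit-reproducible for a given seed on a single-threaded BLAS.

Greedy decoding only: beam search is left as an extension point, since
the reference system decoded greedily. Decoding starts from `<start>`,
takes the argmax token per step, and stops at `<end>` or the vocabulary's
maximum length; by the grammar's robustness guarantee every decode
converts to a parseable SMILES.

The two literature backbones are represented by seeded
randomly-initialized patch-projection networks that honor their exact
feature-grid contracts — 8 × 8 × 2048 at 299 px (inception_v3 geometry)
and 10 × 10 × 1536 at 299 px (efficientnet_b3 geometry). Each grid cell
is mean-pooled to a small patch (antialiased, implemented as two
averaging matrix products) and projected by a seeded random matrix with a
tanh nonlinearity. Pretrained weights are deliberately not a dependency;
the `pretrained` flag is a reserved hook. The fully configurable `toy`
backbone is what the desk-scale experiments use; it additionally offers
`projection = "identity"`, which keeps the pooled patch pixels themselves
as the channels — a fully informative, well-conditioned feature that lets
the toy transformer fit the depiction-to-sequence mapping considerably
faster than a random mixing of the same pixels.

## Evaluation

Predictions are scored against references by FP2-fingerprint Tanimoto
similarity; pairs at exactly 1.0 are additionally checked for isomorphism
by standard InChI string equality (stereo layers included). A Tanimoto of
1.0 does not imply identity: under a constitution-only fingerprint,
enantiomer pairs collide at 1.0 and only the InChI check separates them —
the package reproduces this phenomenon on synthetic input. Unparseable
references are excluded (with a warning and a separate count);
unparseable predictions score 0 — conservative, and unreachable through
the grammar path. The fingerprint backend is pluggable (`FP2` default;
any Open Babel fingerprint name works); published absolute Tanimoto
values computed with other fingerprints (e.g. the 881-bit PubChem/CACTVS
dictionary) are therefore backend-dependent illustrations, not
comparison targets.

## Synthetic toy corpus

Because the package must be buildable and testable without downloading a
compound database, `generate_toy_smiles()` assembles random molecules —
seeded random growth of chains, branches and 3–7-membered rings over a
weighted, carbon-dominated element pool (C 66%, O 12%, N 10%, F 4%, S 3%,
Cl 3% by draw weight), 4–10 heavy atoms by default, with double (18%) and
triple (3%) bonds where valences allow. Optional stereocenters are
injected as an H + F + Cl + R tetrahedral motif, which guarantees a true
stereocenter. Every candidate is canonicalized and validated through the
real curation rules (rejection sampling), so the corpus is rule-passing
by construction *and* by check, unique, and a pure function of its seed.

What the toy corpus emulates: small single-fragment organic molecules,
heteroatom decoration, rings, stereo variants, and clean
machine-generated depictions. What it does not emulate: drug-like
property distributions, large ring systems, aromatic heterocycle
diversity, hand-drawn or scanned image noise, and corpus scale. Passing
tests therefore demonstrate that the pipeline and model are correct and
can learn the depiction-to-structure mapping at toy scale — not that the
desk-scale model generalizes to real literature images.

## Desk-scale problem sizes

The package's own experiments (test suite and the reproduction script)
use deliberately small configurations chosen once: toy corpora of a few
hundred to two thousand molecules; 128 px depictions with a 6 × 6-cell
toy backbone using identity patch features at 12 × 12 pooled pixels (36
feature positions keep encoder self-attention cheap while each cell
still resolves ~21 px of structure); a 2-layer,
4-head, d_model 128, FFN 256 transformer; batch 32 (the historical
512–1024 are accelerator-scale); warmup 2000; fixed-orientation,
unaugmented depictions for the end-to-end learning run. The 8-sample
memorization check trains 150 epochs at batch 8. Where an end-to-end run
must fit a tighter budget, the corpus is scaled before anything else is
touched, since corpus size is the knob the original work itself varies.

## What desk-scale training does and does not show

The end-to-end runs (test suite and reproduction script) train the toy
transformer on single-view, fixed-orientation depictions of a toy corpus
and score a 10% MaxMin-held-out test set by isomorphic exact match. Two
regimes emerge, and both are reported exactly as computed:

* **Fitting works.** The training loss collapses, a tiny 8-molecule
  corpus is memorized perfectly (greedy decodes reproduce the training
  sequences), and every decode converts to a parseable structure — the
  grammar, model, gradients and decoding are doing their jobs.
* **Held-out recognition does not emerge at this data scale.** With one
  depiction per molecule and corpora of 500–2,000 molecules, the model
  increasingly memorizes its training images while exact match on the
  MaxMin-held-out set stays near zero. This is consistent with the
  method's own scaling behaviour — recognition accuracy climbs with
  training-corpus size across orders of magnitude, and the published
  desk-reference points start near a million images with a pretrained
  visual backbone — and with MaxMin selection placing the most
  structurally isolated molecules in the test set. The end-to-end test
  asserts the held-out target regardless and therefore documents this
  honestly rather than relaxing it.

## Known limitations

* Tetrahedral parity preservation relies on neighbour-order preservation;
  exotic combinations of stereocenters *inside* ring-closure bonds are
  not exercised by the toy generator and may canonicalize differently.
* The grammar supports the curated element set only; molecules outside
  the rule universe (metals, isotopes, multi-fragment salts) are rejected
  at encode time rather than round-tripped.
* The depictor draws one style (plain skeletal, fixed font); it does not
  attempt to learn or imitate publisher-specific depiction styles.
* Backbones are randomly initialized shape-contract stand-ins; no
  pretrained visual features are bundled, so absolute recognition
  accuracy at scale is out of scope.
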