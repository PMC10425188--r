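---
title: "Models and methods behind coilgram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind coilgram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(coilgram)
```

This vignette records the scientific and numerical choices inside
`coilgram`: the model assumptions, what each tunable parameter does and
why its default is what it is, what the synthetic generator does and
does not emulate, and the decisions taken where the design was genuinely
open.

## The labeling problem

A protein of length $L$ carries a per-residue label track over
$\{a,\dots,g,i\}$: the seven heptad registers inside coiled-coil helices
and $i$ outside them. Canonical coiled-coil helices advance the register
cyclically, $a \to b \to \dots \to g \to a$; hydrophobic residues at $a$
and $d$ form the inter-helix interface, which is also why the
oligomerization state of a helix is assumed to be readable from the
residue features at its $a/d$ positions. Decoding additionally emits the
label $x$ for in-helix positions whose register the model leaves
unassigned (see the wildcard states below); $x$ never occurs in training
data, where every helix residue has an annotated register.

Non-canonical repeats (hendecads and longer) are out of scope: the
grammar encodes the seven-register cycle only.

## Stage 1: the register scorer

Per-residue features (an $L \times D$ embedding matrix) pass through

* a 1-D convolution with window 15 and 40 filters (ReLU), zero-padded by
  7 positions per side so the sequence length is preserved;
* a bidirectional LSTM with 64 units per direction, concatenated to 128
  features per position;
* a dense layer with 64 hidden units (ReLU) and an 8-unit output layer.

Window 15, 40 filters, 128 recurrent outputs and 64 hidden units are the
cross-validation-selected values of the architecture this package
implements; `stage1_grid_search()` re-runs that selection (filters
$\in \{10,20,40,80,160\}$, recurrent width $\in \{32,64,128,256\}$,
hidden $\in \{12,32,64,128,256\}$) by k-fold cross-validated residue F1
and accepts reduced grids for desk-scale experiments.

Two decisions here were genuinely open:

* **Output normalization.** The output layer is described with sigmoid
  activations yet trained as a probability distribution under a KL
  divergence loss. We apply the sigmoid and renormalize each row to sum
  to one — the closest reading of that combination — and provide plain
  softmax as `output_activation = "softmax"`. With one-hot targets the
  loss reduces to the mean negative log-probability of the true label,
  so it is non-negative and zero exactly at the target.
* **Recurrent directionality.** Whether the original recurrent layer was
  uni- or bidirectional is not stated. Boundary labeling needs right
  context, so we use a bidirectional layer whose two 64-unit directions
  concatenate to the stated 128 features per position.

Training is full backpropagation (implemented in vectorized base R over
BLAS; there is no external deep-learning dependency) with Adam
(learning rate `2e-3` by default — small enough to be stable on the
minibatch sizes below, large enough that synthetic benchmarks converge
in tens of epochs), dropout 0.25 between the three blocks, minibatches
of 16 sequences padded with a mask (masked positions are excluded from
the loss and frozen through the recurrence, in both scan directions),
and early stopping: training halts after 10 epochs without validation
improvement and the checkpoint with minimal validation loss is returned.
When no validation set is supplied, a seeded 10% of the training records
is held out. All randomness (initialization, split, shuffling, dropout)
derives from `stage1_config(seed = )`, so identical calls are
bit-identical.

## Stage 2: the grammar-constrained hidden CRF

The automaton has 20 states: `BEGIN`, `END`, two self-looping background
states `i0` (N-terminal) and `i1` (between and after helices), and two
identical blocks `1a..1g,1H` and `2a..2g,2H`. The first block models the
first helix of a protein, the second all later ones, which lets the
model learn different statistics for first versus subsequent helices.
Within a block, the only register-to-register edge follows the heptad
cycle; `H` is a hidden wildcard that "absorbs" irregular positions.
Open topology details were resolved as follows, each as the minimal
choice consistent with the published state diagram:

* `H` is entered from any register and exits to any register, with **no
  self-loop** by default (one irregular position per excursion);
  `build_cc_automaton(h_self_loop = TRUE)` relaxes this.
* Helices may start at **any register phase** (`BEGIN` and `i0`/`i1`
  connect to all seven registers of the corresponding block), since
  observed helices are cropped at arbitrary phase.
* `H` states cannot terminate a path or leave the helix: every helix
  must end on a concrete register.

Node potentials are linear in the stage-1 probability vector observed at
offsets within `feature_window` (default 1, i.e. only the position
itself) plus a per-state bias; transitions, starts and ends carry free
weights on the allowed edges only. Training maximizes the penalized
conditional log-likelihood
$\sum \log P(\text{labels}\mid\text{features}) - \lVert w\rVert^2/(2\sigma^2)$
with L-BFGS; the gradient is the clamped-minus-free difference of
feature expectations, where the clamped lattice admits every state path
consistent with the labels (H wildcards free over registers). Defaults
$\sigma^2 = 0.05$ and 40 iterations are the selected values of the grid
$\sigma^2 \in \{10^{-4},10^{-3},0.05,0.1\}$,
iterations $\in \{10,20,40,100\}$. The objective is concave, so
different initializations reach the same optimum; weights start at zero.

Numerics: forward–backward runs in scaled linear space (per-position
renormalization with accumulated log scale factors, plus a per-position
max-shift of the node potentials before exponentiation), posteriors and
pairwise marginals are renormalized explicitly, and the log-partition
agrees with exhaustive path evaluation to $10^{-8}$ for all $L \le 12$
in the test suite. Posterior-Viterbi maximizes
$\sum_t \log \gamma_t(s_t)$ over grammar-valid paths; all argmax
tie-breaks take the lowest state index in the fixed order
`i0, i1, 1a..1g, 1H, 2a..2g, 2H`. The per-residue coiled-coil
probability reported for PR curves is the summed posterior of all
non-`i` states — our reading of "the CRF posterior", recorded here
rather than asserted.

## Stage 3: oligomerization state

For each decoded helix the embedding rows at predicted $a$ positions and
at predicted $d$ positions are averaged separately and concatenated
($x = \bar e_a \cdot \bar e_d$, dimension $2D$); $x$-labeled positions
contribute nothing. A $2D \to 128 \to 4$ network with softmax output is
trained by cross-entropy (the loss was unspecified; cross-entropy is the
standard choice for the stated probability output), with the hidden
width selected by mean per-class MCC over $\{16,32,64,128,256\}$
(`oligo_grid_search()`). A decoded helix without any $a$ or without any
$d$ position is *degenerate*: its state is reported unset with a
warning, rather than inventing a fallback. Per-protein majority states
in `coil_predict()$proteins` are a convenience, explicitly derived.

## Evaluation

* Residue scores treat any non-`i` label as coiled-coil; precision,
  recall and F1 use the convention $0/0 = 0$ (the sources are silent;
  this is the standard benchmarking convention).
* Segment scores apply the half-overlap rule: a prediction is correct
  iff its overlap with an observed segment is at least half the length
  of the longer of the two, as a real number (overlap 5 against a
  9-residue segment passes, $5 \ge 4.5$). Matching is greedy in
  left-to-right order with each observed segment consumable once; how
  the original protocol matches one prediction spanning two observed
  helices is unstated, so this policy is documented rather than claimed.
* SOVo/SOVp follow the Zemla (1999) definition on the binary coiled-coil
  labeling, including the δ tolerance term, with observed respectively
  predicted segments as reference. Note that δ deliberately forgives
  small boundary shifts, so SOV = 100 does **not** imply identical
  tracks (a 10-residue helix predicted with two extra residues still
  scores 100); the tests assert the sound direction (agreement ⇒ 100)
  and verify the value against an independent transliteration of the
  formula.
* PR-AUC is step-interpolated (average precision) over all distinct
  residue thresholds.
* Register MCCs are one-vs-rest per register; positions labeled `x` in
  either track are excluded because they assert no register identity.
* `bootstrap_compare()` resamples *sequences* (not residues) with
  replacement — 100 samples of 300 by default — scores each sample with
  the pooled residue/segment/SOV measures and applies a two-sided
  two-sample Welch t-test per measure.

## The synthetic generator

`coil_simulate()` plants what the model class assumes: non-overlapping
helices (length 8–60, separated by ≥ 1 background residue, 0–4 per
protein) with cyclic registers from a uniform random phase, hydrophobic
residues (`L,I,V,M,F,A`) at $a/d$ positions with probability 0.8 against
a polar-biased background (uniform over the 20 residues with
hydrophobics down-weighted ×0.5 — keeping the signal in the register
structure rather than composition alone), one of the four oligomer
classes per helix, and label-conditioned Gaussian embeddings whose
class signal is injected **only** into $a/d$ rows, mirroring the
biophysical rationale for stage 3. Defaults for the quantities the
underlying study fixes elsewhere were chosen once as realistic desk
scale: 200 proteins of length 60–160, embedding dimension 32, mean
separation `class_sep = 3` against per-component noise `noise_sd = 1`
(roughly a 2σ separation per residue along the discriminating direction
— learnable but not trivial).

What it does *not* emulate: the geometry of real protein language model
embeddings (anisotropy, context dependence), non-canonical repeats,
helix-length and composition statistics of real CCDs, and homology
structure between proteins. Passing recovery tests on this generator
therefore demonstrates that the estimation machinery works — not that
the trained models transfer to real proteins, which additionally
requires real embeddings and curated structural annotations.

## Problem sizes and budgets in the shipped checks

The package's own test suite and `scripts/acceptance.R` use sizes chosen
to exercise every code path at desk scale: DP-oracle agreement on all
$L \le 12$ across 50 random weight settings; 10,000 random decodings for
the grammar guarantee; 1,000 random toy instances for the metric
oracles; and an end-to-end run with 200 training and 60 held-out
proteins at the generator defaults, 15 stage-1 epochs, on which the
pipeline reaches residue F1 ≥ 0.9, segment F1 ≥ 0.8 and mean per-class
oligomer MCC ≥ 0.8 (the shipped acceptance thresholds). The
reported numbers in the README were produced by the code shown there.

## Coordinates and formats

All user-facing coordinates are 1-based inclusive — the R/Bioconductor
convention, and the convention of the serialized outputs; conversion
from run-length label tracks happens in exactly two functions
(`segments_from_track()` / `track_from_segments()`). Sequences travel as
FASTA, label tracks as two-line `>id`/track files, embeddings as per-id
binary `.emb` (shape header + row-major float32) or `.tsv` files,
stage-1/oligomer checkpoints as RDS with the label/class order embedded
(a mismatch on load is an error), and CRF models as a human-diffable
text format with the edge list, label map, $\sigma^2$, window and weight
tables.

## Known limitations

* The trained pLM-based models of the original tool are not
  reproducible here: that requires the curated structural datasets and
  ProtT5/ESM2 inference. The embedding contract (`load_embedding()`,
  `add_embeddings()`) is the seam where real embeddings drop in.
* Stage-1 training is CPU-bound R; it is comfortable at the synthetic
  scales above (minutes) but not sized for thousands of real proteins
  at $D = 2304$.
* The CRF's node features are the 8 stage-1 probabilities (optionally
  windowed); raw embeddings are not fed to the CRF.
* `is_valid_label_path()` treats `x` as "any wildcard-state position",
  so validity of decoded tracks is checked against the same grammar
  that produced them; the independent guarantee comes from the
  automaton construction tests.
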