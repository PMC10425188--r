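# coilgram

Coiled-coil domains (CCDs) are bundles of two or more α-helices wound
around each other with knobs-into-holes packing. Each helix follows a
seven-residue *heptad repeat* whose positions — the *registers*
`a b c d e f g` — place hydrophobic residues at `a` and `d`, forming the
interface between helices. Annotating CCDs from sequence means answering
three questions per protein: *where* are the coiled-coil helices, *which
register* does each residue occupy, and *how many helices (and in which
orientation)* form the bundle — its oligomerization state.

`coilgram` is an R toolkit for building and evaluating such predictors.
It is aimed at structural bioinformaticians who want a trainable,
fully-inspectable implementation of the cascaded
network/grammar-CRF architecture for coiled-coil annotation, together
with the field's standard evaluation protocol and a synthetic benchmark
generator so that every stage can be trained and verified offline, with
no external model weights.

## The model

Prediction runs in three independently trained steps:

1. **Register scorer.** Each residue arrives as a feature vector (a
   per-residue embedding; a real deployment concatenates two protein
   language model embeddings of 1024 and 1280 features into 2304 per
   residue — `coilgram` treats the encoder as a pluggable contract). A
   convolutional layer (15-residue window, 40 filters) feeds a
   bidirectional LSTM (128 outputs per position) and a dense head
   (64 hidden units) that emits an 8-way probability distribution per
   residue over `a..g` and `i` (non-CCD). Training minimizes the
   Kullback–Leibler divergence to one-hot targets with Adam, dropout
   0.25 and early stopping (patience 10).

2. **Grammar-constrained hidden CRF.** A 20-state automaton encodes the
   CCD grammar: BEGIN/END, two self-looping background states `i0`/`i1`,
   and two identical helix blocks `1a..1g,1H` / `2a..2g,2H` in which the
   only register→register transition follows the heptad cycle
   `a→b→…→g→a`, and the wildcard state `H` absorbs single irregular
   positions. The CRF is trained (L-BFGS, Gaussian prior σ² = 0.05, 40
   iterations) on the step-1 probability profiles; decoding is
   *posterior-Viterbi*: forward–backward posteriors followed by the
   grammar-valid path maximizing Σₜ log P(stateₜ). Decoded tracks are
   grammar-valid by construction.

3. **Oligomerization state.** For each decoded helix with embedding rows
   E, the means over predicted `a`- and `d`-positions are concatenated,

   ēₐ = (1/Nₐ) Σ_{r:a} E_r,  ē_d = (1/N_d) Σ_{r:d} E_r,  x = ēₐ · ē_d
   (· = concatenation),

   and a single-hidden-layer network (128 units) classifies x into
   parallel dimer, antiparallel dimer, trimer or tetramer.

Scoring implements the standard protocol: residue and segment
precision/recall/F1 (a predicted segment counts as correct only if its
overlap with an observed segment reaches half the length of the longer
of the two), the Zemla segment-overlap scores SOVo/SOVp, precision-recall
AUC over the per-residue coiled-coil posterior, per-register and
per-class MCC, and bootstrap comparison of two methods (100 samples of
300 sequences, Welch's t-test).

## Worked example

Train the full cascade on simulated proteins with planted heptad
helices and evaluate on held-out records:

```r
library(coilgram)

sim   <- coil_simulate(synth_config(n_records = 60, length_range = c(50, 120),
                                    helices_per_record_range = c(1, 2), seed = 7))
train <- sim[1:45, ];  test <- sim[46:60, ]

fit  <- coil_fit(train,
                 stage1 = stage1_config(n_filters = 16, recurrent_units = 32,
                                        hidden = 16, seed = 3),
                 crf_iterations = 20, oligo_epochs = 150, max_epochs = 20)
pred <- coil_predict(fit, test)
head(tidy(pred), 8)   # one row per residue
#> # A tibble: 8 × 8
#>   id     position residue cc_flag register cc_probability segment_id oligo_state
#>   <chr>     <int> <chr>     <int> <chr>             <dbl> <chr>      <chr>
#> 1 SYN00…        1 Y             0 -                0.0209 -          -
#> 2 SYN00…        2 R             0 -                0.0232 -          -
#> # …

coil_evaluate(pred, test[, c("id", "labels")])
#> # A tibble: 16 × 2
#>    measure  value
#>  1 pre_r    0.970
#>  2 rec_r    0.934
#>  3 f1_r     0.952
#>  4 pre_s    0.842
#>  5 rec_s    0.8
#>  6 f1_s     0.821
#>  7 sov_o   92.4
#>  8 sov_p   83.6
#>  9 pr_auc   0.988
#> 10 mcc_a    0.909   # … per-register MCCs b–g all ≥ 0.91
```

`f1_r`/`f1_s` are residue- and segment-level F1 for the coiled-coil
class (the segment score applies the half-overlap rule), `sov_o`/`sov_p`
the segment-overlap measures with observed and predicted segments as
reference, `pr_auc` the area under the precision-recall curve of the CRF
coiled-coil posterior, and `mcc_a`..`mcc_g` one-vs-rest register MCCs.
Predicted helices with their oligomer probabilities sit in
`pred$segments`; `autoplot(pred)` draws the per-residue coiled-coil
posterior with the decoded helices shaded.

A file-based interface mirrors the in-memory one
(`cmd_simulate`/`cmd_train`/`cmd_predict`/`cmd_evaluate`, or the
`inst/exec/coilgram` script with subcommands
`simulate|train|predict|evaluate`): FASTA plus per-id embedding files in,
per-residue TSV and per-segment JSON out.

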