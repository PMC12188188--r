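---
title: "Predicting expression from promoter sequence: models, training and explainability"
author: "camformer"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting expression from promoter sequence: models, training and explainability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camformer)
```

## The prediction task

Gigantic parallel reporter assays (GPRA) measure the regulatory activity of
random DNA: an ~80-nt random insert is cloned between fixed plasmid flanks
(17 nt on the 5' side, 13 nt on the 3' side) upstream of a fluorescent
reporter, yeast cells carrying the construct are flow-sorted into 18
expression bins, and each promoter is assigned the weighted mean bin of its
sequenced cells. The result is millions of (110-nt promoter, real-valued
expression) pairs, and the learning task is a regression
$f : \{A,C,G,T,N\}^{110} \rightarrow \mathbb{R}$.

Two properties of the assay shape every design choice in this package.
First, training labels are noisy: the public training data average only ~2
cells per promoter, while test promoters are sequenced at ≥100 cells, so
training-set expression is a high-variance estimate of the same latent
quantity the test set measures precisely. Second, the only variable signal
lies in positions 18–97; the flanks are constant and informative only
through their interaction with insert edges.

## The model family

`camformer()` fits a residual 1-D convolutional network. The architecture
family, described declaratively by `model_config()`, is:

* a stack of same-length (zero-padded) convolutions along the position axis,
  each followed by optional batch normalization and ReLU;
* additive identity skips over two-layer blocks. The skip entering the block
  that ends at layer 2 starts at the 4-channel encoded input while the block
  emits (say) 512 channels; such channel-mismatched skips are wired through
  a learned 1×1 projection convolution, the standard resolution for
  mismatched residual additions. Projection parameters are included in all
  parameter counts;
* one max pooling along positions at the penultimate position of the network
  — immediately before flattening — with non-overlapping windows (trailing
  positions that do not fill a window are dropped);
* a fully connected head with dropout and a single scalar output.

The shipped presets pin this family to the published Camformer parameter
budgets, which are the verification surface for the architecture
transcription:

| preset            | conv trunk                        | head                | parameters |
|-------------------|-----------------------------------|---------------------|-----------:|
| `camformer`       | 6 layers × 512 ch, skips at 2/4/6 | pool 2, FC 256→512  | 16 558 849 |
| `camformer_small` | 6 layers × 256 ch, skips at 2/4/6 | pool 4, FC 160→96   |  3 436 641 |
| `camformer_mini`  | 4 layers (64/128/128/64), no skips| pool 2, FC 320→128  |  1 384 385 |
| `tiny`            | 2 layers × 24 ch, skip at 2       | pool 5, FC 32       |     24 425 |

Layer-level hyperparameters that the published architecture description
leaves open (kernel widths, fully connected widths, dropout rates, pool
width) are this package's own choices, stored as data in
`inst/presets/*.json` and validated by the budgets above: `camformer` and
`camformer_small` round to 16.6 M and 3.4 M parameters, `camformer_mini` to
1.4 M. One consequence is worth recording: a parameter count is a
quadratic-plus-linear function of the convolutional width, so halving every
conv width of a 16.6 M-parameter model can reduce the count at most
four-fold (to ≥ 4.15 M). The 3.4 M budget of the small variant therefore
cannot be met by channel-halving alone; `camformer_small` keeps the halved
trunk and additionally narrows its pooled fully connected head. The `tiny`
preset is sized for desk-scale ground-truth experiments: its two-layer
receptive field (19 nt) comfortably covers the widest planted motif used in
the validation suite (11 nt) and it trains on a CPU in seconds per epoch.

`count_parameters()` counts trainable scalars of the realized network and is
tested against an independent closed-form formula over the configuration on
random architectures — transcription errors in either the builder or the
presets surface as a count mismatch.

## Sequence encodings

Five encodings share the one-hot base channels `A=[1,0,0,0]`, `C=[0,1,0,0]`,
`G=[0,0,1,0]`, `T=[0,0,0,1]` in channels 1–4 and differ in how they treat
`N` and label uncertainty:

* `onehot` — `N = [0,0,0,0]` (4 channels);
* `onehotWithP` — `N` as the uniform distribution `[.25,.25,.25,.25]`;
* `onehotWithN` — a fifth binary channel marking `N` positions;
* `onehotWithInt` — a fifth channel carrying a per-promoter uncertainty
  scalar broadcast across positions, defined as `1/sqrt(support)` where
  `support` is the read/cell count behind the expression estimate (1 when
  absent). The inverse square root follows the standard-error scaling of a
  mean over `support` observations;
* `onehotWithBoth` — both extra channels (6 total).

`decode_batch()` inverts every scheme exactly and rejects slices with no
scheme-consistent interpretation; the round trip is part of the test suite.

## Preprocessing

`filter_standardize()` applies the assay's published cleaning rules in a
fixed order: discard sequences whose length falls outside 110 ± 3; among
survivors, discard sequences with more than three `N` (counted before
padding); pad shorter survivors with `N` at the 3' end; truncate longer
survivors at the 3' end. Truncation at the 3' end mirrors the padding side —
the rules only state where padding goes, and symmetry keeps the variable
region's 5' anchor at position 18. The filter report satisfies the exact
conservation identity `n_in = n_kept + n_discarded_length + n_discarded_n`
and the operation is idempotent.

## Training

The default loss is mean absolute error (L1): with ~2 cells per promoter the
labels carry heavy-tailed noise, and L1 is robust to the resulting outliers.
MSE and Huber are available for comparison, as are AdamW (default) and Lion,
and three learning-rate schedules (constant, step decay, cosine annealing).
Each epoch the model is scored on a held-out validation split (default 10%;
8% matches the competition-era protocol) by the sum of Pearson and Spearman
correlations, r + ρ; training stops after `patience = 5` epochs without
improvement (a package default — any positive value is configurable) or at
`max_epochs = 50`, and the weights of the best epoch are restored. A
correlation over zero-variance inputs is defined as 0 (with a flag) so that
r + ρ remains total-ordered even on degenerate data.

Seed policy: one integer seed drives the split, the He-initialized weights,
minibatch shuffling and dropout; identical data, configuration and seed
reproduce the fit exactly on the same platform. (Multi-threaded BLAS can
reorder floating-point reductions across machines; within one machine and
thread count, runs are bit-reproducible.)

`ensemble_predict()` averages prediction vectors from seed replicates —
architecturally identical models trained under different seeds — which
reduces both error and run-to-run variance. `subsample_curve()` fixes a
holdout before subsampling and trains on nested subsets (each larger subset
contains every smaller one) so that curve points differ only in training
data volume. `generate_grid()` enumerates the Cartesian product of option
axes; the default axes — 5 encodings × 3 losses × 2 optimizers × 3
schedulers — give 90 combinations per architecture and 270 over the three
main presets.

## Evaluation

`correlations()` reports r, r² and ρ (average ranks for ties).
`category_report()` evaluates per promoter category and forms the
competition-style weighted scores Σ w_c r_c / Σ w_c (and likewise for ρ);
category weights are a required input with a uniform default, because the
competition's own weighting is not public. Categories with fewer than two
observations are excluded and flagged. `delta_norm(ρ₁, ρ₂) = (ρ₂ − ρ₁) /
(1 − ρ₁)` expresses an improvement as the fraction of the baseline's
remaining headroom that the model closes, which makes gains comparable
across categories whose baselines differ. `bootstrap_compare()` resamples
observations with replacement (degenerate resamples are redrawn and
counted), recomputes both models' correlations per replicate, and applies a
paired t-test to the per-replicate differences.

## Explainability

**ISM.** `ism()` evaluates the model on the original promoter and on every
single-base substitution across the variable region — 3 variants at each of
the 80 positions, 240 in total for an N-free region (`N` positions are
skipped and flagged, since a substitution into `N` has no reference
semantics). `delta[p, b]` is the prediction change for placing base `b` at
position `p` (exactly 0 at the reference base), and the per-position
importance is the negative mean of the three non-reference deltas:
positive importance marks positions whose mutation lowers predicted
expression. Evaluation is batched and the results are independent of the
batching.

**ISM-logo entropy.** To rank promoters by how concentrated their
importance profile is, `ism_entropy()` normalizes the absolute importances
to a probability vector over the 80 positions and returns its Shannon
entropy (natural log by default, configurable). Low entropy means
importance mass sits on few positions — the signature of discrete
regulatory motifs; the flat profile attains the maximum, log 80 ≈ 4.38.
Summing over positions (rather than per-position over the four bases) was
an open choice; it is the variant that directly measures positional
concentration, which is what the ranking is used for.

**Grad-CAM.** For a regression network the raw scalar output plays the role
of the class score: `gradcam()` backpropagates the output to the chosen
convolutional feature map, averages the gradient over positions to obtain
per-channel weights, forms the channel-weighted sum of the feature map,
rectifies it (rectification after weighting, so channels with negative
influence can cancel before the cut), and linearly interpolates the map to
input coordinates. Maps are nonnegative, length 110, and deterministic in
eval mode. Since all conv layers here preserve length, interpolation is the
identity in practice; it is kept so maps from any pooled architecture
remain comparable.

**Embeddings.** `activation_embedding()` flattens a layer's `(h, w, c)`
output to a vector of length `d = h·w·c` per sequence, the input expected by
t-SNE/UMAP-style tools (the embedding algorithms themselves are deliberately
out of scope — any standard implementation applies).

## Motif logic

`scan_pwm()` is a log-odds scanner: score = Σ log(p/background) over motif
positions, probabilities regularized by a pseudocount (default 0.001,
renormalized) so zeros stay finite; both strands are scanned (minus-strand
hits keep forward-sequence coordinates) and `N` contributes zero information
— the neutral treatment for padding. The default threshold of 0 keeps
windows that beat the background. The scanner and the Fisher-based
`motif_enrichment()` (presence of ≥1 hit, top vs bottom expression
quantile, Benjamini–Hochberg across motifs) are method-analogous,
deliberately simple replacements for external motif-suite tools (FIMO/SEA);
they reproduce the analysis logic but are not bit-compatible with those
tools' scores or E-values.

`cooccurrence_expression()` builds the pairwise mean-expression matrix
`pair[i, j]` over sequences carrying both motifs (the diagonal is each
motif's baseline) and the difference matrix `difference[i, j] = pair[i, j] −
pair[i, i]`, the expression shift associated with motif j joining motif i;
under-supported cells (default < 5 sequences) are masked.
`grouped_ism_profile()` asks the sharper question — does a motif's own
importance profile change when a second motif overlaps it? — by aligning
ISM importance across all strand-oriented instances of motif A and
splitting them by whether any B hit shares at least one position
(partially overlapping motif pairs are exactly the interesting case, hence
the ≥1-position rule).

## The synthetic GPRA generator

Recovering known ground truth is the only way to validate this pipeline at
desk scale, so the generator is a first-class module. It emulates:

* the construct geometry — uniform random 80-nt inserts between fixed
  (arbitrary, documented) 17-nt and 13-nt flanks. Only the flanks'
  fixed-ness matters to the method, not their sequence;
* planted regulatory logic — each `motif_spec()` is planted independently
  with its own probability, at a uniform non-overlapping position (rejection
  sampling, 100 attempts, then an error naming the motif — ambiguous ground
  truth is refused rather than silently accepted), on a uniform strand, the
  site sampled column-wise from the PWM and written over the insert so
  length stays 110;
* an additive latent expression: baseline + planted effects + interaction
  effects for co-planted pairs + a GC-content term over the variable region
  (GC-expression correlation is a known strong feature of this assay);
* the binned readout: each of `cells_per_promoter` cells observes
  latent + Gaussian noise, is clipped into an 18-bin equal-width grid, and
  the reported expression is the mean bin index — the weighted mean bin of
  the real assay. The grid spans mean ± 2 sd of the latent distribution,
  estimated from 10 000 draws at generation time, because the real
  bin-to-expression calibration is not public; the simulator's grid is a
  stand-in, not a reconstruction. Setting `cells_per_promoter = 2` vs `100`
  reproduces the training/test noise asymmetry of the real data.

Deliberately not modelled: sequencing depth, PCR bias, plasmid copy number,
and the real library's sequence composition. Passing recovery tests
therefore demonstrate that the estimator, attribution and interaction
machinery work when the generative assumptions hold; they do not certify
performance on real data, where label noise is non-Gaussian and motif
grammar is richer.

Gaussian cell noise is the simplest model sufficient for recovery testing
and is not a claim about the assay's noise process.

## Numerical choices and degenerate inputs

* He initialization for weights, zero biases, unit batch-norm scales;
  batch-norm ε = 1e-5, running-statistics momentum 0.1 (unbiased variance
  in the running estimate).
* Max pooling uses `floor(L / width)` windows; within-window ties take the
  first maximum (backward routes gradient to that element).
* A non-finite training loss aborts with a diagnostic naming the epoch and
  learning rate rather than continuing from poisoned weights.
* Zero-variance labels or predictions give correlation 0 with a flag,
  everywhere (training, metrics, bootstrap; degenerate bootstrap resamples
  are redrawn and counted).
* PWM columns must sum to 1 within 1e-9 at construction; MEME files, which
  round to a few decimals, are renormalized on read.
* All coordinates are 1-based inclusive; the variable region is positions
  18–97.

## Problem sizes in the validation suite

The packaged experiments are sized for a single CPU: the main recovery
experiment uses a 20 000-promoter library (one +2 activator, one −3
composite repressor embedding the activator's consensus, one −1
interaction, 10 cells/promoter at unit noise) with the `tiny` preset
trained for 6 epochs — enough for held-out ρ ≈ 0.78, ISM sign recovery
above 90% of planted instances, and separation of overlap-grouped ISM
profiles. The ensemble experiment trains five seeds on 4 000 promoters.
These sizes are the package's chosen desk-scale study conditions; the same
code runs unchanged on full-scale data.

## Known limitations

* The training engine is CPU-bound R/C++; it is meant for desk-scale
  experiments and architecture study, not for multi-million-sequence
  training runs, which require GPU tooling outside this package's scope.
* Preset kernel widths and head dimensions are pinned only through total
  parameter budgets; other internals (e.g. exact dropout rates) are
  package choices and may differ from any particular external
  implementation of the same architecture family.
* The enrichment and scanning routines are approximations of the MEME-suite
  tools they stand in for, adequate for the package's analyses but not for
  cross-tool score comparison.
* Competition category weights are not public; weighted scores computed
  here use user-supplied (default uniform) weights.
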