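---
title: "Adversarial imputation of longitudinal microbiome data: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adversarial imputation of longitudinal microbiome data: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Longitudinal microbiome studies sample each subject's community at a
series of planned timepoints, but subjects routinely miss visits, so the
subject x timepoint grid has holes. Discarding incomplete subjects wastes
most of a cohort; imputing the missing samples keeps them usable for
downstream analyses (diversity trajectories, outcome classifiers).
`microgen` implements a generative adversarial imputer for this setting,
together with seven classical baselines, a synthetic cohort simulator with
MCAR/MAR/MNAR amputation, and an evaluation suite.

## Data representation and preprocessing

The input is a relative-abundance (RA) table: per observed sample, taxon
proportions summing to 1. Missing samples are stored as all-zero vectors
with an observation mask `e` (1 = observed). Because compositions live on
a simplex, all modelling happens on the centered log-ratio (clr) scale:

* zeros are replaced by a pseudo-count equal to half the *global* minimum
  nonzero RA over all observed entries (a single global value keeps the
  zero-restoration threshold in post-processing well defined), and each
  sample is renormalized;
* `clr_j = ln x_j - mean(ln x)` per sample, so clr vectors sum to zero.

Natural log is used throughout (the base only rescales clr-scale errors
uniformly). Time is kept in real study units (e.g. months); the forward
gap `delta_f[i]` is the elapsed time since the most recent observed sample
before timepoint `i` (0 at the first timepoint, accumulating across runs
of missing samples), and `delta_b` mirrors it backwards.

## The generator

**Phylum features.** Taxa are partitioned by phylum; inside each cluster
taxa are ordered by decreasing geometric mean of the absolute Spearman
correlations with all cluster members (self-correlation included — it only
rescales by a root and cannot change the order), so correlated taxa sit
next to each other. Correlations are computed on clr values pooled over
all observed samples; ties use average ranks and sorting ties break by
taxon id, so the order is bit-reproducible. A per-cluster convolutional
module (two 1-D convolutions along the ordered-taxon axis, kernel 3,
16 then 8 filters, LeakyReLU slope 0.2, max-pooling of width 2 with ceil
semantics, same-padding) extracts local features; clusters smaller than
the kernel bypass the convolution and contribute raw clr values. Per-
cluster feature vectors are concatenated per timepoint.

**Recurrent imputation.** A one-layer bidirectional tanh RNN (hidden size
32 per direction by default) consumes the feature sequence. Three design
points matter and are worth stating explicitly:

1. *Carried inputs.* At missing timepoints the network input is the
   nearest observed sample in the direction of travel (last observation
   carried forward for the forward RNN, next observation carried backward
   for the backward RNN). On the clr scale a zero vector means "every
   taxon at its geometric mean", so zero placeholders are ambiguous;
   carried inputs are the convention of the decay-based recurrent
   imputation family this model belongs to, and they are fixed given the
   data and mask, which keeps the convolution workspaces precomputable.
2. *One-step-ahead residual outputs.* The output for timepoint `i` is the
   carried input plus a linear readout of the hidden state of `i-1`
   (forward) or `i+1` (backward). Reading the *current* hidden state
   instead creates an identity shortcut — the network can copy its own
   input at observed timepoints, driving the reconstruction loss to zero
   without learning any temporal structure (we verified this
   experimentally: reconstruction loss collapses while imputation error
   stays at chance). The residual form also means the untrained generator
   already interpolates between neighbouring observations.
3. *Decay combination.* The two directions are blended with trainable
   factors `lambda = exp(-ReLU(W delta + b))`, one scalar per timepoint
   and direction, decaying with the time gap. Decay biases initialize at
   `ln 2` so the untrained model averages the two carries; no
   `lambda_f + lambda_b = 1` constraint is imposed.

The final imputation passes observed values through exactly:
`x_bar = x (*) e + x_tilde (*) (1 - e)` — an identity that holds for any
weight setting and is asserted as a test invariant.

**Initialization.** Glorot-uniform weights with two adjustments: the
RNN input weights start six times below the Glorot limit (clr features
span roughly ±8, and a unit-variance init saturates the tanh cells, which
demonstrably freezes training), and the convolution fans account for the
kernel. The LSTM forget bias starts at 1.

## The discriminator and losses

The discriminator is a 10-unit LSTM over the timepoint axis with two
heads: the final hidden state feeds a sigmoid real/fake probability and
every step's hidden state feeds a softmax over the `k` timepoint classes.
The real branch sees `x_bar (*) e` and the fake branch `x_bar (*) (1-e)`.

Generator loss: `lossG = -log D(fake)` (adversarial), `lossR` (L1 between
generated and actual values over observed samples, normalized by the
observed count), and `lossC` (mean L1 between the forward and backward
generated tensors) — summed without weights. Discriminator loss: binary
cross-entropy on the two branches plus the timepoint cross-entropy with
one-hot targets equal to the timestep indices, computed on the real
branch (the temporal structure worth learning is that of actual data).
Probabilities are clamped to `[1e-7, 1 - 1e-7]` before logs.

Training is full batch (cohorts are small): five discriminator Adam steps
then one generator Adam step per epoch, both at learning rate 1e-3, with
dropout on the CNN features during training. The published dropout
setting of this model family ("0.7" under TensorFlow 1.x, whose dropout
argument is the *keep* probability) corresponds to a drop fraction of
0.3, the default here; dropping 70% of the features saturates the
recurrent layer and stops learning. Training stops when the generator
total loss has made no new minimum for `patience_epochs` (default 1000)
epochs, with a hard cap (default 20000); the *final* weights are kept —
restoring the weights of the loss minimum is counterproductive here
because the adversarial term drifts upward as the discriminator
strengthens even while reconstruction improves. Every run is bit
reproducible given the seed (all randomness flows from one generator;
training uses its own RNG stream, so results are independent of R's RNG
state).

Ablation variants: `bigan` removes the CNN (raw clr features), `rnn`
additionally removes the discriminator (reconstruction-only training).

## Baselines

Seven classical imputers operate per subject per taxon on the clr scale
with the same observed-value passthrough: within-subject mean and median,
linear and cubic fits over the observed `(t, value)` pairs (order reduced
when observations are scarce, nearest-observed-value extrapolation at the
edges to avoid wild clr values), a centered moving window of width 3
(expanding to the nearest observation when empty), last observation
carried forward (first observation carried backward for leading gaps), and
a deterministic chained-equation regression (MICE-style: per taxon,
subjects as rows and timepoints as columns, mean-initialized, 10 sweeps,
single imputation, no posterior draws — a simplification chosen for
testability).

## Synthetic cohorts

`generate_base_cohort()` builds a fully observed cohort: per subject, a
sparse Dirichlet baseline composition (structural zeros at rate
`sparsity` stay zero at every timepoint), log-scale trajectories that
revert to the subject baseline with AR(1) coefficient `ar_coefficient`
and innovation sd `innovation_sd`, plus a *cohort-level* per-phylum random
walk (`phylum_sd` per step) shared by all subjects — emulating the strong
developmental trends of infant-cohort studies and inducing within-phylum
correlation. `perturb_subjects()` implements the small-additive-noise
recipe for deriving new subjects from templates: per nonzero entry,
`N(mu, 1e-6)` noise with `mu` drawn once per run from `[1e-6, 2e-6]`,
zeros preserved, and the net change re-balanced in equal shares so every
sample still sums to 1.

Defaults (60 taxa, 4 phyla, 8 timepoints at months 4, 7, ..., 25, 30
subjects, sparsity 0.25, `ar_coefficient` 0.7, `innovation_sd` 1.5,
`phylum_sd` 0.4) were calibrated once so that the classical imputers
reproduce the error regime reported for real infant cohorts — LOCF the
worst, mean/median close behind, interpolating methods better — and were
not revisited afterwards. What the simulator does *not* emulate: read
sampling noise, taxon blooms, batch effects, or compositional count
sparsity beyond structural zeros; passing benchmarks here therefore shows
correct mechanics and the expected method ordering on smooth compositional
time series, not performance on any particular real dataset.

`ampute()` applies MCAR/MAR/MNAR missingness: subjects are split among
patterns (defaults: all timepoints for MCAR; interior timepoints for
MAR/MNAR so scoring variables remain observed); under MAR/MNAR a
weighted-sum score of standardized per-sample mean clr values — over the
still-observed timepoints for MAR, over the candidate timepoints for MNAR
— is pushed through a logistic curve whose offset is tuned by bisection so
the expected missing fraction matches the requested rate. A subject that
would lose every sample keeps its last one.

## Evaluation

`mae_clr()` is the mean absolute clr-scale error over all (missing
sample, taxon) entries. `postprocess_to_ra()` inverts the clr transform,
zeroes entries below the recorded pseudo-count and re-distributes the
deficit equally over the surviving taxa, so outputs are exact
compositions. Shannon and Bray-Curtis are the textbook closed forms
(cross-checked against vegan in the tests); the diversity comparison
reports the paired-t statistic over missing samples, Pearson correlations
of the paired alpha values and of the matched Bray-Curtis upper
triangles, and a seeded 2-D NMDS embedding (coordinates and stress only;
vegan's monoMDS does the embedding). Zero metrics are the symmetric
difference and recall of the zero sets over missing entries; recall is
reported as absent when there are no true zeros.

`benchmark()` runs the 10-fold protocol: subjects are split into folds
and the fold's test subjects are treated as missing. When an amputation
pattern is supplied, the test subjects receive that pattern (training
subjects stay fully observed) and the masked samples are scored — the
cross-validation reading in which the held-out data is "considered to be
missing". Without a pattern, the test subjects' interior timepoints are
masked instead; note that under that variant a subject observed only at
the endpoints makes the neighbour-average estimate coincide with the
subject mean, so method comparisons degenerate.

## Problem sizes and numerical choices

The package's own benchmark runs use the simulator defaults (30 x 8 x 60,
20% MCAR) with training capped at 3000 epochs and plateau patience 500 —
a scaled-down setting chosen so a full 10-fold, five-seed comparison runs
on a laptop; patience below a few hundred epochs stops before the
correction head has learned anything (the adversarial term makes the
total-loss plateau detector fire early). Log arguments are clamped at
1e-7; clr sums are checked to 1e-9; compositions to 1e-6. Ties in
max-pooling take the earlier position; Spearman ties use average ranks.
Degenerate inputs are defined away where possible (all-zero datasets
error; singleton clusters get `rho_bar = 1`; subjects with a single
observed sample fall back to that sample under within-subject baselines).

## Known limitations

* The GAN's advantage over classical interpolation is modest at this
  cohort scale and vanishes when subjects are observed at too few
  timepoints (the discriminator also separates real from fake trivially
  by the zero-row support pattern, so the adversarial signal is weak).
* The MICE baseline is a deterministic single imputation, not full
  multiple imputation with Rubin pooling.
* Phylum labels are the only phylogenetic signal used; no tree distances.
* Subjects sampled at wildly different schedules are supported through
  the union grid and time gaps, but accuracy degrades when few subjects
  share a timepoint.
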