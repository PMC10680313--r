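---
title: "Multi-task prediction of drug-combination synergy and monotherapy sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-task prediction of drug-combination synergy and monotherapy sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the model

High-throughput combination screens report, for a pair of drugs on a cancer
cell line, a Loewe-additivity synergy score: positive values mean the pair
inhibits growth beyond what dose additivity of the two monotherapies would
predict. Screens also yield a monotherapy sensitivity score per drug and cell
line (RI, Relative Inhibition: the normalized, log10-transformed area under
the single-drug dose-response curve, roughly on a 0--100 scale). The two
quantities are biologically coupled — how synergistic a pair is depends in
part on how each partner acts alone — which makes them natural co-tasks for
multi-task learning.

`mtsynergy` jointly learns four outputs in one feed-forward network:

* a synergy regression score (Loewe scale) and a synergy class
  (strongly synergistic iff score > 30, strictly),
* a sensitivity regression score (RI scale) and a sensitivity class
  (sensitive iff RI > 50, strictly).

Inputs are engineered features compressed by pre-trained autoencoders:

* **Drugs** — a hashed circular (Morgan-style) fingerprint of radius 3
  folded to 1024 presence/absence bits, concatenated with the molecular
  descriptor panel of the OpenBabel engine after dropping any descriptor
  with missing values or zero variance across the drug set; columns are
  z-scored. The exact bit mapping of a hashed fingerprint is
  featurizer-specific, so `featurizer_version()` is recorded in feature
  metadata and run manifests, and test fixtures are frozen against it.
* **Cell lines** — log2(TPM+1) expression, genes missing from a profile
  imputed with per-gene reference means, reduced to the 5000 genes of
  largest variance (ties broken by gene identifier), z-scored.

The predictor is a shared trunk of two fully connected layers with batch
normalization and ReLU. For a sample (drug A, drug B, cell line c) the trunk
is applied twice — to [code(A), code(c)] and [code(B), code(c)] — giving
representations I and II. The synergy branch consumes I‖II; the sensitivity
branch consumes I alone, so a drug's predicted sensitivity is independent of
its partner by construction. Each branch is a stack of FC+ReLU+dropout
layers with two heads: a linear regression head and a 2-unit softmax head.
Because concatenation is order-sensitive, every training sample enters in
both drug orders, and reported synergy predictions average the two orders —
making them exactly symmetric in the drugs.

The training objective is the unweighted sum of four terms: mean squared
error for both regressions and binary cross-entropy (probabilities clamped
to [1e-7, 1-1e-7]) for both classifications. The MSE terms are on raw score
scales (hundreds) and dominate the BCE terms (order one); per-term weights
are exposed through variant configuration but default to one to keep the
objective the plain sum.

## Dual cross-validation and leakage control

Synergy generalization is assessed leave-combination-out: unordered drug
pairs are shuffled and dealt round-robin into five folds, so a combination
appears in exactly one fold. Since every individual drug still appears in
all folds, sensitivity needs its own split: drugs are independently dealt
into five drug-folds. In cross-validation round *f*, the model trains on
three combination folds (a fourth, rotating with the seed, is the validation
set for early stopping), and within every training mini-batch the
sensitivity loss skips rows whose row-drug belongs to drug-fold *f*. At test
time, synergy is predicted for every fold-*f* sample, and sensitivity only
for (drug, cell) pairs whose drug is in drug-fold *f* — drugs whose
sensitivity was trained on are never scored. Early stopping monitors the
total validation loss with patience 100 within a 500-epoch cap (package
defaults), keeping the checkpoint with the lowest validation loss; test
predictions come from that early-stopped checkpoint, not a refit.

Hyperparameters follow a grid search over first-layer sizes {2048, 4096,
8192} and learning rates {5e-4, 1e-4, 5e-5}; ties break toward the lower
learning rate, then the smaller layer, so the choice is deterministic.

## Numerical and design choices

Decisions the architecture description leaves open, fixed here:

* **Autoencoders** — two FC encoder layers with ReLU and dropout (0.2)
  between them and a *linear* code layer, plus two decoder layers with ReLU
  between and a linear output; "ReLU between FC layers" is read literally,
  and a ReLU-activated bottleneck also suffers dying-unit collapse on
  narrow codes, so the linear code is both the literal and the numerically
  sound reading. Hidden width defaults to the geometric mean of input and
  code widths rounded to a power of two; reconstruction loss is the
  per-sample sum of squared errors averaged over samples. Encoders are
  frozen after pretraining.
* **Branch geometry** — widths [w, w/2, w/4] from each branch's input
  width; batch normalization only in the trunk; branch dropout 0.5 by
  default.
* **Second trunk layer** — half the first layer's width.
* **Regression-head bias** — initialized at the training-target mean.
  Adam's step size is tiny relative to the raw Loewe/RI scales, so a
  zero-initialized bias would dominate the early loss for hundreds of
  epochs before the fit begins.
* **Z-scoring scope** — normalization statistics are fitted once on the
  full feature matrix before splitting (preprocessing-first); a train-only
  mode exists behind `zscore_scope: train` with the usual caveat that
  feature normalization from test rows is a mild form of leakage.
* **Zero-variance columns** (commonly fingerprint bits constant across a panel)
  are centered and divided by one, not zero.
* **Boundary convention** — both labelers are strictly greater-than; the
  30 boundary is scored negative by definition and the 50 boundary follows
  the same convention for consistency.
* **Classification accuracy** uses a 0.5 cutoff on the positive-class
  probability; PR-AUC integrates the precision-recall curve step-wise
  without interpolation; ROC-AUC is the rank statistic with averaged ties.
* **Seeding** — one top-level seed fans out to stage seeds through a
  documented arithmetic derivation (`derive_seed`), so any stage can be
  rerun in isolation bit-for-bit.

## What the synthetic generator emulates

`simulate_synergy_dataset()` produces a complete miniature screen with no
external files: drugs as valid SMILES composed from a fragment grammar
(ring cores, linkers, common heteroatom groups; rejection-sampled for
parseability and uniqueness), a log-normal TPM matrix with gene-specific
location and scale (so variance ranking is non-degenerate) and round-robin
tissue labels, and score tables planted on the engineered features
themselves: the z-scored drug and cell feature matrices are projected onto
seeded random rotations of their top four principal axes; sensitivity is an
affine function of the drug and cell projections rescaled to roughly 0--100,
and synergy is a symmetric bilinear/trilinear function of the two drug
projections and the cell projection, scaled so that 10% of samples exceed
the positive threshold of 30 before Gaussian noise (sd 5 on both scales) is
added. Planting on dominant principal axes mirrors how real
structure-activity signal rides the main axes of chemical and
transcriptional variation; planting on the *features* (rather than on
detached latent variables) is deliberate, so that a bug anywhere in the
feature pipeline breaks the recovery tests. A small fraction of synergy
rows is duplicated with fresh noise to exercise replicate averaging.

The generator does **not** mimic real chemical space, expression
covariance, or the empirical score distribution of public screens beyond
scale and positive rate. Passing recovery tests therefore demonstrates that
the pipeline, model and training loop work end to end on learnable signal —
not that any particular accuracy holds on real screens.

## The reference study and its problem sizes

The default fixture is 40 drugs × 20 cell lines × 2000 genes with 60% of
the 780 possible pairs, each screened on all cell lines (~9400 synergy
samples), and a full 38 × 20-style sensitivity grid. These sizes keep a
full dual five-fold cross-validation in the minutes range on a single CPU
while leaving enough samples for stable out-of-fold correlations.

At this panel scale some large-screen defaults are counterproductive, so
`small_panel_protocol()` fixes the study configuration: encoder codes of
width 64 (at or above the rank of the 40-drug and 20-cell feature matrices,
so compression is nearly lossless), autoencoder dropout 0 (with 40 training
rows, dropout starves the code of signal), 2000 pretraining epochs (one
epoch is a single Adam step at this size), a 128-wide trunk, branch dropout
0.2, learning rate 1e-3, batch 128, and a 40-epoch predictor budget.
`run_synthetic_study()` runs the full model and the synergy-only ablation on
identical codes, folds and seeds and reports pooled out-of-fold metrics;
`scripts/acceptance.R` is a thin wrapper around it.

```{r}
library(mtsynergy)
study <- run_synthetic_study(seed = 1)
study$metrics
autoplot(study$cv_full, task = "synergy")
```

## Known limitations

* The engine is plain R matrix code: appropriate for the desk-scale
  fixture and for method study, not for screens with thousands of drugs;
  the paper-scale grid search over 8192-wide trunks is expressed but slow.
* Sensitivity generalization is leave-drug-out: with small drug panels the
  task is intrinsically hard, and its out-of-fold correlation is both lower
  and more variable than synergy's — multi-task sharing with the synergy
  task is precisely what pulls it up.
* Classification metrics on the fixture reflect a 10% positive rate;
  PR-AUC in particular is sensitive to that rate and not comparable across
  datasets with different prevalence.
* Replicate averaging treats all replicates equally; there is no
  measurement-error model.
* On the synthetic fixture the synergy-only ablation can match or slightly
  beat the full model on the synergy task: the planted signal is low-rank
  and the synergy table alone is ample to learn it, so the auxiliary task
  mostly adds gradient interference there. The multi-task benefit reported
  on real screens depends on monotherapy data carrying drug-level
  information the synergy table lacks — a situation the fixture does not
  reproduce.
* Leave-drug-out sensitivity metrics on a 40-drug panel rest on eight
  held-out drugs per fold and vary substantially from seed to seed; treat
  any single-seed sensitivity correlation as a point estimate with wide
  uncertainty.
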