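---
title: "Methods: stacked ensemble prediction of RNA m5C sites"
author: "methylstack"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: stacked ensemble prediction of RNA m5C sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The prediction problem

RNA 5-methylcytosine (m5C) site prediction is framed as binary
classification of fixed-width nucleotide windows: a candidate cytosine
plus 20 nt of flank on either side (window length L = 41, the common
convention for this task). Labels are 1 for methylated and 0 for
unmethylated windows; training collections are assumed balanced 1:1, so
no class re-weighting is applied anywhere. Windows are canonicalized to
uppercase DNA (U mapped to T) on input: descriptor tables are defined
over {A, C, G, T}, and public m5C collections derive from bisulfite
sequencing of genomic material, so the package is indifferent to whether
files arrive as RNA or DNA. L must be odd so the 0-based center index
(L − 1)/2 is exact; records that are the wrong length, contain ambiguity
codes (N etc.), or lack a center C are rejected by default — no encoder
has defined behaviour for ambiguity codes — with an opt-in
`skip_invalid` mode that drops them under a logged warning.

## Descriptor families

Eleven deterministic sequence-to-vector transforms cover composition,
positional, and correlational views of a window (dimensions at L = 41
with default parameters):

| encoder | features | captures |
|---|---|---|
| NAC | 4 | global mononucleotide composition |
| Kmer (k = 3) | 64 | global k-mer spectrum |
| CKSNAP (gaps 0–5) | 96 | paired composition at fixed gaps |
| ENAC (window 5) | 148 | locally smoothed composition per position |
| NCP | 123 | per-position chemical-property triples |
| DBE | 160 | per-position 4-bit dinucleotide codes |
| PS2 | 640 | per-position dinucleotide one-hot |
| Z-curve | 3 | purine/pyrimidine, amino/keto, weak/strong balances |
| Mismatch (k = 3, m = 1) | 64 | k-mer spectrum tolerant to substitutions |
| MMI | 30 | pair and triple mutual-information summaries |
| ASDC | 16 | ordered pair composition over all skip distances |

All counting encoders report frequencies rather than raw counts so that
feature scales are window-length independent (at fixed L the two differ
only by a constant). Defaults (k = 3, max gap 5, ENAC window 5,
one-mismatch tolerance) are the conventional published defaults for
these families and every one is overridable per run. The Z-curve is the
3-component global form; the spec slot for a phase-specific variant is
reserved in `encoder_spec()` without an API change. DBE is deliberately
the compact 4-bit binary code (not a one-hot) so it is non-redundant
with PS2; the two are cross-checked in the tests by the exact
decode/one-hot correspondence. For MMI the pairwise term is
I2({x,y}) = f2 · ln(f2/(f1(x) f1(y))) over unordered adjacent pairs, and
the triple term conditions the first two letters of the
alphabetically sorted triple on the third; any vanishing frequency sets
the corresponding term to 0 (the zero-log convention), which keeps every
output finite. Feature names (`Kmer_TAG`, `ENAC_sw.22.G`, `PS2_327`,
...) are part of the public interface because attribution reports rank
them.

## The base-model grid and stacking

Every encoder is paired with every classifier in the roster:
gradient-boosted trees (XGB), AdaBoost.M1 over decision stumps (ADA, the
boosting loop implemented in-package with probabilities from the
logistic link on the ensemble margin), RBF support vector machine (SVM,
with cross-validated Platt scaling for probabilities), extremely
randomized trees (ET), k-nearest neighbours (KNN, k = 5), ridge-penalized
logistic regression (LR, lambda = 1/n, the conventional unit-cost
regularization; ridge keeps the fit well-posed when features outnumber
fold records, as with PS2), random forest (RF), a single-hidden-layer
neural network (MLP, 8 units, weight decay 0.01), Gaussian naive Bayes
(NB), a CART decision tree (DT) and linear discriminant analysis (LDA).
DT doubles as the low-end comparator in meta-classifier swap studies.
Margin, neighbour, linear and network classifiers receive
train-fold-standardized features; tree ensembles consume raw features;
NB and LDA drop features that are degenerate (zero variance) within a
class, which the fixed center cytosine otherwise produces in the one-hot
encoders.

The single most consequential design choice is how the second level sees
the first: meta-features are **out-of-fold probabilities**. One
stratified k-fold assignment (k = 5 by default, matching the customary
5-fold evaluation protocol) is shared by all grid cells so the rows of
the meta-feature matrix are aligned; each record's probability in every
column comes from a model whose training fold excluded that record, and
the final per-cell model is refit on the full training set for new data.
Training on in-fold predictions instead would leak labels into the
meta-level; the test suite checks the operational signature of such
leakage (null-data AUC pulled above chance) directly. Meta-features are
probabilities, not hard labels, preserving the base models' confidence.

The default meta-classifier is a random forest; any roster algorithm can
be swapped in. Voting alternatives share the identical base-probability
matrix: soft voting averages probabilities; hard voting thresholds each
base probability at 0.5 (so all algorithms vote uniformly) and takes the
majority, with an exact half split counted positive — a deterministic,
documented tie-break. The final label uses probability >= threshold
(default 0.5), ties positive, consistently across stacking, voting and
the prediction writer.

## Evaluation and the significance protocol

Threshold metrics (accuracy, sensitivity, specificity, F1, Matthews
correlation) follow their standard 2x2 definitions; a zero-denominator
metric on a degenerate fold is reported as 0 with a warning flag rather
than crashing. AUC uses the rank (Mann–Whitney) formula with tied scores
counted one half, and the reported ROC curve comes from a threshold
sweep over unique scores whose trapezoidal integral equals the rank AUC
exactly. Pipeline cross-validation retrains the whole stack (grid plus
meta) inside each outer-training split, so no outer-held-out record
touches any level of the model scoring it. Cross-species analysis
trains on each tagged species and evaluates on every species'
independent split, reporting all six metrics as tag-by-tag matrices;
diagonal cells are definitionally the single-species independent
evaluations.

Stacked-vs-base comparisons use the per-record absolute prediction
error |p̂ − y|: paired two-sided t and Wilcoxon signed-rank tests on the
per-record error differences. Zero differences are dropped before
ranking (the standard signed-rank convention); a zero-variance
difference vector makes the t-test not applicable (NA, flagged), and an
all-zero one disables both tests — never silently p = 1. Raw p-values are
reported by default, with an optional Holm adjustment across the base
models.

## The synthetic generator: what it emulates and what it does not

The generator emulates the *structure* the pipeline assumes — balanced
classes of fixed-width center-C windows — with a class signal of tunable
strength expressed as positionally biased nucleotide composition: by
default the six positions within ±3 of the center emit G with
probability 0.9 (strong), 0.45 (weak) or the background 0.25 (null)
in positives, against a uniform background. Positional composition was
chosen as the default signal because most of the eleven descriptor
families can express it, so end-to-end tests separate encoder bugs from
ensemble bugs; a dinucleotide-correlation mode (first-order Markov
positives with elevated stay probability) exercises the pair-based
encoders specifically. Under the strong setting the generating model
itself bounds what any pipeline can recover: the Bayes-optimal count
discriminant has AUC ≈ 1, and the tests verify a simple count statistic
reaches ≥ 0.95.

Two-species experiments generate either a shared motif (transfer should
succeed) or independent motifs (no transfer signal should exist). For
the independent case, each species' signal positions are drawn from
disjoint flank pools (upstream vs downstream of the center) and the
motif is composition-balanced — five positions enrich the species'
signal nucleotide at p = 0.5 and five deplete it to p = 0, keeping the
positives' expected global composition equal to background. The balance
matters: a one-sided enrichment shifts global composition, which
global-composition features (NAC, Kmer) of a foreign-trained model can
read, producing systematic spurious transfer; the balanced construction
makes the foreign species background-distributed in both the positional
and the global statistics of the trained model's feature space.

The generator does **not** emulate bisulfite-conversion error, coverage
noise, real m5C motif biology, non-uniform genomic background
composition, or homology between training and test windows. Passing
tests therefore demonstrate that the machinery is correct (leakage-free
stacking, faithful encoders, calibrated evaluation), not that any
particular accuracy will be attained on real species data.

## Numerical and statistical choices

- **Determinism.** Every stochastic step (folds, model fits, Shapley
  permutations, t-SNE init) derives its seed from the run seed; xgboost
  and ranger run single-threaded. Identically seeded runs reproduce
  metric tables to 1e-8 (bit-identical for most learners).
- **Statistical bands in tests.** Chance-level checks (null AUC within
  0.5 ± 0.06, null grid accuracy within 0.5 ± 0.07) are asserted on
  seed-averaged statistics: at the study sizes used (n = 400 per split,
  3 seeds) a single-draw AUC has standard error ≈ 0.04, so the band is
  applied where the averaging makes it a ≥ 2.5-sigma bound; similarly
  the generator's positional-frequency convergence uses a family-wise
  4-sigma bound across the ~160 position-by-nucleotide cells. These
  calibrations come from the binomial/Mann–Whitney variance formulas,
  not from observed test outcomes.
- **Attribution backends.** Gradient-boosted cells are explained by the
  exact tree-path algorithm (TreeSHAP) on the margin (log-odds) scale;
  all other models by Monte-Carlo permutation Shapley values on the
  probability scale, with a fixed background subsample (≤ 100 rows) and
  fixed permutations. Both backends satisfy local accuracy — the
  per-record attribution sum telescopes to the model output minus the
  base value — to 1e-8 for the sampling backend (double precision) and
  1e-5 for the tree backend, whose library stores contributions in
  float32.
- **t-SNE.** Exact-gradient descent on the KL divergence (perplexity 30
  by default, early exaggeration ×4 for 100 iterations, momentum
  0.5→0.8, adaptive gains, 500 iterations), O(n²) per iteration — at the
  embedding sizes used here (n ≤ ~1000 probability vectors) the exact
  algorithm is fast and removes approximation error; embedding quality
  is asserted only through separability preservation, never absolute
  coordinates. Requesting a perplexity with n ≤ 3·perplexity errors
  with a suggested maximum.
- **Degenerate inputs.** Single-class training data, misaligned labels,
  mismatched window lengths, unknown grid cells and malformed FASTA all
  raise early, named errors; empty prediction sets write a header-only
  table.

## Problem sizes

Library-scale runs in the tests and the acceptance script use a reduced
3-encoder × 3-classifier grid (NAC, NCP, Kmer × LR, NB, RF) on 400
training and 200–400 independent synthetic windows — sizes chosen so the
full battery (null controls over three seeds, transfer contrasts,
power simulations) completes in minutes on one CPU while keeping every
statistical band meaningful. The full 11 × 11 grid on collections of
tens of thousands of windows is supported by the same code paths; the
per-cell cost is dominated by SVM/MLP fits and scales linearly in the
number of cells.

## Known limitations

- CatBoost and LightGBM, which appear in some published rosters of this
  task, have no maintained R implementation used here; the roster keeps
  eleven families by including CART and LDA instead, and any cell can be
  replaced through the classifier registry.
- Probabilities of the final ensemble are not calibrated; thresholded
  decisions at 0.5 are well-defined but the scores should not be read as
  calibrated posteriors.
- The hard-voting fraction is a score, not a probability; its ROC is
  coarse when the number of base models is small.
- Genome-scale scanning (extracting candidate windows from references)
  and upstream site calling are out of scope; inputs are pre-extracted
  windows.
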