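---
title: "Classifying marmoset vocalizations with Optimum-Path Forests"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying marmoset vocalizations with Optimum-Path Forests}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(callforest)
```

`callforest` classifies common-marmoset call types from audio. This
vignette is the package's account of the method: the signal chain, the
LPC feature model, the Optimum-Path Forest classifier, the evaluation
metrics and experiment protocols, and the design decisions behind each —
including what the synthetic test corpus does and does not establish.

## The signal chain

Marmoset calls carry most of their energy between 4 and 10 kHz, well
above cage clatter and air handling. Recordings (44.1 kHz mono WAV) are
therefore band-pass filtered to that band before anything else. The
filter is a 4th-order Butterworth applied forward and backward
(`signal::filtfilt`), a standard bioacoustics choice: zero phase shift
means segment boundaries computed on the filtered signal line up with the
raw waveform, and the squared magnitude response rolls off steeply enough
that a 100 Hz hum is attenuated below 1% RMS while a 7 kHz whistle passes
essentially unchanged.

Segmentation follows an amplitude-threshold rule: a call candidate spans
from `pad_s` (default 0.5 s) before its first threshold crossing to
`pad_s` after its last. Two conventions had to be fixed where practice
varies:

* **Threshold.** Field recordings differ in noise floor, so the default
  threshold is `5 * median(abs(x))` — the median of a signal that is
  mostly silence estimates the noise floor robustly, and a factor of 5
  sits far above it while staying below call amplitudes. It is exposed as
  a parameter for corpora where that heuristic fails.
* **Event grouping.** Nothing in the segmentation rule itself says when
  two bursts are one call. We merge crossings whose padded spans overlap,
  so bursts closer than `2 * pad_s` form one segment. With the default
  padding this correctly keeps a multi-whistle Phee (gaps ~0.15 s) or a
  Twitter (gaps ~0.04 s) as a single call, while bouts separated by more
  than a second split apart. This is a convention of this package, not a
  property of the corpus.

Stereo input is averaged to mono with a warning; every downstream stage
assumes a single amplitude sequence.

## LPC features

Each call is summarized by the coefficients of an order-$n$ linear
predictor $\hat{x}_t = \sum_{k=1}^{n} a_k x_{t-k}$: the spectral-envelope
description standard in speech processing. The default order is 20,
chosen after comparing orders 10–25 in steps of 5 (prediction-error power
is monotone non-increasing in order; 20 balances detail against
dimensionality for calls of this bandwidth). One vector describes one
whole call — no framing or frame-averaging — which is the simplest
mapping of "n features per call" and keeps every classifier's input a
plain 20-column table.

The estimation pipeline is: Hann window over the whole call (suppressing
the hard edges segmentation leaves), biased autocorrelation to lag $n$
(the biased estimator guarantees a positive semi-definite sequence), then
the Levinson–Durbin recursion. Two further stabilizers, both standard in
speech coding, are applied to the autocorrelation:

* a **Gaussian lag window** of 60 Hz equivalent bandwidth, and
* a **white-noise correction** inflating $r_0$ by $10^{-4}$.

These matter because tonal marmoset calls (Phee, Loud-shrill, Seep) are
nearly pure sinusoids: their autocorrelation matrix is numerically
rank-deficient, and without regularization the recursion returns huge,
unstable coefficients whose within-class scatter swamps the
between-class structure. Lag windowing broadens each spectral peak
slightly (60 Hz is negligible against the ≥700 Hz spacing of the call
types' carriers), and the noise floor bounds the spectral dynamic range.
With them, coefficients are $O(1)$ and vary smoothly with carrier
frequency. LPC is amplitude-scale invariant, so recording gain never
leaks into the features. The gain/error term is not included as a
feature; the $n$ predictor coefficients alone are the feature vector.

## The Optimum-Path Forest classifier

OPF treats classification as competition on a graph. The training
samples form a *complete* graph (the original and most widely used
supervised variant — not the k-NN-graph variant) whose arcs are weighted
by a distance between feature vectors. Training has three steps:

1. **Prototype election.** A minimum spanning tree is computed over the
   training distances; every endpoint of an MST edge whose endpoints
   carry different labels becomes a prototype. Prototypes thus sit
   exactly on class frontiers, where errors concentrate.
2. **Competition.** A path's cost is its maximum arc weight
   ($f_{\max}$); prototypes start at cost 0 and all other paths at
   $+\infty$. Each sample's optimum cost $C(s)$ is the minimum over all
   paths from any prototype of that bottleneck cost, and the sample
   inherits the label of the prototype whose tree conquered it. The
   propagation is a priority-queue minimax variant of Dijkstra's
   algorithm — correct for $f_{\max}$ because the cost along any path is
   non-decreasing.
3. **Ordering.** Nodes are stored sorted by ascending cost.

Classification evaluates $\min_s \max\{C(s), d(s,t)\}$ over training
nodes $s$, walking the cost-ordered list and stopping as soon as the next
stored cost cannot beat the best value found — the efficient
classification step of the complete-graph OPF. The test suite verifies
against two independent oracles (exhaustive minimax path enumeration, and
a naive full scan) that neither the queue-based training nor the
early-stopped search changes any result.

Ties — equal MST edge weights, equal path costs, equal classification
values — are broken toward the lower node index throughout, making
training and prediction fully deterministic. Duplicated feature vectors
across classes produce a zero-weight frontier edge (both endpoints become
prototypes) and a warning.

Five arc-weight metrics are supported: Euclidean, Manhattan, Canberra,
chi-square and Bray–Curtis. The last three are textbook-defined only for
non-negative data, and LPC coefficients are signed, so explicit
conventions are used and documented: Canberra skips components with
$|x_i|+|y_i|=0$; chi-square uses $\sum (x_i-y_i)^2/|x_i+y_i|$ with
zero-denominator terms skipped; Bray–Curtis is
$\sum|x_i-y_i| / \sum(|x_i|+|y_i|)$. Their known weakness on signed
features is the point of including them as comparisons. Because
$f_{\max}$ and the classification argmin are order statistics, any
monotone transform of the distances (e.g. squaring, as some OPF
implementations do internally) leaves predictions unchanged; a property
test confirms this.

## Comparison classifiers

The six baselines delegate numerics to mature implementations behind one
`train_baseline()` surface — the bespoke science here is OPF and the
metrics, not SVM solvers:

| algorithm | backing | protocol |
|---|---|---|
| Gaussian Bayes | own (chol-based) | per-class full covariance, empirical priors; ridge regularization on degenerate covariances (warned) |
| MLP | own (optim L-BFGS-B) | hidden layers (8, 16), softmax cross-entropy, iteration cap 2000 with convergence warning |
| SVM (RBF/linear/poly) | e1071/libsvm | 5-fold CV over $C \in \{2^{-5},2^{-3},...,2^{15}\}$, $\gamma \in \{2^{-15},...,2^{3}\}$ (11 × 10 grid) |
| k-NN | class::knn | 5-fold CV over odd $k \in [1, \lfloor m/5 \rfloor]$, Euclidean |
| logistic regression | glmnet | L2, one-against-all, fixed small $\lambda$ |
| AdaBoost | own SAMME.R over rpart | 50 rounds of depth-3 trees |

The MLP is written in-package (a two-hidden-layer softmax network trained
with `optim`'s limited-memory BFGS) because single-hidden-layer
implementations cannot express the (8, 16) architecture; likewise
AdaBoost-SAMME.R is a short, well-specified reweighting loop over
weighted `rpart` fits. Depth-3 base trees (rather than stumps) are used
because one-node stumps are too weak for an 8-class, 20-feature problem;
the round count (50) follows common practice. The linear and polynomial
SVM variants reuse the RBF $C$ grid, as no separate grid is specified for
them. Cross-validation folds shrink (with a warning) when the rarest
class has fewer members than folds. Each training run is seeded, so a
repeated fit with the same seed reproduces identical predictions.

## Evaluation metrics

The headline accuracy is deliberately *restrictive*: for each class $i$,
$e_{i,1} = FP_i / (N - N_i)$ and $e_{i,2} = FN_i / N_i$, total error
$E_i = e_{i,1} + e_{i,2}$, and
$\mathrm{Acc} = 1 - \sum_i E_i / 2K$. Unlike raw hit rate, a classifier
that always answers the majority class scores 0.5 on two balanced
classes, and errors against small classes weigh as much as errors
against large ones. For $K = 2$ with equal class sizes this accuracy
provably equals the mean per-class recall; the suite checks the identity
on 1000 random matrices. Alongside it the package reports per-class
sensitivity, precision and F1, macro-F1 (unweighted, appropriate for the
near-balanced 27–30-exemplar classes), and the mean row-normalized
diagonal ("balanced accuracy") used to summarize the sub-class confusion
tables. A class never predicted gets precision and F1 of 0 with a
warning rather than NaN.

For hierarchical classification, the **compounded accuracy** of a
sub-class is the product of its principal class's sensitivity and its own
sub-class sensitivity — the probability that both routing stages succeed.
The package ships the real corpus's reference confusion tables
(`reference_confusions()`, percent scale, rows = true class), from which
`reference_compounded()` reproduces the reported rates: overall sub-class
accuracies of 83% (Tsik table) and ~56% (Phee table), and compounded
accuracies 58% / 38% / 42% for Phee-2/3/4 and 70% / 58.5% for Tsik /
Tsik-ek. Two arithmetic quirks of the published narrative are noted and
left as printed: a "remaining 64%" whose components sum to 54%, and "52%"
for a 51.2% table cell.

## Experiment protocols

`stratified_split()` assigns $\lceil f \cdot n_i \rceil$ samples of each
class to training (each side always keeps ≥1 per class) — stratification
is used even though plain splitting would be simpler, because the
balanced accuracy is undefined for a class absent from the test set; the
ceiling rule reproduces the 27/3 partition of a 30-exemplar class at
$f = 0.9$. `run_sweep()` crosses algorithms with training fractions
(default 0.1–0.9) and repetitions (default 100), aggregating mean ± SEM
(`sd/sqrt(reps)`) and accumulating confusion counts. Repetition $r$ uses
seed `base_seed + r`, identical across algorithms so all classifiers see
the same partitions; seeds are recorded for replay. Hyperparameter
searches re-run inside every repetition — the search is part of training.
Per-sample prediction time is recorded but never asserted: it is
hardware-dependent. `hierarchical_eval()` runs the two-stage protocol:
an 8-class principal task after merging Phee-2/3/4 → Phee and
Tsik/Tsik-ek → Tsik, plus dedicated sub-classifiers trained on the Phee
and Tsik exemplars only.

## The synthetic corpus, and what passing tests show

`synth_dataset()` generates deterministic stand-ins for the 11 call
types: FM tones, band-limited noise bursts and mixed chevron-plus-tail
shapes in the 4–10 kHz band, with 0.6 s of context, white noise at 5%
relative RMS by default, and seeded per-call jitter (±10% duration, ±5%
carrier). The archetypes are loosely modeled on the call types'
spectrogram shapes — Twitter as eight rapid upsweeps, Trill as 30 Hz
sinusoidal FM, Phee-$n$ as $n$ long whistles — and are spaced in carrier
frequency and bandwidth so their LPC envelopes separate cleanly. Default
sizes mirror the real corpus: 30 exemplars per class, ~240 calls for the
eight-class task.

These fixtures establish *plumbing*, not biology: that segmentation,
feature extraction, training, prediction and scoring compose correctly,
that accuracy is high when classes are separable by construction, that it
degrades as synthetic noise rises, and that it grows with training
fraction. Real marmoset calls vary in ways the generator does not emulate
(caller identity, amplitude modulation detail, overlapping calls,
colony reverberation), so synthetic accuracies say nothing quantitative
about real-data accuracy — reproducing the real-data comparison requires
downloading the corpus and running
`inst/scripts/replicate_real_data.R`, which asserts only that each
algorithm beats chance.

Scales used by the shipped checks were chosen to exercise each claim at
desk scale: the end-to-end acceptance run uses the eight principal
archetypes at 30 calls/class with 20 repetitions of the 90%/10% split;
oracle-equivalence sweeps use 200 random training sets of ≤10 samples
(where exhaustive path enumeration is feasible); AR-process recovery uses
$10^5$-sample realizations.

## Known limitations

* WAV support covers PCM and IEEE-float RIFF files — the corpus format —
  not compressed or extensible-format WAV.
* One LPC vector per call discards temporal structure *within* a call;
  sub-classes that differ mainly in syllable count (Phee-2/3/4 share a
  carrier) are genuinely hard for this representation, for the synthetic
  generator as for the real corpus.
* The Gaussian Bayes classifier estimates full covariances; with fewer
  samples than features per class it leans on its ridge regularization.
* Canberra, chi-square and Bray–Curtis distances on signed LPC features
  use the documented sign conventions; they are included as comparisons,
  not recommendations.
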