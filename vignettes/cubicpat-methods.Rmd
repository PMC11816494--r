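---
title: "Cubic-pattern EEG features, CWINCA selection and tkNN: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cubic-pattern EEG features, CWINCA selection and tkNN: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cubicpat)
```

## The model

`cubicpat` classifies fixed-length multichannel EEG epochs with a pipeline
whose every stage is an explicit, deterministic computation: ordinal
channel-triplet features, cumulative-weighted iterative NCA selection
(CWINCA), an ensemble kNN with iterative majority voting (tkNN), and a
symbolic decoding of the selected features into cortical-lobe sequences
(Directed Lobish).

### Cubic-pattern features

For an epoch of `ln` time samples over `n >= 3` channels, each time sample's
channel vector is sorted in descending order; ties keep ascending channel
index (a stable sort — quantized EEG does produce exact ties, so the rule is
pinned rather than left to chance). Each consecutive triplet of the rank
permutation `id` is coded as a base-`n` integer

$$\mathrm{map}_j = (id_j - 1)\,n^2 + (id_{j+1} - 1)\,n + (id_{j+2} - 1),
\qquad j = 1, \dots, n-2 ,$$

and the epoch's feature vector is the histogram of all `ln (n-2)` codes over
the fixed support `0..n^3 - 1`. Consequences worth stating:

* **Conservation.** `sum(counts) = ln (n - 2)` always; this is the single
  strongest internal check and is asserted throughout the test suite.
* **Rank invariance.** Any strictly increasing transform of the whole epoch
  (gain, offset, monotone nonlinearity) leaves the features bit-identical.
  Amplitude calibration between recording systems therefore cannot leak into
  classification.
* **Time-permutation invariance.** The histogram ignores temporal order
  within the epoch; the features measure how often channel-amplitude
  *orderings* occur, not when.
* **Support.** Without ties at most `n (n-1) (n-2)` of the `n^3` bins can be
  hit (triplet digits are pairwise distinct); the dense length-`n^3` vector
  is kept anyway for simplicity at this scale (32,768 doubles at n = 32).

Internally bins are 0-based (`bin = map`); R's 1-based indexing appears only
at the storage boundary (`counts[map + 1]`).

### CWINCA selection

Features are weighted by neighborhood component analysis with a diagonal
metric. Writing `D_ij = sum_f w_f^2 (x_if - x_jf)^2`, soft neighbor
probabilities `p_ij = exp(-D_ij) / sum_{k != i} exp(-D_ik)` define the
leave-one-out objective

$$F(w) = \sum_i \sum_{j \in \mathrm{class}(i)} p_{ij}
       \; - \; \lambda \sum_f w_f^2 ,$$

maximized by projected gradient ascent (weights clipped at zero) with an
adaptive step. Numerical choices, all exposed as arguments of
`nca_weights()`:

* distances are rescaled once so the mean pairwise distance at the uniform
  start `w = 1` equals 1, making the exponential kernel scale-free on raw
  histogram counts (no standardization by default; a `standardize` flag
  exists);
* ridge penalty `lambda = 1` drives uninformative features toward zero;
* convergence at objective change `< 1e-6`, at most 100 iterations;
* the fit is deterministic — no random initialization — so identical inputs
  give identical weights; duplicated columns receive equal weights by
  symmetry of the updates.

The selection loop range is the pair of prefix lengths at which the
cumulative normalized weight (features sorted by descending weight, ties
broken by ascending index) first reaches 0.75 (`sv`) and 0.99 (`fv`). Within
`[sv, fv]` each prefix is scored by the inner accuracy calculator — 1-NN,
Euclidean, stratified 10-fold CV with a fixed fold seed; the simplest kNN,
since only k and metric are open choices here — and the first maximum wins,
favoring the smaller feature set on ties. Selected sets are nested by
construction: the set of size `a` is a prefix of the set of size `a + 1`.

A cumulative-sum guard of `1e-9` absorbs floating-point round-off at exact
threshold hits (e.g. 100 equal weights must give `sv = 75`, not 76).

### tkNN classification

The ensemble sweeps `k = 1..5`, distances {cityblock, chebyshev, euclidean}
and vote weighting {inverse, equal}: 30 configurations, each producing one
out-of-fold prediction per sample. Fold schemes are stratified 10-fold
(within-class shuffle under the run seed, dealt round-robin) or
leave-one-subject-out (every subject's epochs form one test fold). The 30
outcomes are sorted by descending accuracy (stable on ties) and for each
`q = 3..30` the per-sample mode of the top-`q` predictions is added — 28
voted outcomes. The final outcome is the accuracy argmax over all 58
candidates, so it dominates every single configuration by construction.

Deterministic tie rules (the bare mode and argmax leave these open):

* neighbor ties at equal distance: training index order (stable sort);
* label-vote ties inside kNN: the label of the nearest neighbor carrying a
  tied label;
* inverse weighting at distance zero: the zero-distance neighbor's label
  outright (so inverse and equal weighting coincide exactly at `k = 1`);
* mode ties in majority voting: the label predicted by the most accurate
  participating outcome;
* argmax ties among the 58 candidates: lowest candidate index (a
  parameter-based outcome beats an equally accurate voted one).

Sorting and the final argmax use plain overall accuracy on the same
cross-validated predictions that produced the outcomes.

Metrics come from the confusion matrix: accuracy, per-class recall and
precision, per-class and macro F1, and the geometric mean of per-class
recalls. Per-class F1 is reported alongside the macro average because a
single-class F1 on the majority class can exceed accuracy and the two are
easy to confuse when comparing published tables.

### Directed-Lobish decoding

A selected feature index `value` is decoded by base-`n` digit separation,
`ch_j = (floor((value-1)/n^{j-1}) mod n) + 1`, `j = 1, 2, 3`. The digits
emerge in *reverse* of the encoding order, so by default the triplet is
reversed before symbol lookup, making the emitted symbols follow the
original rank order `(id_j, id_{j+1}, id_{j+2})`. Histogram and entropy are
order-independent; transition tables are not, which is why the choice is
explicit (`symbol_order = "decoded"` keeps the raw digit order).

Each channel maps to a lobe symbol through a montage lookup table; the
bundled `lut32` and `lut14` cover the two supported caps, and both are
locked by golden tests. The 14-channel montage spans only 8 of the 14
symbols (no midline or central electrodes), so its maximum sequence entropy
is `log2(8) = 3` bits; the 32-channel montage spans all 14
(`log2(14) = 3.8074` bits). Entropy is computed from the symbol histogram
(not the transition matrix), in bits throughout, and the complexity ratio is
`100 * entropy / log2(alphabet size)`. The connectome graph has the symbols
with nonzero histogram as nodes and transition counts as directed edge
weights, exported as GraphML or DOT.

## The synthetic-data generator

Real mental-performance and stress EEG corpora of this design are private,
so the generator emulates their *shape*: binary labels, many epochs per
subject, 14 or 32 channels, 15 s epochs at 128 or 256 Hz (defaults: 14
channels, 128 Hz, 10 subjects per class x 10 epochs = 200 epochs).

Because the features are pure rank statistics, the class signal is planted
where the statistic looks: per-channel **gain order**. Class-2 epochs have 4
evenly spaced channels scaled by `1 + effect_size` (default 3x); a purely
spectral contrast would be invisible to the features and make every test
vacuous. Each subject carries a multiplicative log-normal per-channel gain
`exp(subject_sd * z)`, and epochs are an oscillatory mixture (theta/alpha/
beta sinusoids with random phases on a fixed per-channel amplitude profile)
plus white Gaussian noise. Pink-noise realism, artifacts and true
physiological structure are deliberately out of scope: passing tests show
the pipeline recovers rank-order contrasts under subject heterogeneity, not
that it detects any particular cognitive state in real recordings.

Two behaviors of the generator matter for interpreting tests:

* **Subject identity is a signal path under 10-fold CV.** With
  `subject_sd > 0`, labels are constant within subject and the subject's
  gain signature is learnable, so sibling epochs in training folds let kNN
  beat chance even at `effect_size = 0`. That is a real property of
  within-subject validation, not a bug — it is why LOSO accuracies trail
  10-fold accuracies, and the package asserts that ordering as a trend over
  seeds. Consequently the chance-calibration check (zero effect, accuracy
  inside the 95% binomial band of 0.5) is run on iid epochs
  (`subject_sd = 0`), where label exchangeability actually holds.
* **The final tkNN accuracy is a maximum over 58 correlated candidates**,
  hence an optimistic statistic; on null data it sits above the median
  single-configuration accuracy. The binomial chance band is therefore a
  tight check, and users comparing to it should prefer the nested,
  subject-grouped configuration for honest generalization estimates.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `epoch_seconds` | 15 s | epoch duration; `ln = fs * epoch_seconds` samples |
| `t_low`, `t_high` | 0.75, 0.99 | cumulative-weight bounds of the selection loop |
| inner evaluator | 1-NN, Euclidean, 10-fold | accuracy calculator inside selection |
| `k` grid | 1..5 | ensemble kNN neighbor counts |
| distances | cityblock, chebyshev, euclidean | ensemble metrics |
| vote weights | inverse, equal | ensemble weighting schemes |
| IMV range | q = 3..30 | top-q majority votes (28 outcomes) |
| `lambda` | 1 | NCA ridge penalty |
| `seed` | 1 | controls every fold shuffle and the generator |

## Pipeline order and leakage

`run_pipeline()` follows the literal stage order: selection is fit once on
the full feature matrix, then the classifier is cross-validated on the
selected columns. This mirrors the reference procedure but lets selection
see test labels (a caveat shared by most published feature-engineering
pipelines). `run_config(nested = TRUE)` re-fits the entire selector inside
every training fold for leak-free estimates; it is the recommended setting
for reporting generalization and the default remains the literal order for
comparability.

## Degenerate inputs and numerical edges

* Epochs with missing values are rejected with the offending time sample;
  no imputation.
* `k` larger than a training fold is truncated with a warning (relevant for
  LOSO with few subjects).
* All-zero NCA weights make the cumulative range undefined — an error, not
  a silent fallback.
* Single-symbol sequences have a zero transition matrix and zero entropy;
  empty selections give empty sequences.
* An entropy exceeding `log2(alphabet)` (beyond `1e-9`) is an invariant
  violation and errors.

## Problem sizes used by the shipped checks

The structural ensemble check runs on 200 epochs of 2 s at 64 Hz (the
30/28/58 counts are size-independent); the end-to-end recovery and
chance-calibration checks run at the full study shape — 200 epochs of 15 s
at 128 Hz, 14 channels — and the remaining suites use 5x4 to 30x10 epochs,
sizes at which the brute-force oracles are exact and fast.

## Known limitations

* Only within-epoch rank structure is visible: contrasts expressed purely in
  spectra or temporal dynamics at equal amplitude ranks are undetectable by
  design.
* The 58-way maximum makes reported accuracies optimistic; use
  `nested = TRUE` with LOSO for honest estimates.
* No preprocessing (filtering, re-referencing, artifact rejection) is
  implemented or assumed.
* EDF or other binary acquisition formats are not read; epochs enter as
  numeric CSV plus a manifest, or in memory.
* Multiclass inputs are handled by the natural mode/argmax generalizations,
  but the geometric mean and the published operating points target binary
  problems.
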