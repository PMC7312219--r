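---
title: "Bi-objective EEG channel selection: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bi-objective EEG channel selection: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Scalp EEG for seizure monitoring is recorded with dense montages (here the
22-channel longitudinal bipolar montage, `chb_montage`), but portable
seizure-detection devices need few electrodes. Channel selection is
therefore a genuinely bi-objective problem: maximize the cross-validated
accuracy of a seizure/seizure-free classifier while minimizing the number
of channels it needs. There is usually no single best answer — the
deliverable is the Pareto front of (accuracy, channel count) trade-offs,
from which a device designer picks.

`eegselect` implements this as a wrapper search. Each candidate channel
subset is encoded as a binary chromosome (one gene per channel), scored by
actually training and cross-validating a classifier portfolio on that
subset's features, and evolved with from-scratch NSGA-II and NSGA-III
implementations. A greedy backward-elimination baseline is included for
comparison.

## The pipeline

1. **Epochs.** 6-second multichannel epochs at 128 Hz (768 samples), in
   balanced seizure/seizure-free classes. Real EDF recordings are
   down-sampled from 256 Hz with a zero-phase anti-alias filter (cutoff
   0.45 x the target rate) and cut into non-overlapping windows that never
   straddle an annotated seizure boundary; controls are drawn seeded and
   uniformly from fully-outside windows, with an optional exclusion margin
   (default 0 — the proximity of controls to seizure onset is not
   specified by the data conventions we follow, so it is a parameter, not
   a guess).
2. **Sub-bands.** Each channel's epoch is decomposed either by empirical
   mode decomposition (EMD) or a 4-level discrete wavelet transform with
   the biorthogonal 2.2 mother wavelet. At 128 Hz the DWT sub-bands
   (A4, D4, D3, D2, D1) cover 0-4, 4-8, 8-16, 16-32 and 32-64 Hz — the
   classical EEG rhythms. For EMD, the two IMFs closest to the original
   signal in Euclidean (Minkowski p = 2) distance are retained; distant
   IMFs are the classical symptom of redundant sifting output.
3. **Features.** Four features per sub-band: instantaneous log-energy,
   Teager log-energy, Higuchi fractal dimension, Petrosian fractal
   dimension — 8 features per channel for EMD (2 IMFs x 4) and 20 for DWT
   (5 bands x 4). The two energies capture amplitude/frequency content;
   the two fractal dimensions capture waveform roughness, which
   discriminates spike-wave discharges from background.
4. **Fitness.** A channel subset is scored by the best mean stratified
   k-fold CV accuracy over a four-family classifier grid: margin
   classifier with sigmoid/linear/RBF kernels, kNN with 1-9 neighbours,
   random forest with depths 2-5, and Gaussian naive Bayes.
5. **Search.** NSGA-II or NSGA-III over chromosomes, fitness
   (accuracy, channel count), population 20, at most 500 generations,
   with an objective-space tolerance of 1e-4 checked every 5th
   generation. Backward elimination provides the greedy baseline
   (exactly C(C+1)/2 = 253 evaluations for C = 22).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| `fs`, `duration_s` | 128 Hz, 6 s | epoch convention of the target datasets; 768 samples |
| DWT wavelet, levels | bior2.2, 4 | fixed from prior work; yields the five rhythm bands |
| EMD `sd_threshold` | 0.2 | classical sifting stop (normalized squared change between iterates); the source describes sifting only in a figure, so the stop rule is this package's choice |
| EMD `n_keep`, `minkowski_p` | 2, 2 | two closest IMFs by Euclidean distance |
| Higuchi `k_max` | 10 | conventional for N around 768; never stated upstream, configurable |
| energy floor | 1e-12 | log-energies are undefined for silent bands; floored at -12 |
| CV folds `k` | 10 | reduced automatically to the smaller class size (e.g. 9-fold) |
| population, generations | 20, 500 | stated search budget |
| `tolerance`, `check_interval` | 1e-4, 5 | front-movement termination (below) |
| crossover, mutation | 0.9 two-point, 1/C bit-flip | canonical NSGA settings; unstated upstream |
| NSGA-III partitions `p` | N - 1 | Das-Dennis point count equals the population size for M = 2 |
| forest size | 100 trees | only depth 2-5 is specified; tree count is this package's choice, configurable |

## Numerical and design choices

**Teager energy index range.** The printed operator sums
`|w(r)^2 - w(r-1) w(r+1)|` for r up to N-1 but needs both neighbours, so
the sum runs over the interior r = 2..N-1 while the divisor stays N.

**Petrosian binarization.** Sign of the first difference, zero differences
inheriting the previous sign; the sign-change count of that sequence is
N-del. This is the standard construction; the binarization is not specified
upstream.

**Higuchi degenerate input.** A constant signal has zero curve length at
every scale; the implementation warns and returns the sentinel 0. Sub-band
k_max is clamped for very short sub-bands so the N > 2 k_max precondition
always holds.

**Higuchi increments.** The curve length uses absolute increments
|X(m+ik) - X(m+(i-1)k)|; without the absolute value the inner sum
telescopes and lengths could be negative.

**Missing IMFs.** Epochs whose residue oscillates too little to yield
`n_keep` IMFs get zero-filled feature blocks, keeping the per-channel
feature count fixed at 8.

**Fitness = grid maximum.** Parameter selection uses CV accuracy on the
same folds that report it, mirroring the original wrapper design. This is
optimistically biased — on pure-noise features with 80 instances the
best-of-grid accuracy sits around 0.55-0.75 rather than 0.5, shrinking
toward 0.5 as n grows (the permuted-label tests quantify this). Accuracy
ties break by fixed family priority (margin classifier, kNN, forest,
naive Bayes) so classifier-usage statistics are deterministic.

**Per-fold standardization.** Features are centred/scaled with
training-fold statistics only; margin and neighbour classifiers are
scale-sensitive and the upstream convention is unstated.

**Classifier implementations.** No SVM/forest/kNN packages are available
in the target environment, so the portfolio is self-contained: the margin
classifier is kernel regularized least squares (the LS-SVM form) with
regularization 1/cost and kernel scale gamma = 1/(p var), which preserves
the kernel grid being searched; the random forest (gini, mtry = sqrt(p),
bootstrap, majority vote) is compiled C++ with its own deterministic RNG;
kNN breaks vote ties by the nearest neighbour's label; naive Bayes is
Gaussian with a 1e-9 variance floor.

**Termination metric.** "Objective-space tolerance" is defined here
explicitly (it is a library default upstream, undocumented): snapshot the
archive front at every check; match entries between consecutive snapshots
by channel count; the change is the maximum |delta accuracy| over matched
entries (accuracy already lives in [0,1]; channel counts are matched so
their change is zero), and an unmatched channel count counts as change 1.
Terminate when the maximum change is below the tolerance. Tolerance 0 is
allowed and makes the criterion unreachable — useful for exercising the
500-generation ceiling.

**The archive is the result.** All best solutions found anywhere in the
run are reported, not the final population: the archive keeps the best
accuracy ever observed per channel count (with the winning classifier and
the generation it was found), pruned to the mutually non-dominated set.
Equal accuracies prune toward fewer channels. Fitness evaluations are
memoized by subset bitmask with a fixed CV seed per run, so each subset
has a unique accuracy and re-evaluation is free.

**Backward-elimination counting.** The full-montage evaluation is counted,
making the total C(C+1)/2 = 253 for 22 channels; ties on accuracy remove
the lowest-index channel.

## What the synthetic generator emulates — and what it does not

`generate_epochs()` produces balanced two-class epochs in which the class
signal lives only on a known channel subset: background is per-channel
pink (1/f) noise plus a 10 Hz alpha sinusoid at 0.3 relative RMS; seizure
epochs add a sharpened 3 Hz spike-wave surrogate (a cubed sinusoid, so
that both energy and fractal features respond) scaled to `snr` times the
background RMS on the informative channels. All component phases are
random per epoch, and one global seed expands to per-epoch substreams so
the result is order-independent.

Defaults mirror the data conventions the pipeline targets: ~80 epochs per
class would match the real per-patient datasets; the desk-scale tests use
40+40. `snr = 3` makes a planted channel essentially perfectly separable
— which is what the recovery tests require; at `snr = 0` the two classes
are generated identically.

This stand-in deliberately omits: realistic seizure morphology and
evolution, artifacts (EMG, eye blinks), inter-channel correlation of
background activity, and non-stationarity across a recording. A green
planted-recovery test therefore establishes that the search machinery
finds channels carrying class information — not that the feature set
suffices for clinical EEG. One consequence of the clean world: with
`snr = 3` a single informative channel already reaches accuracy 1.0, so
with two planted channels the non-dominated archive holds only a
single-channel entry (any two-channel entry is dominated); recovery is
then judged by the minimal subset being composed of informative channels.

## Known limitations

* Per-patient results on real CHB-MIT recordings require downloading the
  dataset; the EDF path is implemented and tested on synthetic EDF files
  only, and the native summary-file annotation format is not parsed
  (intervals come from a two-column CSV).
* The oracle-equivalence guarantee for the GA is demonstrated on
  structured, enumerable fitness landscapes (per-channel contributions
  plus pairwise synergies). On an i.i.d.-random landscape no search can
  beat enumeration, and full front coverage is not attainable within the
  generation budget.
* The grid-maximum fitness is optimistically biased by design (fidelity
  to the original wrapper); reported accuracies should be read as model
  selection scores, not unbiased generalization estimates.
* Two objectives only; many-objective extensions (adding e.g. sensitivity
  or hardware cost) would need different reference-point densities for
  NSGA-III.
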