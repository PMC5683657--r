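---
title: "Methods: dynamic population coding analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dynamic population coding analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(popcode)
```

This vignette documents the models, estimators and design choices behind
`popcode`. The package analyses trial-aligned spike trains of a tone-driven
neural population — windowed rates, selectivity, mutual information,
population decoding, Poisson diagnostics — and ships a synthetic population
generator so every analysis can be exercised, tested and reproduced without
recorded data.

## The scientific question

Auditory cortical neurons respond to a stationary tone in two regimes: a
high-rate, broadly tuned transient right after sound onset, adapting within
one or two hundred milliseconds to a low-rate, narrowly tuned sustained
response. A classical interpretation assigns the two regimes different
roles — detection at onset, identification during the sustained epoch,
because selectivity is higher there. The analyses in this package quantify
the alternative view: what a downstream decoder can recover depends chiefly
on the number of spikes the read-out window contains, wherever in the
response those spikes occur. The package therefore centres on two kinds of
read-out windows: fixed-length windows slid over time, and windows grown
from a fixed left edge until they hold a target number of pooled spikes.

## Windowing conventions

Windows are half-open intervals `[start, start + L)` in ms, with sound
onset at `t = 0`. The half-open convention is a package decision (boundary
handling is rarely stated in the experimental literature); it makes
adjacent windows partition time exactly, which the test suite asserts as a
conservation law. Constant-spike-count windows are grown rightward in 1-ms
increments — the finest step used anywhere in the pipeline — until the
pooled count (all neurons, all trials, all stimuli) reaches the target; an
explicit condition (`popcode_insufficient_spikes`, carrying the achieved
count) is raised when the record ends first. Times are stored in ms, rates
reported in spikes/s.

## The synthetic population generator

`population_config()` describes an experiment; its defaults emulate the
structure of the motivating study: 171 neurons, six 500-ms tones from 1 to
32 kHz spaced one octave apart at 85 dB SPL, 20 trials, recordings from
300 ms before onset to 700 ms after offset. Each neuron has

* a best frequency on a log-uniform grid over the stimulus range (with
  0.25-octave jitter), so every tone drives part of the population;
* a spontaneous rate drawn uniformly from 1–10 spikes/s;
* Gaussian log-frequency tuning whose width starts at 1.5 octaves and, in
  the default *differential adaptation* mode, narrows to 0.7 octaves with
  the same time constant as the rate adaptation — off-preferred responses
  decay back to spontaneous, so the population sparsifies as it adapts;
* an evoked drive that switches on at a 20-ms latency, jumps to
  150 spikes/s at the best frequency and decays exponentially
  (`tau` = 60 ms) to a 12 spikes/s sustained value, switching off one
  latency after sound offset.

Spike trains are sampled as an inhomogeneous Poisson process by per-ms
binning: each 1-ms bin contributes a Poisson count with the bin's expected
value and spikes are jittered uniformly within the bin. This makes expected
counts exact in any ms-aligned window and keeps the generator fast and
simple; thinning would be an equivalent alternative.

The defaults were calibrated once, before the downstream analyses were
frozen, so that the generated population reproduces the qualitative
structure the analyses presuppose: mean population rate maximal within
50 ms of onset and far lower late in the stimulus; more effective stimuli
per neuron at onset than during the sustained epoch; Poisson count
statistics throughout. The balance between the two epochs is genuinely
delicate: narrow sustained tuning raises the per-spike information of the
sustained code, and with too extreme a width contrast (for instance 2.0
narrowing to 0.5 octaves with a 20 spikes/s sustained rate) the sparse
sustained responses decode *better* than onset in equal 15-ms windows,
which contradicts the response structure being emulated. The chosen values
(150 → 12 spikes/s, 1.5 → 0.7 octaves, `tau` 60 ms) restore the intended
asymmetry while staying within physiologically reasonable ranges for A1.

What the generator deliberately omits: trial-to-trial noise correlations
between neurons (the motivating data were recorded sequentially, so the
analyses never see them), non-Poisson spiking (refractoriness, bursting),
latency heterogeneity across neurons, and frequency-dependent response
magnitudes. Passing tests therefore demonstrate that the *pipeline*
recovers the right answers from data with known structure — not that real
cortical data satisfy the Poisson or independence assumptions.

## Selectivity: effective stimuli

A neuron's selectivity at time `t` is summarised by the number of stimuli
whose spiking rate in a 50-ms window starting at `t` significantly exceeds
the spontaneous rate — the *effective stimuli* count, inversely related to
selectivity. Significance uses the exact one-sided Poisson conditional
test: conditioned on the total of the test and reference counts, the test
count is binomial with success probability given by the exposure ratio.
The spontaneous reference pools all pre-onset spikes of the neuron
(`[-300, 0)` ms across all trials and stimuli), maximising reference
precision. Bonferroni correction defaults to the *whole-recording* family
(tested windows × stimuli per neuron), with a per-window family available;
the choice is configurable because the appropriate family depends on how
the profiles are consumed. Windows are indexed by their start time;
"first 200 ms" means starts in `[0, 200)` and "last 300 ms of the sound"
means starts in `[200, 450]`, so windows lie inside the sound.

The broad-tuning subset (`select_broad_tuning_subset()`) keeps neurons
whose maximum effective count early exceeds that late and whose median
late count is at least 1 — the neurons that mimic narrow tuning probed
with finely spaced tones.

## Mutual information with bias correction

Mutual information between the stimulus set and a neuron's windowed spike
count is total entropy minus mean stimulus-conditional entropy, stimuli
equiprobable, probabilities by frequency of occurrence, in bits. Plug-in
entropies are biased downward at finite sample size, so every entropy is
corrected by subsample extrapolation: entropies of random subsamples at
10%–100% of the data (100 draws per size by default; subsampling without
replacement, stratified per stimulus, with draws shared between the
conditional and total entropies) are regressed on `1/M'` and `1/M'²`, and
the intercept is the corrected estimate. Correction is applied to each
entropy before combining. Corrected MI can come out slightly negative on
information-free data; such values are retained unmodified, and the
pre-onset baseline of the MI time course serves as the practical gauge of
residual bias. The Ma bound `−log2 Σ p_k²` is computed alongside every
estimate; if it exceeds the plug-in entropy the sample is too small and a
warning is raised.

Two numerical notes. First, the correction removes the *bias* almost
entirely (on Poisson(2) counts at M = 120 the mean error shrinks from
about −0.05 to below −0.01 bits) but inherits the plug-in's sampling
noise (sd ≈ 0.09 at that size), so on any single sample the corrected
estimate beats the plug-in only somewhat more often than not; averaged
over samples the improvement is roughly tenfold. Second, the regression
needs at least three distinct subsample sizes and raises an error
otherwise.

For time courses over many windows and neurons the package default of 100
subsample draws is unnecessarily precise; the analysis scripts and the
acceptance runs use 20–30 draws, which changes epoch means by far less
than the neuron-to-neuron spread. Problem sizes used by the shipped
analyses: all 171 neurons, 15-ms windows, onset span `[0, 100]` at 5-ms
steps and sustained span `[200, 500]` at 15-ms steps.

## Decoders

Three population decoders consume single-trial response vectors (one
dimension per neuron, spikes/s — or raw counts in the count simulations,
where the common window length makes the two equivalent):

* **LDA** — PCA on the training trials retaining the smallest number of
  components reaching 90% variance, then Fisher discriminant axes (at most
  `n_classes − 1`) in PCA space; classification by the nearest class mean
  in discriminant space. The within-class scatter is ridge-regularised by
  `1e-9 × trace/dim` when singular, which 15 training trials in a
  high-dimensional PCA space can produce. Test samples are always
  projected with the transforms fitted on training data.
* **TMPEUC / TMPCOS** — template matching: per-stimulus mean training
  response, classification by minimum Euclidean or angular
  (`1 − cosine`) distance.

Ties break deterministically toward the lowest stimulus index. A
spike-free test vector has no direction, so under the angular metric it is
assigned distance 1 to every template and resolves to the first class.
Cross-validation is 4-fold with contiguous per-stimulus trial blocks
(trials 1–5, 6–10, ...); a repeated random-split scheme (15 train / 5 test
per stimulus by default) quantifies split uncertainty. Label-shuffle and
independent-oracle tests guard against information leakage between folds.

## Window-length analysis

Accuracy-vs-length sweeps start a window at a fixed time (20 ms for the
onset epoch, 200 ms for the sustained epoch — early enough in each epoch
to leave room for long windows) and extend it rightward. Saturation
accuracy is the mean over lengths 150–200 ms; the minimum useful window is
the smallest tested length reaching 80% of saturation. Near the ceiling
the 4-fold band accuracies can be exactly constant, so the uncertainty of
a saturation *difference* is estimated from repeated random train/test
splits rather than from a degenerate bootstrap over identical band values.

Constant-spike-count time courses place left edges every 5 ms across the
stimulus (edges `[0, 450]` ms by default, keeping the grown windows inside
the sound) and decode each grown window. Because the first ~20 ms of
edges precede the response latency, their windows collect mostly
spontaneous spikes and decode poorly; this rising segment carries most of
the residual variation of the otherwise flat constant-count curve, and
with the 2,000-spike target the curve's SD lands right at the factor-2
threshold relative to fixed 15-ms windows that the package's acceptance
checks use (about 0.50 for LDA, 0.51–0.54 for the template decoders; well
below 0.5 for a 500-spike target or when pre-latency edges are excluded).

## Poisson statistics

Fano factors use the unbiased (n−1) variance over trials; cells with zero
mean count are flagged `NA` and excluded from summaries. The observed CV
(sd/mean of single-trial rates) is compared with the Poisson law
`CV = 1/√(r·T)` through a coefficient of determination computed against
the zero-parameter prediction, so `r²` may be negative when the prediction
fits worse than the mean. Goodness of fit tests the Poisson null against a
negative-binomial alternative by likelihood ratio; since the null sits on
the parameter boundary, the statistic is referred to the mixture
`0.5·χ²₀ + 0.5·χ²₁`, and constant or underdispersed counts give `p = 1`
(underdispersion is not the tested alternative). Diagnostics run over
15-ms nonoverlapping windows per neuron–stimulus pair, with epochs
labelled `[-300, 0)`, `[0, 200)`, `[200, 500]` ms.

The count discriminability between two rates,
`d′ = |r1 − r2|·T / √((r1 + r2)·T/2)`, uses the average of the two Poisson
variances; its exact invariance under `(r1, r2, T) → (k·r1, k·r2, T/k)` is
the algebraic heart of the constant-spike-count account and is
property-tested to machine precision.

## Uniform-adaptation simulations

`derive_base_rates()` fixes the window start at 30 ms and grows it to
2,000 pooled spikes, yielding per-(neuron, stimulus) mean rates. The
simulation draws 20 trials of Poisson counts with mean `k_r·r·k_T·T` per
cell and decodes them with all three decoders. Under the reciprocal rule
(`k_T = 1/k_r`, `k_r` from 0.1 to 1) the count distributions are identical
at every `k_r`, so accuracy differences across `k_r` reflect only
simulation noise — 20 replicate seeds furnish the standard errors to
verify flatness. Under the unity rule (`k_T = 1`, `k_r` up to 1.5)
expected counts scale with `k_r` and accuracy rises accordingly.

## Trajectories

The trajectory matrix averages rates over trials in 10-ms nonoverlapping
bins from 30 ms before onset to sound offset (53 bins) and concatenates
the six stimuli along columns — 171 × 318 for the default experiment. PCA
runs over the 318 column-samples in neuron space, centred per neuron and
unscaled (all entries share units); projections are smoothed per stimulus
with a 5-point centred moving average that shrinks at the sequence ends.
Smoothing is applied after projection (the alternative order is ambiguous
in common practice; after-projection smoothing keeps the PCA basis
unsmoothed). Pairwise trajectory separation in PC1–3 quantifies that
stimulus responses remain distinguishable in both epochs.

## Known limitations

* Sequentially pooled populations carry no noise correlations; all
  decoding results inherit that idealisation.
* The entropy correction targets count distributions over ~20 trials per
  stimulus; far smaller samples trip the Ma-bound warning.
* The Poisson GOF test's negative-binomial alternative has little power
  against underdispersion by construction.
* The generator's onset transient is a parametric stand-in (step onset,
  exponential adaptation); it reproduces the qualitative epoch structure,
  not any particular recorded population.
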