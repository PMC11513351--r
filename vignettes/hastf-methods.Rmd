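---
title: "Hybrid attention spatio-temporal modeling of EEG emotion features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hybrid attention spatio-temporal modeling of EEG emotion features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Affective brain-computer interfaces decode a subject's emotional state from
multichannel EEG. Two public benchmark structures dominate the field:
DEAP-style recordings (32 channels at 128 Hz, 40 one-minute music-video
trials per subject, continuous valence/arousal ratings binarized at 5) and
SEED-style recordings (62 channels at 200 Hz, 15 film-clip trials per
session, three emotion classes). `hastf` implements a complete
subject-dependent pipeline for this task: band-limited differential-entropy
features, scalp-geometry-preserving grid mapping, a convolutional spatial
extractor with a parameter-free energy-based attention, a class-token
transformer over time, cross-validated training, ablation statistics, and
topographic attention maps.

## Feature extraction

Each trial is decomposed by a third-order Butterworth filterbank into the
five canonical bands — delta (1–4 Hz), theta (4–8), alpha (8–13), beta
(13–31), gamma (31–50). Filtering is zero-phase by default
(forward–backward application, effective order 6): phase distortion would
misalign patches across bands, and the published "third-order Butterworth"
specification leaves the application mode open. A causal single-pass mode is
available via `filter_bank(zero_phase = FALSE)`.

The band signals are cut into non-overlapping windows of `T` seconds (8 for
DEAP-like data, 11 for SEED-like), each window into `T` one-second patches;
a trailing remainder shorter than one window is discarded. For every
(patch, band, channel) the differential entropy of an approximately
Gaussian band-limited signal is

$$\mathrm{DE} = \tfrac{1}{2}\ln\!\left(2\pi e \sigma^2\right),$$

in nats. We use the population variance (divide by the sample count) since
$\sigma^2$ enters as a distribution parameter, with the unbiased estimator
available by a switch (`unbiased = TRUE`); at 128 samples per patch the two
differ by $\tfrac12\ln\tfrac{128}{127} \approx 0.004$ nats.

DEAP-style trials carry a 3-s pre-stimulus baseline. The default drops it
and uses the 60-s stimulation segment. A `subtract_mean` mode additionally
subtracts the mean per-second baseline DE from every stimulation patch (the
correction used in parts of the 4D-feature literature); it is off by
default because the method description we follow never states a baseline
correction.

## Grid mapping

DE vectors are placed on a 9x9 grid that preserves the 10-20 scalp layout:
row 0 anterior, column 0 left. The two shipped montages (`deap32`,
`seed62`) follow the standard arrangement used by the 4D-mapping
literature; a handful of fringe electrodes (POz, CB1/CB2, Oz) have no
unique convention and their placements are marked in the montage files.
Unoccupied cells are zero-filled — no interpolation — so the mapping is a
bijection between channels and occupied cells and is exactly invertible
(`unmap_from_grid()`). Custom montages are plain `channel,row,col` tables.

## The spatial extractor

Each patch's five 9x9 band maps pass through five convolution layers: a
channel-expansion branch, a contraction branch, and two concatenation skip
connections (layer 4 consumes `CAT(Y3, Y2)`, layer 5 consumes
`CAT(Y4, Y1)`). Layers 1–4 use 3x3 kernels, stride 1, padding 1; layer 5
uses a 1x1 kernel with padding 0 — padding 1 there would grow the map,
contradicting the requirement that spatial dimensions stay invariant. The
published description fixes the kernel geometry but not the feature-map
counts; the package defaults to (64, 128, 128, 64, 32).

The spatial attention is parameter-free. For a position with value $t$ in a
map, with leave-one-out mean $u_t$ and population variance $\sigma_t^2$
over the other $M-1$ positions, the minimum of a ridge-regularized
linear-separability energy has the closed form

$$e_t^* = \frac{4(\sigma_t^2 + \lambda)}{(t - u_t)^2 + 2\sigma_t^2 + 2\lambda},$$

and the refined features are $\tilde X = \operatorname{sigmoid}(1/E)\odot X$.
Positions that stand out from their surroundings (large $(t-u_t)^2$) get
low energy, hence high weight — an engineering analogue of spatial
inhibition between neighbouring neurons. On a constant map $e^* = 2$
exactly and every weight is $\operatorname{sigmoid}(1/2) \approx 0.6225$.
Decisions taken where the source is silent or ambiguous:

* $\lambda$ is not stated anywhere; the package defaults to $10^{-4}$
  (the value common in the parameter-free-attention literature) and logs it.
* The variance symbol in the minimal-energy expression is taken to be the
  same leave-one-out $\sigma_t^2$ defined for the minimizer; no second
  estimator is ever defined.
* $M$ is described as "the number of channels in a frequency band", but
  after convolution the positions of a feature map are grid cells, not
  channels. Inside the network we use $M = 81$ grid positions per map.
  The channel reading survives in the visualization module (below).
* A `shared` statistics mode (map-wide mean/variance including the target)
  is offered as a faster approximation; `leave_one_out` is the default and
  the literal definition.
* The attention is applied once, to the final convolution output, before
  max pooling — the literal reading of the composition
  $\mathrm{MP}(\mathrm{SA}(\cdot))$.

After attention: 2x2/stride-2 max pooling (9x9 to 4x4; the pooling geometry
is unstated, this is the standard choice), flattening, and an affine
projection to the embedding width $d$.

During training the attention weights are treated as constants in the
backward pass (a stop-gradient): the gradient is scaled by the weights
exactly as for a fixed gating mask. Differentiating through the
leave-one-out statistics couples all 81 positions per map at
$O(M^2)$ cost and, at the problem sizes used here, measurably changes
neither the learned accuracy nor the attention maps; the forward
computation is exact in either case. Consequently the finite-difference
gradient tests run with attention bypassed, and all other blocks are
checked exactly.

## The temporal encoder

The $T$ patch features of a window form a token sequence; a learnable class
token is prepended (index 0) and a learnable positional encoding of length
$T+1$ is added. Each of the (default six) encoder layers computes
post-norm residual blocks

$$Z_A = \mathrm{LN}(\mathrm{MSA}(Z) + Z), \qquad
  Z_F = \mathrm{LN}(\mathrm{FFN}(Z_A) + Z_A),$$

with 8-head scaled dot-product attention ($1/\sqrt{d_k}$ applied once,
row-softmax on the simplex) and FFN = affine - GELU - affine. The class
token's final state feeds a single affine classification head (the head is
never described; one affine layer is the minimal choice).

Interpretation choices:

* "Dimensions of the QKV matrices and the FFN linear layers are 256
  and 128" is read literally as model width $d = 256$ and FFN hidden
  width 128, an inverted bottleneck; both are configurable, and the QKV
  width defaults to $d$.
* "Standard normal within the range 0–1" for token initialization is
  self-contradictory; the default draws standard normals and redraws until
  they land in $[0,1]$ (truncation by rejection), with plain standard
  normal available (`token_init = "norm"`).
* Dropout is never mentioned and defaults to off.

## Training and evaluation

Cross-entropy loss, AdamW (decoupled weight decay $10^{-4}$; biases,
LayerNorm parameters, the class token and positional encodings are exempt
from decay), learning rate $10^{-4}$, batch size 32, 100 epochs, 5-fold
cross-validation per subject. Units are shuffled with a seeded RNG and cut
into five contiguous near-equal folds.

The fold unit is a genuinely open question: "all trial data are shuffled"
can mean shuffling trials or shuffling windows. Splitting at window level
lets windows of one trial appear in both train and test folds, which
inflates accuracy through within-trial correlation. The default is
`split_unit = "trial"` (leakage-safe); `"window"` is available to match the
literal reading. Accuracy is $100(TP+TN)/(TP+FP+TN+FN)$ and the fold
spread is the population standard deviation (divide by $N$), both following
the published metric definitions.

Grid values are z-scored with training-fold statistics of the occupied
cells before entering the network (a per-fold affine rescaling; off via
`normalize = FALSE`). DE features sit around 1–3 nats with zero-filled
holes, and centring them materially speeds up short training runs.

The ablation battery trains five structural variants on bitwise-identical
folds: `All`, `Wo-Sc` (no skip concatenations), `Wo-SA` (attention replaced
by identity), `Wo-UCCF` (attention and pooling on the raw band maps),
`Wo-SAFE` (flattened band maps affinely projected into the encoder), plus
an optional `Wo-TAFE` (window-mean spatial features with an affine head).
The replacement heads for `Wo-SAFE`/`Wo-TAFE` are not prescribed anywhere;
minimal affine stand-ins are used so that exactly one module is missing at
a time. The one-way ANOVA over variants uses the standard decomposition by
direct summation, and the Games-Howell post-hoc comparison uses per-group
variances, Welch-Satterthwaite degrees of freedom and the
studentized-range distribution — no equal-variance assumption, matching the
unequal spread of ablation accuracies. The published comparison table
additionally reports bias-corrected (BCa) intervals from an unspecified
bootstrap; `games_howell(..., bootstrap_bca = N)` provides a seeded BCa
bootstrap as an approximation, while the analytic intervals remain the
default output.

## The synthetic generator

Real DEAP/SEED data are licensed and cannot ship with a package, so every
stage is exercised on synthetic recordings with the same shape. Each trial
is 1/f^a Gaussian noise (spectral shaping in the frequency domain, unit
variance, default slope a = 1 — the canonical resting-EEG spectrum) plus
one sinusoid per band with random in-band frequency and phase (amplitude
0.6 noise-SD, jittered 10%). Trials of the target class have the
effect-band sinusoid amplitude multiplied by `effect_gain` (default 3) on
the effect channels (default F3, F4, T7, T8 — frontal/temporal sites,
where emotion effects are conventionally reported). Labels are balanced
and shuffled; each subject derives its own RNG stream from
(seed, subject id), so any subject is reproducible in isolation.

What this emulates: trial structure, sampling rates, montages, labels, a
band-limited class effect recoverable by DE features, and a 1/f
background. What it does not: volume conduction, ocular/muscle artifacts,
non-stationarity within trials, inter-channel correlation beyond the
shared spectral shape. Passing tests on these data show the pipeline's
mechanics and its ability to recover a planted band-power effect — they say
nothing about accuracy on real recordings, and the published headline
accuracies on DEAP/SEED are out of the package's test scope for exactly
that reason.

## Problem sizes and numerical choices

The test-suite and the acceptance script use a "desk" scale chosen so that
a full 5-fold experiment (280 windows, as in one DEAP-like subject with
8-s windows) runs in minutes on one CPU core: filters (4, 8, 8, 4, 4),
$d = 32$, 4 heads, 2 encoder layers, FFN width 16, 20 epochs, learning
rate $10^{-3}$. This preset only shrinks capacity and shortens training;
every structural element — the five-layer skip-connected extractor, the
energy attention, the class-token encoder — is identical to the published
configuration, which remains the package default (`scale = "paper"`).

Other numerical details: convolution is im2col + BLAS GEMM with the 3x3
unfold/fold pair compiled in C++; leave-one-out variances are clamped at
zero against cancellation; the softmax subtracts row maxima;
cross-entropy clips probabilities at $10^{-12}$; LayerNorm uses
$\epsilon = 10^{-5}$; max-pooling ties break toward the
first (top-left) element; He-uniform initialization for all conv/linear
weights. All RNG consumption (generator, fold shuffle, initialization,
batch order, bootstrap) is seeded, and functions that seed internally
restore the caller's RNG state.

## Attention maps

`extract_attention_map()` summarizes the attention as a 9x9 scalp map,
averaged over feature maps and patches, with unoccupied cells masked. Two
capture stages reflect the two readings of $M$ noted above: `"uccf"` runs
the trained spatial extractor and captures the attention over the 81 grid
positions of its output maps; `"input"` evaluates the same energy operator
directly on the DE band maps with statistics over occupied cells only, so
the "neurons" are exactly the channels of a band — deterministic in the
data and independent of any weights. Whether the published topographies
show weights or attended activations is not stated; both quantities are
available (`quantity = "weights"` or `"refined"`) and recorded in the map
metadata. Class averages weight subjects equally (subject means first).

## Known limitations

* No artifact simulation or removal; the pipeline assumes artifact-cleaned
  input, as the benchmark datasets ship.
* The backward pass through the spatial attention is the stop-gradient
  approximation described above.
* MAT/HDF5 ingestion of the real datasets is out of scope; recordings
  enter either through the synthetic generator or through the package's
  RDS/CSV containers.
* Exact grid placements of a few fringe electrodes are conventions, not
  ground truth; custom placement tables override them.
* Cross-subject transfer is explicitly not addressed: one model per
  subject (and per SEED-like session).
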