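---
title: "Gamma-kernel convolutional decoding: model, training protocol, and benchmarks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gamma-kernel convolutional decoding: model, training protocol, and benchmarks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gammanet)
```

## The decoding problem

Multi-unit activity recorded from a planar electrode array in the spinal cord
carries descending motor commands; the goal is to reconstruct, time bin by
time bin, the smoothed envelope of an EMG channel recorded simultaneously from
a forelimb muscle. Two properties of such data shape the design:

* the temporal dimension is long (hundreds of bins per trial) while the
  spatial dimension is small (tens of channels) with no spatial hierarchy, so
  the network is convolutional only in time and densely connected across
  channels; and
* muscle activity *outlasts* the neural command that produced it, so the map
  from neural envelopes to EMG needs memory — a pointwise (memoryless) linear
  readout cannot represent it.

All signals are envelopes: the RMS power of the raw signal, computed as
`sqrt` of the squared signal smoothed with a Gaussian kernel (sigma = 10 ms;
in the frequency domain another Gaussian whose half-power point
`sigma_f * sqrt(2 log 2)` is about 37.5 Hz for `sigma_f = 100/pi` Hz). Neural
channels are first high-passed at 20 Hz (zero phase, 3rd-order Butterworth)
to remove movement artifacts; EMG envelopes are additionally low-passed at
1–5 Hz to serve as regression targets; everything is downsampled to 100 Hz,
giving 400 bins for a 4-s trial.

## The model

The decoder stacks two kinds of layers.

**Session-dependent feature layers** (default widths 27 → 21 → 15 → 9) are
pointwise affine maps followed by a leaky ReLU, applied independently at every
time bin. Electrode micro-drift makes channel identities session-specific, so
each recording day gets its own feature stack; the stacks project every
session into the same 9 shared features, under the assumption that the true
motor command is low-dimensional. Because they have length 1 in time they are
implemented as matrix products — mathematically identical to width-1
convolutions.

**Shared temporal regression layers** (default widths 9 → 6 → 3 → 1) are
causal convolutions whose kernels are closed-form Gamma functions. Each
input–output channel pair has one kernel

\[ F(t) = \alpha\,\beta^2\, t_f\, e^{-\beta t_f}, \qquad
   t_f = \tfrac{1}{\theta\beta}\,\ln\!\left(e^{\theta\beta (t - t_0)} + 1\right), \]

with three trainable parameters: the area under the curve \(\alpha\) (any
sign), the inverse time constant \(\beta > 0\), and the onset delay
\(t_0 > 0\). The warped time \(t_f\) is a SoftPlus of \(t - t_0\): strictly
positive, so no epsilon guard is ever needed, and differentiable in \(t_0\)
and \(\beta\) everywhere, which is what makes the onset delay trainable. The
corner-sharpness constant \(\theta\) is fixed at 10. The \(\beta^2\) factor
normalizes the kernel so its area stays \(\alpha\) when \(\beta\) changes:
the optimizer can stretch or compress the kernel in time without altering the
output variance, and only \(\alpha\) needs variance-preserving (Xavier)
initialization. \(\beta\) and \(t_0\) are stored as `log_beta` and `log_t0`
so they remain positive under unconstrained gradient steps.

Convolutions are front-padded with zeros: the output at bin *t* depends only
on inputs at bins ≤ *t* (strict causality, verified by perturbation tests). A
leaky ReLU (slope 0.01) follows every layer except the final one, whose raw
output is the prediction; small negative excursions are penalized by the loss
rather than clipped, since the EMG target's own low-pass filtering can
undershoot.

The *naive* configuration replaces the Gamma kernels with unconstrained
10-bin (100 ms) kernels — the same convolution operator with every tap free.
It serves as the reference for what the closed form buys: a 30-bin Gamma
kernel costs 3 parameters instead of 30, and the count is independent of the
sampling rate.

## Training and model selection

Each EMG channel is decoded independently. The loss is the plain sum of
squared errors between prediction and low-pass-filtered EMG over all training
trials, **excluding the first second of every trial** — the burn-in window
exceeds the network's total kernel span, so solutions cannot exploit the
filters' startup transient. The same exclusion applies to all reported
metrics. No L1/L2 regularization is used; early stopping via validation
checkpoints takes its place. Optimization is full-batch ADAM (learning rate
0.1, B1 = 0.9, B2 = 0.999, eps = 1e-8) for 1000 steps by default; sessions
are small enough that minibatching buys nothing.

Trials are split deterministically: sequential groups of five, first three to
Training, fourth to Set A, fifth to Set B (60/20/20 for multiples of five; a
trailing partial group follows the truncated pattern). There is no
randomization, so every restart sees the identical split.

Training a deep stack from a random initialization either converges or it
does not, so the whole procedure is restarted (16 times by default) from
independent initializations — the only thing that differs between attempts.
Within an attempt, every step is a candidate model; the checkpoints with the
highest pooled R² on A and on B are retained (`A_max`, `B_max`). Across
attempts, the `A_max` checkpoint with the highest *Training + Set A* R² sum
is selected — without ever reading Set-B scores — and evaluated once on B;
symmetrically for `B_max` on A. The session's overall score is the mean of
the two held-out values. Exact ties resolve to the lowest attempt index.
Because only one model is tested per fold, the 16 attempts are not samples
from a distribution, and mean-over-attempts performance is close to zero by
construction; the selection-based score is the meaningful quantity.

R² is pooled: one `1 - SS_res/SS_tot` over all included (trial, bin) points
of a set, not a per-trial average; the Pearson correlation is computed over
the same pooled points. Pooling matches reporting an overall score per
session and is the convention used everywhere in the package.

Two controls run under the *identical* protocol:

* **Pointwise linear decoder** — one affine layer, no rectification, no
  temporal memory. Its neural inputs are first low-pass filtered to the EMG
  target's bandwidth (they would otherwise be far noisier than the target).
  The CNN-minus-linear gap isolates what memory and nonlinearity contribute.
* **Time-permutation null** — one random permutation of all pooled
  (trial, bin) positions applied to whole cross-channel time slices of the
  neural tensor, as the last preprocessing step. Channels move together, so
  every instantaneous spatial statistic is preserved exactly; only temporal
  structure is destroyed. Scores on shuffled inputs bound what alignment and
  slow transients alone can achieve.

## Synthetic sessions and what they do (and do not) show

No public recordings exist for this preparation, so the package ships a
generator that emulates the statistical structure the decoder assumes:

* **latent commands** (default 3): nonnegative smooth burst trains, bursts
  jittered around the trial midpoint (reach-to-pull alignment), 20%
  trial-to-trial amplitude jitter;
* **neural envelopes** (default 27): a rectified nonnegative session-specific
  mixing of the latents — the mixing matrix drifts between sessions while the
  latent dynamics stay shared, mirroring the session-dependent/shared layer
  split — plus half-normal noise (nonnegative, preserving the envelope
  convention);
* **EMG envelopes** (default 4): rectified sums of Gamma-filtered latents
  plus half-normal noise. The planted kernels default to onset delays of 20
  and 40 ms and time constants of 30 and 60 ms; the generator's kernel span
  is 600 ms so that the slowest planted path satisfies
  `t0 + 8/beta <= span` (the decoder's own regression kernels stay at
  300 ms).

The generator returns the planted truth (latents, mixing matrices, kernel
table), sufficient to reconstruct the noise-free EMG exactly; `truth_decoder()`
builds the analytically inverse decoder, and on noise-free data its
predictions equal the targets to floating-point error — the realizability
anchor for every downstream benchmark.

**Parameter recovery** uses the only identifiable configuration: one latent,
one EMG path, a `d -> 1` feature stack and a single `1 -> 1` Gamma regression
layer. After training, the network's end-to-end impulse response is measured
by probing — a lone pulse shaped like the session's mixing column on an
otherwise silent input, baseline-subtracted — and the closed form is fit to
the probed response by multi-start least squares. Recovery is judged on the
probe, not by reading parameters, because the layers of a deeper composition
are only identified up to their composite response. On the noise-free
benchmark the recovered onset delay lands within a fraction of a millisecond
of the planted 20 ms and the time constant within ~1% of the planted 30 ms;
at ~10 dB EMG SNR the held-out R² stays above 0.9 (the noise ceiling at that
SNR is ~0.91).

What passing these benchmarks does **not** show: the generator has no
biomechanics, no stretch reflexes, no electrode crosstalk, no nonstationarity
within a session, and its noise is well-behaved half-normal. Real recordings
degrade decoding for reasons the synthetic data cannot reproduce, and
performance numbers on synthetic sessions say nothing quantitative about real
preparations — only that the estimator recovers what was planted under its
own assumptions.

## Numerical choices

* **Riemann scaling.** The regression layers convolve with `dt * F(k * dt)`
  — the Riemann approximation of the continuous convolution integral — so a
  layer's gain to a smooth input equals the kernel area \(\alpha\). This is
  the property the \(\beta^2\) normalization exists for; without the `dt`
  factor every layer would amplify by `1/dt` (100x at 10 ms bins), initialized
  stacks would start six orders of magnitude off target, and most training
  attempts would diverge. The exported primitive `gamma_layer_forward()`
  remains the unscaled pure operation; the scaling lives in the network (and
  the synthetic generator uses the same convention, keeping planted problems
  exactly realizable).
* **Discretization.** Kernels are sampled at bin centers `t = k * dt`,
  `k = 0 .. n_taps - 1`, matching the front-padded convolution's indexing. The
  discrete area `sum(taps) * dt` tracks the continuous area alpha to within
  2% provided the kernel support fits in the window (`t0 + 8/beta <= span`)
  *and* the time constant is resolved by the grid (`1/beta` at least ~2
  bins). Sharper kernels are under-sampled at 10 ms bins: the Riemann sum can
  err by several percent, with the worst case at half-bin onset phases. A
  small inherent area inflation (~1.3% at theta = 10) from the SoftPlus warp
  near onset persists even at fine sampling. Property tests therefore draw
  time constants from 18–35 ms; halving `dt` while doubling `n_taps` changes
  the area by under 1% (rate invariance).
* **Overflow guards.** The SoftPlus switches to its asymptote `t - t0` when
  `theta * beta * (t - t0) > 30`; far below onset, where `log1p(exp(z))`
  underflows, the warped time is floored at the smallest positive double so
  strict positivity survives IEEE arithmetic.
* **Zero-phase filtering.** Forward–backward application of
  `signal::butter` coefficients with odd-reflection padding. The pad must
  outlast the filter transient, which scales with the cutoff *period*, not
  the filter order: a 3rd-order 20 Hz high-pass at 16 kHz rings for ~0.3 s
  (thousands of samples). The pad is therefore
  `max(3 * (order + 1), 8 * fs / cutoff)` samples, capped at the signal
  length minus one.
* **Envelope edges.** The Gaussian kernel is truncated at ±4 sigma and
  renormalized to unit sum (<1e-4 mass lost, deterministic length); the
  squared signal is mirror-extended, folding as often as needed when the
  kernel is wider than the signal.
* **Downsampling** is plain stride selection: the envelope kernel (and the
  EMG low-pass) already band-limit the signal, and no additional anti-alias
  stage is specified by the preprocessing chain.
* **Initialization.** Feature weights and kernel areas are Xavier-uniform;
  onset delays and time-to-peak are drawn uniformly from 5–30 ms ("on the
  order of 10 ms" — the exact distribution is a package choice). Biases start
  at zero. Attempt *k* of a fit uses seed `seed + k - 1`, so a single seed
  reproduces the full restart set.
* **Ties and degenerate inputs.** Selection ties go to the lowest attempt
  index; a zero-variance target makes R² undefined and raises an error rather
  than returning a sentinel; non-finite losses abort an attempt, which is
  kept in the records flagged non-convergent (its checkpoints are whatever
  was recorded before divergence).

## Design choices where the design was open

* **Leaky-ReLU slope 0.01** — the reference architecture names leaky
  rectification without a slope; 0.01 is the common default. Setting the
  slope to 1 turns the activation into the identity, which is how the linear
  control reuses the same machinery (`linear_spec()`).
* **Feature-layer biases** are included (initialized to zero); Gamma layers
  have no additive bias — the closed form defines the connection completely.
* **Shuffle granularity** — the permutation moves whole cross-channel time
  slices rather than shuffling channels independently; this preserves
  instantaneous spatial statistics so the null isolates temporal structure
  specifically.
* **Linear control bias** — the pointwise control includes an intercept; a
  decoder asked to produce a nonnegative envelope from zero-mean-ish inputs
  needs one.
* **Artifact rejection** is an explicit per-trial exclusion list on
  `assemble_session()`, not an automated detector.
* **Interchange format** — sessions persist in a plain-text directory
  container (`meta.json` plus one full-precision CSV per tensor, 17
  significant digits, which round-trips IEEE doubles exactly). The layout
  mirrors a hierarchical store: one group per session with `neural` and
  `emg` members.

## Problem sizes used by the shipped benchmarks

The test suite and the acceptance script scale the study down so the full
battery runs on one CPU in minutes; these sizes are the package's benchmark
definition:

* recovery benchmarks: 1 session, 20 trials of 400 bins, 27 neural channels,
  single latent/path; 300 ADAM steps, 2–3 restarts;
* CNN-vs-linear separation: 1 session, 20 trials, 3 latents planted with a
  100 ms onset delay and 25 ms time constant, full-width network
  (27 → 21 → 15 → 9 → 6 → 3 → 1); 300 steps, 3–4 restarts — with the
  Riemann-scaled layers (above) training converges from essentially every
  initialization on these realizable problems, so small restart counts
  already give seed-robust scores;
* property suites: 1000 kernel draws, 100 causality instances, finite
  differences over every parameter of a small two-session decoder.

## Known limitations

* Training can still fail from unlucky initializations on hard or noisy
  problems (the restart protocol absorbs this by design); on the shipped
  realizable benchmarks convergence is near-universal.
* The Gamma parameterization assumes unimodal causal responses per channel
  pair; genuinely multimodal dynamics need stacked layers to compose them.
* Kernel time constants below ~2 bins are under-resolved at the analysis
  rate; train at a higher rate if such dynamics matter (the closed form keeps
  the parameter count unchanged).
* R² on burst-like envelopes concentrates error at burst timing mistakes; a
  timing-tolerant metric would be more forgiving, and correlation is reported
  alongside R² for that reason.
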