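# gammanet

Causal temporal convolutional decoding of EMG envelopes from multi-channel
neural envelopes, with closed-form **Gamma-function convolution kernels**.

## The problem

Multi-unit activity recorded from a small planar electrode array in the
corticospinal tract carries descending motor commands. The goal is to
reconstruct, bin by bin, the smoothed envelope of a simultaneously recorded
muscle's EMG. Muscle activity *outlasts* the neural command that drives it,
so the decoder needs temporal memory — exactly what a pointwise (Wiener-style)
linear readout lacks — yet sessions contain only tens of trials, far too few
to fit unconstrained convolution kernels without overfitting.

`gammanet` addresses this with a six-layer causal network: three
session-dependent pointwise feature layers (widths 27 → 21 → 15 → 9, leaky
ReLU) that compensate for day-to-day electrode drift by projecting every
session into nine shared features, followed by three shared regression layers
(9 → 6 → 3 → 1) whose kernels are the closed form

```
F(t) = α β² t_f exp(−β t_f),   t_f = ln(exp(θβ(t − t₀)) + 1) / (θβ)
```

— three trainable parameters per channel pair (area `α`, inverse time
constant `β`, onset delay `t₀`; `θ = 10` fixed) instead of one parameter per
tap. The SoftPlus-warped time `t_f` is strictly positive and differentiable
in `t₀` and `β` everywhere, so the onset delay itself is trained by gradient
descent; the `β²` factor keeps the kernel's area equal to `α` as the
optimizer stretches it in time. Training is full-batch ADAM (learning rate
0.1, 1000 steps by default) on a sum-of-squares loss that excludes the first
second of every trial, repeated from 16 random initializations; a
deterministic two-fold protocol (sequential groups of five trials:
3 training / 1 Set A / 1 Set B) selects early-stopped checkpoints `A_max` /
`B_max` and reports the mean of the two held-out scores. Pointwise-linear and
time-permutation controls run under the identical protocol.

No public recordings exist for this preparation, so the package ships a
synthetic session generator with planted ground truth (latent burst commands,
session-specific mixing, Gamma-filtered EMG) used by all benchmarks; see the
methods vignette (`vignettes/gammanet-methods.Rmd`) for the model, the
numerical choices, and what the synthetic benchmarks do and do not show.

## Worked example

Recover planted kernel dynamics end to end, then compare the full decoder
against the pointwise linear control on a session whose EMG lags its neural
drive by a planted 100 ms Gamma kernel:

```r
library(gammanet)

## single-path parameter recovery (noise-free)
rep <- recovery_benchmark(config = training_config(steps = 300, restarts = 2,
                                                   seed = 1), seed = 1)
print(rep)
#> planted:   t0 = 20.0 ms, tau = 30.0 ms
#> recovered: t0 = 20.0 ms (err 0.0 ms), tau = 30.0 ms (rel err 0.1%)
#> held-out:  overall R2 = 1.0000, r = 1.0000

## planted 100 ms lag: Gamma CNN vs pointwise linear control
pg  <- data.frame(latent = 1:3, emg = 1L, alpha = 1, beta = 1/0.025, t0 = 0.1)
syn <- synth_generate(synth_config(trials_per_session = 20, n_emg = 1,
                                   n_latents = 3, planted_gamma = pg, seed = 2))
tc  <- training_config(steps = 300, restarts = 3, seed = 1)
fit <- gammanet(syn$sessions$s1$neural, syn$sessions$s1$emg, config = tc)
print(fit)
#> Gamma-kernel EMG decoder
#>   sessions: 1; EMG channel: 1; restarts: 3; steps: 300
#>   features 27 -> 21 -> 15 -> 9 | regression 9 -> 6 -> 3 -> 1 (gamma)
#> A_max(B): R2 = 0.9985 (r = 0.9993)   [attempt 1, step 286]
#> B_max(A): R2 = 0.9989 (r = 0.9994)   [attempt 1, step 285]
#> overall:  R2 = 0.9987, r = 0.9994

lin <- linear_control(syn$sessions$s1$neural, syn$sessions$s1$emg, config = tc)
lin$score$overall_r2
#> [1] 0.4604
```

The first block plants a single latent → EMG path (`t₀` = 20 ms, `1/β` =
30 ms), trains the restart protocol, probes the trained network's end-to-end
impulse response, and refits the closed form to it: the onset delay comes
back within a fraction of a millisecond and the time constant within ~0.1%.
The second block shows the headline contrast: with a 100 ms planted lag the
memoryless linear control stalls near R² ≈ 0.46 while the Gamma CNN, trained
and selected under the identical protocol, reaches R² ≈ 0.999 on held-out
trials. `coef(fit)` returns the trained kernel table (`alpha`, `beta`, `t0`
per channel pair); `predict`, `residuals` and `plot` work as for any fitted
model object.

A command-line interface over the same functions lives in
`inst/cli/gammanet-cli.R` (subcommands `simulate`, `preprocess`, `evaluate`,
`pipeline`).

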