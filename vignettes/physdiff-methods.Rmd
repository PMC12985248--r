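---
title: "Physics-aware PPG-to-ECG diffusion: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Physics-aware PPG-to-ECG diffusion: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(physdiff)
```

## The problem

Wearable devices measure photoplethysmography (PPG): the optical trace of
peripheral blood-volume change. Clinical diagnosis needs the
electrocardiogram (ECG). The two are linked by cardiac electromechanical
coupling — each electrical R-peak triggers a contraction whose pressure
wave reaches the periphery one pulse transit time (PTT) later — so a PPG
window carries latent information about the ECG that produced it. The
inverse map is ill-posed: the vascular tree low-pass filters the sharp
electrical transients, and many ECGs are compatible with one PPG.

`physdiff` treats the reconstruction as conditional generative modelling:
it learns `p(x0 | c)` for an ECG window `x0` given its paired PPG window
`c`, with a denoising diffusion model whose conditioning pathway is a
differentiable lattice-Boltzmann (LBM) encoder of the PPG, and whose
training objective penalizes violations of a hemodynamic consistency
constraint on the estimated clean signal.

## Model components

### Lattice-Boltzmann physics encoder

The PPG window (length `L`) is treated as a 1-D spatial domain carrying a
pressure-like field. A learnable lifting layer distributes it into `Q = 3`
non-negative mesoscopic channels (D1Q3 velocities `e = (-1, 0, +1)`),

    F_i(x) = softplus(W_i c(x) + b_i),

after which `K` iterations of *collide-and-stream* evolve the state:

* **Collision** — a learned channel-mixing (1x1) linear map produces a raw
  residual `C~`. A moment projection subtracts, per site, the mass excess
  `sum_i C~_i` (spread uniformly over channels) and the momentum excess
  `sum_i e_i C~_i` (spread along `e` with coefficient `e_i / sum_j e_j^2`),
  so the applied residual conserves both moments *exactly*, for any learned
  weights. The package also exposes `projection = "three_over_q"`, an
  alternative momentum coefficient `3 e_i / Q`; for D1Q3 that variant
  leaves a first-moment residual and exists only for comparison — the
  default projection provably zeroes both moments for any zero-sum
  velocity set.
* **Streaming** — channel `k` is shifted circularly by `e_k * s` samples.
  Periodic boundaries keep streaming an exact permutation, so global mass
  is conserved to machine precision; wrap-around leakage over `K * s = 4`
  samples of a 512-sample window is negligible and affects only the window
  edges.

The readout takes the kinetic moments density `rho = sum_i F_i` and
momentum `rho u = sum_i e_i F_i`; their concatenation `h_phys = [rho,
rho_u]` (L x 2) is the conditioning embedding. `K` is not prescribed by
the underlying formulation; the default is `K = 4`, configurable via
`lbm_config()`. An equilibrium distribution is never materialized: the
learned collision absorbs the relaxation dynamics.

### Dual-branch denoising U-Net

The backbone takes the noisy ECG `x_t`, a sinusoidal timestep embedding
passed through a small learned MLP, and `h_phys`. It is a 1-D U-Net of
pre-norm residual blocks (group norm, SiLU, 3-tap convolutions, a learned
per-block timestep projection, and a near-zero second convolution so each
block starts close to identity), with stride-2 average pooling,
nearest-neighbour upsampling and skip connections. Defaults: depth 5, two
blocks per level, channel widths doubling once below the top level
(16/32/32/32/32 at base width 16). Depth matters more than width here for
two reasons: the receptive field must comfortably cover the PTT lag
(0.2-0.3 s is 26-38 samples at 128 Hz), and a coarse bottleneck
(L' = 32) is what lets the model commit to a globally coherent beat train
for the whole window. These sizes were chosen from the descent of the
training objective and the morphology of samples during development, under
the constraint of single-CPU training in minutes.

Design points that were genuinely open and how they were resolved:

* **Where `h_phys` enters.** Cross-attention at the bottleneck is the
  stated mechanism (queries from the ECG latents, keys/values from the
  pooled hemodynamic features; rows of the attention matrix are softmax
  distributions). Its described purpose is temporal re-alignment between
  the hemodynamic and electrical domains — compensating PTT — but a purely
  content-based `Q K^T` score cannot express a time shift (keys carry no
  positional information). The backbone therefore adds a learnable
  relative-position bias to the attention logits (`logit[i, j] +=
  rel[j - i]`), the standard device for shift-structured attention; rows
  remain softmax-normalized, and a zero value projection still leaves the
  features untouched. In addition, `h_phys` is channel-concatenated to
  the input by default (`concat_condition = TRUE`), which covers the
  alternative reading of the architecture and speeds up conditioning at
  desk scale; a flag disables it. The exported `cross_attention()` is the
  plain content-only form.
* **Geometry-head parameterization.** With `head_param = "x0"` (the
  default) the convolutional head emits the clean-signal estimate and the
  noise residual is recovered algebraically through the forward marginal,
  `eps_hat = (x_t - sqrt(ab_t) x0_hat) / sqrt(1 - ab_t)`; a learned
  timestep-gated long skip from `x_t` feeds the head. The two
  parameterizations are algebraically equivalent as function classes, but
  their training dynamics at a 500-step budget are not: the x0 target is
  the same at every timestep, so the condition-to-waveform decode receives
  full-strength gradient from every sample, whereas the eps target carries
  the condition at amplitude `sqrt(ab/(1-ab))` — negligible exactly where
  conditioning matters. At desk scale the eps-parameterized head
  (`head_param = "eps"`, the direct convolutional noise head) learns the
  unconditional prior but not the conditional alignment. The denoising
  loss under `"x0"` is the inverse-SNR-weighted form of the
  noise-prediction loss: `||x0 - x0_hat||^2 = (1-ab)/ab ||eps -
  eps_hat||^2`; under `"eps"` a bounded version of the same weighting is
  applied (`snr_cap`).
* **Head placement.** The topology (QRS mask) head consumes full-resolution
  decoder features, because the mask must be length `L`; it is a
  convolution plus sigmoid, emitting `r_hat` strictly inside `(0, 1)`.

Both heads are initialized near zero (exactly-zero heads under the eps
parameterization would emit `eps_hat = 0`, `r_hat = 0.5` but block all
upstream gradients on the very first step).

### Diffusion machinery

A linear variance schedule `beta_t` defines the forward corruption; the
closed-form marginal gives `x_t = sqrt(ab_t) x0 + sqrt(1 - ab_t) eps`
with `ab_t` the running product of `1 - beta_t`. Tweedie's single-step
estimate inverts it around the predicted noise,

    x0_hat = (x_t - sqrt(1 - ab_t) eps_hat) / sqrt(ab_t),

which is where the physics loss is evaluated — on the estimated clean
manifold rather than the noisy state. Ancestral sampling runs the learned
reverse chain from `x_T ~ N(0, I)`; by default the implied `x0_hat` is
clipped to `[-1, 1]` (signals are min-max normalized) and re-injected into
the posterior mean, and the posterior variance is `beta_tilde_t`
(`sigma = "beta"` is available).

`noise_schedule()` builds the canonical linear chain (1e-4 to 0.02 over
1000 steps). The desk-scale configuration uses `T = 50` with
`noise_schedule_scaled()`, whose endpoints `beta_1 = 0.5/T`,
`beta_T = 10/T` keep the total injected noise (`sum(beta) ~ 5.25`, hence
`ab_T ~ 5e-3`) independent of chain length: the short chain still ends at
the standard-normal prior that sampling starts from, and the
signal-to-noise ratio decays smoothly instead of collapsing in the first
few steps — an aggressive early decay leaves too few steps in the
mid-chain region where beat positions are committed, which shows up
directly as dropped beats in the samples.

### Composite objective

    L_total = lambda_diff * L_diff + lambda_reg * L_reg + lambda_phys * L_phys

* `L_diff`: element-mean MSE between injected and predicted noise.
* `L_reg`: element-mean binary cross-entropy between the topology head and
  the ground-truth QRS mask (probabilities clamped at 1e-7). The mask is
  the indicator `|t - t_p| <= 16` around each R-peak — 33 samples per
  interior peak, clipped at window edges.
* `L_phys`: MSE between the temporal derivative of `x0_hat` (central
  differences, one-sided at the edges; spacing one sample) and a learnable
  per-site linear projection `P(h_phys)` of the two moment channels. This
  couples the slope of the generated ECG to the momentum information the
  encoder extracted. Early in training, at large `t`, `x0_hat` amplifies
  the residual noise by `1 / sqrt(ab_t)`, so `L_phys` starts large and
  noisy; it collapses by two orders of magnitude within a few hundred
  steps as the noise prediction improves.

Weights default to `(1, 1, 0.1)`; they are exposed in `loss_weights()`.
The topology weight matters more than its auxiliary billing suggests: its
target is timestep-independent and purely condition-determined, so it is
the strongest teacher of the conditioning pathway at short budgets — at
`lambda_reg = 0.1` the topology branch stays unlearned after 500 steps,
at 1 it localizes QRS regions almost perfectly. Gradients flow into the
encoder both through the backbone conditioning and through the physics
target; `phys_target_detach = TRUE` stops the latter path if a
fixed-target reading is preferred. Timesteps are drawn uniformly on
`{1..T}` per example.

The optimizer is Adam (peak `lr = 2e-3`, linear warmup then cosine decay
to zero) — rates chosen for the short desk-scale runs this package
targets (hundreds of steps rather than the ~1e5-step regimes where 2e-4
is customary), from the descent behaviour of the training objective. The
global gradient norm is clipped at 1 before each update: the physics term
spikes by orders of magnitude whenever a high-`t` draw meets an imperfect
noise prediction, and without clipping each spike wipes the optimizer
state for hundreds of subsequent steps. An exponential moving average of
the parameters (`ema_decay = 0.99`) is kept and used for all inference.

## What the synthetic generator emulates

`generate_dataset()` produces paired records with known ground truth:

* ECG: per-beat sums of five Gaussian bumps (P, Q, R, S, T) with fixed
  relative offsets/widths/amplitudes scaled by the local RR interval;
  R dominant and positive, so R-peak indices are known by construction.
  RR intervals are Gaussian with mean `60 / HR` s and SD `rr_cv` times
  the mean, truncated to `[0.3, 2]` s (keeping templates from overlapping
  pathologically). The AF-like rhythm mode forces `rr_cv >= 0.15`,
  emulating the irregularly irregular RR sequence of atrial fibrillation;
  regular rhythm with `rr_cv = 0` yields CV below 0.02.
* PPG: one log-normal pulse (fast upstroke, slow decay) per beat, starting
  `round(ptt_s * fs)` samples after the R-peak, plus a 0.25 Hz baseline
  wander sinusoid and white noise. The kernel parameters place the
  steepest discrete upstroke within two samples of the pulse onset at
  128 Hz, making the PTT recoverable by cross-correlating the R-peak and
  onset impulse trains. The exact pulse shape is deliberately not
  load-bearing.
* Defaults (75 BPM, `rr_cv = 0.03`, PTT 0.25 s, `noise_sd = 0.02`,
  baseline wander 0.1) are the package's choice of a clean but non-sterile
  wearable-like record; the end-to-end study draws heart rate uniformly
  from 60-90 BPM and PTT from 0.2-0.3 s.

What it does **not** emulate: physiologically calibrated morphologies,
motion artifacts, sensor saturation, ectopic beats, or pathological
waveforms beyond rhythm irregularity. A model that passes the synthetic
study has demonstrated that the architecture, conditioning pathway and
objective function work as specified — not that it reconstructs clinical
ECG; that claim would require the clinical waveform corpora this package
deliberately does not depend on.

## Preprocessing conventions

Signals are resampled to 128 Hz (Fourier-domain, band-limited; linear
interpolation was rejected for aliasing), segmented into non-overlapping
4-s windows (`L = 512`, trailing remainder dropped), and min-max
normalized per window *and per channel* to `[-1, 1]` — channel-separate
normalization is required for exact per-modality inversion, whose
round-trip error is below 1e-10. Constant windows cannot be scaled; they
are returned as zeros with a degeneracy flag and excluded from training.
The QRS mask is the odd-width indicator `|t - t_p| <= 16` (33 samples per
interior peak): an even, 32-sample window cannot be centred on a peak
index, so the symmetric indicator is the consistent choice.
When simulator ground-truth peaks are available they are used for
mask supervision (removing detector error from training targets); the
simplified Pan-Tompkins detector (5-15 Hz band-pass, differentiate,
square, 150-ms integration, adaptive threshold, 200-ms refractory,
refinement to the local ECG maximum within 25 ms) is used for blind data
and for heart-rate evaluation, where it is applied symmetrically to true
and generated windows.

## Numerical choices and degenerate inputs

* All randomness flows through seeded generator handles isolated from the
  global RNG state; identical configurations are bit-reproducible.
* The conserving projection and streaming are exact in double precision
  (residuals below 1e-12 in practice; the tests require 1e-6).
* BCE probabilities are clamped at 1e-7; the Frechet-distance covariance
  gets a 1e-6 ridge, and its matrix square root is computed through the
  symmetrized product `S_r^(1/2) S_g S_r^(1/2)` with negative eigenvalue
  clamping — at `L = 512` with tens of windows the raw product is not
  exactly symmetric positive semidefinite.
* Heart rate uses the span between the first and last detected peak,
  `60 fs (n-1) / (t_last - t_first)`, which is robust to partial beats at
  window edges; windows with fewer than two peaks are excluded from
  HR-MAE rather than imputed.
* Gradients are computed by the package's own reverse-mode autodiff on
  dense matrices; every operator is validated against central finite
  differences (relative error under 1e-4) in the test suite, including
  end-to-end through the encoder and all three loss components.

## Desk-scale study sizes

The self-contained study trains the default configuration — `L = 512`,
base width 16, depth 5 with two blocks per level, `T = 50`, 500 Adam
steps, batch 16 — on 200 synthetic windows (heart rate 60-90 BPM, PTT
0.2-0.3 s) and evaluates on 32 held-out windows: trained-vs-untrained
RMSE, HR-MAE, and FD. These sizes are the package's chosen desk-scale
study conditions; a run takes a few minutes on one CPU. The acceptance
script reruns exactly this study.

## Known limitations

* The backbone is intentionally small; at these sizes the sampler's
  outputs reproduce beat placement and gross morphology, not fine P/T-wave
  detail. A residual failure mode is an occasional beat that fails to
  nucleate during sampling — the pulse transit time is not identifiable
  from a single PPG window (it varies per record), so the conditional
  mean of a sharp R-wave is phase-blurred and the sampler must commit to
  a phase; capacity determines how reliably it does.
* Periodic streaming boundaries are physically artificial at window edges.
* The Frechet distance at `L = 512` from ~32 windows is a heavily
  regularized estimate; it is reported for completeness but only large
  differences are meaningful at that sample size.
* Real-waveform ingestion is limited to the package's CSV containers;
  WFDB files are out of scope (no WFDB reader exists in this R stack, and
  no required path needs one).
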