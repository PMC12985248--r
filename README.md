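# physdiff

Physics-aware conditional diffusion for reconstructing single-lead ECG
waveforms from PPG (photoplethysmography) windows, in pure R.

Wearables measure PPG — the optical trace of peripheral blood-volume
change — while diagnosis needs the ECG. Each electrical R-peak launches a
pressure wave that reaches the periphery one pulse transit time (PTT)
later, so a PPG window carries latent information about the ECG that
produced it, low-pass filtered by the vascular tree. `physdiff` learns the
conditional distribution `p(x0 | c)` of an ECG window `x0` given its
paired PPG window `c` with a denoising diffusion probabilistic model
(DDPM) whose conditioning pathway and training objective embed
hemodynamic structure:

* **Lattice-Boltzmann physics encoder.** The PPG window is lifted into
  three non-negative mesoscopic channels (D1Q3, velocities `{-1, 0, +1}`)
  by `F_i = softplus(W_i c + b_i)`, evolved by K learnable
  collide-and-stream iterations, and read out as kinetic moments
  `rho = sum_i F_i`, `rho_u = sum_i e_i F_i`. The learned collision
  residual is moment-projected so mass and momentum are conserved
  *exactly* at every site, for any learned weights; streaming is an exact
  circular shift. `h_phys = [rho, rho_u]` conditions the denoiser.
* **Dual-branch 1-D U-Net.** A shared encoder-decoder over the noisy ECG
  `x_t` (with sinusoidal timestep embeddings) feeds a geometry head that
  predicts the injected noise `eps` and a topology head that predicts a
  QRS-region probability mask through a sigmoid. `h_phys` enters through
  cross-attention at the bottleneck (`Z' = Z + softmax(QK'/sqrt(d_k)) V`)
  and, by default, by input concatenation.
* **Composite objective.**
  `L = lambda_diff ||eps - eps_hat||^2 + lambda_reg BCE(r, r_hat)
  + lambda_phys ||d/dt x0_hat - P(h_phys)||^2`, where
  `x0_hat = (x_t - sqrt(1 - ab_t) eps_hat) / sqrt(ab_t)` is Tweedie's
  single-step denoising estimate — the physics constraint acts on the
  estimated clean signal, not the noisy state.

Because clinical waveform corpora are not required anywhere, the package
ships a synthetic paired PPG-ECG generator with known R-peaks,
controllable PTT, regular and AF-like (irregularly irregular) rhythms,
noise and baseline wander; training, evaluation and all tests run on it
at desk scale. Gradients come from a small reverse-mode autodiff engine
included in the package and validated against finite differences.

## Worked example

```r
library(physdiff)

# 1. simulate paired records (60-90 BPM, PTT 0.2-0.3 s) and window them
cfg  <- sim_config(duration_s = 20, seed = 1)
recs <- generate_dataset(48, cfg, seed = 1,
                         hr_range = c(60, 90), ptt_range = c(0.2, 0.3))
wins <- make_windows(recs)        # 4-s windows at 128 Hz, L = 512

# 2. fit the conditional diffusion model (desk-scale config)
fit <- physdiff(wins[1:200], steps = 500, base_width = 16, T_steps = 50,
                seed = 1, verbose = TRUE)
#> step 500  L_diff 0.0389  L_reg 0.0789  L_phys 0.0073  total 0.1185
print(fit)
#> Physics-aware PPG-to-ECG diffusion model
#>   window length L: 512   diffusion steps T: 50
#>   backbone: depth 5, base width 16, attention d_k 32
#>   LBM encoder: D1Q3, K = 4 collide-stream steps, exact projection
#>   trained steps: 500 on 200 windows
#>   final losses: L_diff 0.0389  L_reg 0.0789  L_phys 0.0073

# 3. translate held-out PPG windows into ECG and evaluate
hold <- wins[201:232]
gen  <- predict(fit, hold, seed = 2)
truth <- sapply(hold, `[[`, "ecg")
evaluate_windows(truth, gen, fs = 128)
#> RMSE   0.3469   (n = 32 windows)
#> HR-MAE 2.830 BPM (n = 32 windows with detectable rate)
#> FD     47.1246
```

Training takes a few minutes on one CPU. RMSE is pointwise error on the
min-max-normalized scale; HR-MAE compares heart rates derived from
Pan-Tompkins R-peak detection on true and generated windows (windows with
fewer than two detected peaks are excluded); FD is the Frechet
(Wasserstein-2) distance between Gaussian fits to the two window sets,
each window treated as one 512-dimensional vector. An untrained model
sampled on the same windows gives RMSE near 0.7 and no usable heart rate,
so the fitted values above reflect genuine conditioning on the PPG.

The lattice encoder, diffusion algebra and metrics are all exposed
directly (`lbm_encode()`, `forward_sample()`, `tweedie_x0()`,
`ancestral_sample()`, `frechet_distance()`, ...), and
`inst/cli/physdiff.R` wraps the pipeline (simulate / train / translate /
evaluate / e2e) for shell use.

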