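Package: physdiff
Title: Physics-Aware Conditional Diffusion for PPG-to-ECG Waveform Synthesis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reconstructs single-lead electrocardiogram (ECG) waveforms from
    photoplethysmography (PPG) windows with a conditional denoising diffusion
    model whose conditioning embedding is produced by a differentiable
    one-dimensional lattice-Boltzmann (D1Q3) hemodynamic encoder.  The
    denoising backbone is a dual-branch 1D U-Net with physics-guided
    cross-attention; training combines the standard noise-prediction loss
    with a QRS-region segmentation loss and a Tweedie-projected hemodynamic
    consistency loss.  Includes a synthetic paired PPG-ECG generator with
    known R-peak ground truth, a simplified Pan-Tompkins R-peak detector,
    and evaluation metrics (RMSE, heart-rate MAE, and Frechet distance on
    signal windows).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    graphics,
    utils,
    signal,
    jsonlite
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
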