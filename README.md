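# npwmf — nonprewhitening model observers for CT low-contrast detectability

Task-based image quality in CT is assessed with model observers: algorithms
that perform the clinical detection task (is the faint disk there or not?) and
report how well an ideal-but-human-calibrated reader would do. The
nonprewhitening matched filter (NPWMF) is the workhorse observer for
low-contrast detectability phantoms. It is almost always evaluated in the
Fourier domain from the noise power spectrum (NPS) and a task transfer
function (TTF) — a shortcut that is exact only for stationary noise. Modern
iterative and deep-learning reconstructions denoise nonlinearly and break that
assumption, and Fourier-domain figures of merit can then overstate the benefit
of denoising.

This package computes the NPWMF observer **three ways** so the routes can be
compared on the same images:

1. **Fourier** (method 1): `d′² = [∫ |ΔF(ν)|² |T(ν)|² dν]² / ∫ |ΔF(ν)|² |T(ν)|² N(ν) dν`,
   with the NPS `N` estimated from repeat scans, the TTF `T` from a disk edge,
   and `ΔF` the analytic disk task spectrum `C·π(D/2)²·2J₁(πDρ)/(πDρ)`.
2. **Spatial, Gaussian responses** (method 2): decision variables
   `L = Δī᙭ᵀ i` are formed for feature-present and feature-absent ROI vectors
   `i` (background-subtracted) with the template `Δī` equal to the expected
   present-minus-absent difference; then
   `d′² = (E[L₂] − E[L₁])² / (½(Var[L₁] + Var[L₂]))` and
   `AUC = Φ(d′ / √(1+β) / √2)`, where `β` is an internal-noise parameter
   (default 3.0) degrading the ideal observer to human efficiency.
3. **Spatial, general** (method 3): the nonparametric pairwise AUC
   `AUC = (n₁n₂)⁻¹ ΣΣ Φ((L₂ − L₁)/σ)` with internal noise
   `σ² = β(Var[L₁] + Var[L₂])`, assuming neither Gaussian responses nor
   stationarity.

Uncertainty comes with each route: a percentile bootstrap over TTF/NPS
replicates (method 1), the analytic relative uncertainty
`u = 100·√(1/(nm d′²) + 1/(4(n−1)m))` for `n` repeats × `m` slices
(method 2), and the standard error of per-slice AUCs (method 3). A
percent-correct to AUC conversion for M-alternative forced-choice reader
studies (`mafc_pc_to_auc()`) connects the model to human data.

Because scanner ensembles are bulky, the package ships a synthetic phantom
simulator: disk features blurred by a Gaussian PSF, embedded in correlated
quasi-stationary Gaussian noise synthesized from a parametric radial NPS, with
optional nonstationarity and an edge-preserving denoiser surrogate that
reproduces the qualitative behaviour of IR/DLIR denoising. Every estimation
path is testable against known ground truth.

## Worked example

```r
library(npwmf)

# a faint 4 mm / 10 HU detection task plus a 12 mm / 50 HU rod for the TTF
layout <- data.frame(center_x_mm = c(19.2, 57.6), center_y_mm = c(38.4, 19.2),
                     diameter_mm  = c(4, 12),     contrast_hu  = c(10, 50))
spec  <- phantom_spec(grid_shape = c(192, 192), pixel_size = 0.4,
                      features = lapply(seq_len(nrow(layout)), function(i)
                        do.call(disk_feature, as.list(layout[i, ]))),
                      psf_sigma = 0.6)
noise <- noise_spec("parametric-ramp", target_std = 10)
ens   <- simulate_ensemble(spec, noise, n_repeats = 40, m_slices = 5, seed = 1)

fit <- npwmf(ens, layout, beta = 3, bootstrap_B = 0)
fit
```

```
NPWMF model observer fit: 2 feature(s), beta = 3, n = 40 repeats x m = 5 slices

 feature          Fourier Spatial, Gaussian    Spatial, general
 D=4 mm, C=10 HU  0.862   0.853 (0.831, 0.872) 0.853 (0.838, 0.869)
 D=12 mm, C=50 HU 1.000   1.000 (1.000, 1.000) 1.000 (1.000, 1.000)
```

Each column is one estimation route; the value is the AUC of the observer for
that feature (with its 95% interval where the route provides one). On this
stationary ensemble the three routes agree: the faint 4 mm disk is detected
with AUC ≈ 0.85, the high-contrast rod is trivially detectable. For the 4 mm
feature the underlying detectability indices are d′ = 3.08 (Fourier) and
d′ = 2.96 ± 4.3% (spatial), consistent within the stated uncertainty. Enabling
the denoiser surrogate (`noise_spec(..., denoiser = list(strength = 0.9))`)
drives the Fourier column above the spatial columns — the divergence that
makes spatial-domain evaluation the safer choice for nonlinear
reconstructions. `summary(fit)`, `coef(fit)`, `plot(fit)`, and
`predict(fit, newdata)` expose the full outcome table, the AUC matrix, a CI
plot, and Fourier-domain predictions for unseen feature sizes.

A configuration-driven pipeline (`validate_config()` / `run_analysis()`) and a
thin CLI (`inst/cli/npwmf.R`, subcommands `simulate` / `analyze` / `compare`)
run the same analysis from a YAML file and write CSV/JSON outcome tables plus
a log of every defaulted decision. Ensembles are exchanged as multi-page TIFF
with a plain-text sidecar (`write_ensemble()` / `read_ensemble()`); externally
measured NPS/TTF curves enter as two-column CSV (`read_nps()` / `read_ttf()`).

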