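---
title: "NPWMF model observers in the Fourier and spatial domains"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{NPWMF model observers in the Fourier and spatial domains}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npwmf)
```

## The observer and its three computations

The nonprewhitening matched filter (NPWMF) is a linear observer whose template
is the expected signal: for an image vector $\mathbf{i}_{h,j}$ (class $h = 1$
absent, $h = 2$ present) the decision variable is the inner product
$L_{h,j} = \Delta\bar{\mathbf{i}}^{\mathsf T}\, \mathbf{i}_{h,j}$ with
$\Delta\bar{\mathbf i} = \mathrm E[\mathbf i_2 - \mathbf i_1] = \mathbf t\,\Delta\mathbf f$,
the object difference $\Delta\mathbf f$ seen through the system's spatial
transfer $\mathbf t$. Unlike prewhitening or Hotelling observers it applies no
noise decorrelation, which is what makes it both popular and sensitive to how
the noise statistics are represented.

The package evaluates the observer three ways on the same data:

* **Method 1 (Fourier).** Assuming quasi-stationary noise, detectability is
  the radial integral
  $d'^2 = \bigl[\int |\Delta F|^2 |T|^2 \, d\nu\bigr]^2 / \int |\Delta F|^2 |T|^2 N \, d\nu$
  over 2D spatial frequency, with the disk task spectrum
  $\Delta F(\rho) = C\,\pi (D/2)^2 \, 2 J_1(\pi D \rho)/(\pi D \rho)$ known
  analytically, the task transfer function $T$ measured from a disk edge, and
  the noise power spectrum $N$ measured from repeat scans.
* **Method 2 (spatial, Gaussian responses).** $d'$ from the first two moments
  of the decision variables,
  $d'^2 = (\mathrm E[L_2]-\mathrm E[L_1])^2 / \tfrac12(\mathrm{Var}[L_1]+\mathrm{Var}[L_2])$,
  mapped to $\mathrm{AUC} = \Phi\!\bigl(d'/\sqrt{1+\beta}/\sqrt2\bigr)$.
* **Method 3 (spatial, general).** The nonparametric pairwise AUC
  $\frac{1}{n_1 n_2}\sum\sum H(L_{2,i}-L_{1,j})$ (ties count one half), or its
  internal-noise smoothing $\Phi\bigl((L_{2,i}-L_{1,j})/\sigma\bigr)$ with
  $\sigma^2 = \beta(\mathrm{Var}[L_1]+\mathrm{Var}[L_2])$ — equivalent to the
  method-2 mapping exactly when the decision variables are Gaussian.

The internal-noise parameter $\beta$ (default **3.0**, dimensionless) degrades
the ideal linear observer to human efficiency; it was calibrated against
4-alternative forced-choice reader data, and `mafc_pc_to_auc()` provides the
percent-correct to AUC conversion (Gaussian independent responses, the
M-AFC integral solved by quadrature and root-finding to $10^{-9}$) used for
such comparisons.

Methods 2 and 3 need no stationarity assumption. Method 1 does, and the
package exists largely to quantify what happens when that assumption fails:
on stationary ensembles all three agree; with the denoiser surrogate enabled
the Fourier route reports systematically higher AUC than the spatial routes.

## ROI geometry and extraction

For each feature the present ROI is a circle of radius $D/2$ in pixels —
kept real-valued, not rounded — expanded by `n_exp` pixels; a gap of `n_gap`
pixels separates it from a background annulus `n_ann` wide. Defaults are
(4, 4, 4), the values used with an in-house iodine-insert phantom at 0.469 mm
pixels; a `"catphan"` preset supplies (3, 3, 3) for the tighter Catphan
CTP515 layout. Annulus pixels overlapping a neighbouring feature's ROI are
excluded. The local background — the annulus mean averaged over all repeat
scans, computed per slice position, so slice-to-slice level differences are
respected — is subtracted from every extracted vector. The feature-absent ROI
is an exact mirror of the present mask about the image vertical midline by
default; where the background is not mirror-symmetric the caller supplies
per-feature offsets instead (the absent mask is then the present mask
translated by a whole number of pixels, which guarantees equal pixel counts).
Coordinates are 0-based (row, column) with pixel centres at integer positions.

Background subtraction matters twice. First, it makes the absent-class
expectation exactly zero, so the template can be estimated from the present
class alone (`estimate_template(..., source = "present")`), halving template
noise; the default remains the two-class difference. Second, it is the reason
the lower-variance `dprime_spatial(..., absent_mean = "zero")` variant is
valid: the absent mean is known, not estimated. The analytic uncertainty
$u = 100\sqrt{1/(nm\,d'^2) + 1/(4(n-1)m)}$ (one ROI pair per slice,
independent responses) describes exactly that estimation route; estimating
the absent mean from data adds a second $1/(nm\,d'^2)$ term and inflates the
spread about 15 % above $u$ at $d' \approx 2.8$, $nm = 550$. The package's
calibration tests therefore exercise the known-zero route; the default
two-mean estimator is kept for general use where background subtraction
may be imperfect.

A related caveat is resubstitution bias: when the template is estimated from
the same observations it is applied to, $\hat d'$ is biased upward by roughly
$p/(2\,nm\,d'^2)$ for $p$ ROI pixels (a few percent for typical geometries,
worse for large ROIs or small ensembles). In simulation studies the analytic
template (`template = "analytic"`, the known blurred disk profile) removes
both this bias and the template noise, and is what the package's
cross-domain equivalence checks use.

## Fourier-side estimation choices

The estimation details are deliberately conventional and all configurable:

* **NPS.** Noise realizations are each repeat minus the across-repeat mean
  image (per slice), rescaled by $n/(n-1)$. Square ROIs (default 64 px) tile
  the background with 50 % overlap; each patch is mean-subtracted, tapered by
  a power-normalized Hann window (plain periodograms of mid-frequency-peaked
  CT spectra leak badly into the low-frequency band — +65 % in the first band
  in a rectangular-window experiment at 64 px — while the taper keeps
  band-averaged errors within a few percent), transformed, and averaged; the
  2D spectrum is radially binned with width $1/(\text{roi}\cdot\Delta x)$.
  Parseval's identity (NPS integral = pixel variance) holds to < 3 % and is
  asserted in the tests.
* **TTF.** Circular-edge technique on the across-repeat mean image: the disk
  centre is refined by an intensity-weighted centroid of the thresholded
  disk, the edge-spread function is accumulated in 0.1 px radial bins,
  differentiated by central differences, and the magnitude of its complex
  Fourier transform (shift-invariant, unlike a cosine transform) is
  normalized to one at zero frequency, with noise-floor truncation beyond the
  first near-zero dip. Against a known Gaussian PSF the recovered TTF is
  within 3 % down to the 10 % amplitude point. A contrast-to-noise guard
  (default 5) refuses unreliable edges and recommends more repeats. Because
  TTF noise, not NPS noise, dominates the variance of the Fourier $d'$ when
  the edge is faint, the recommended phantom includes a dedicated
  high-contrast rod (12 mm, 50 HU in the default layout) for the TTF — the
  standard practice of measuring transfer on a measurable insert.
* **Integration.** Both curves are interpolated onto a common radial grid up
  to the Nyquist frequency of the coarser input and integrated with the
  trapezoidal rule and $2\pi\rho\,d\rho$ weighting (1024 nodes by default).

Uncertainty for method 1 uses the percentile bootstrap (default 1000
resamples) over per-slice TTF curves and per-repeat NPS curves; a scaled-down
coverage experiment in the test suite (150 trials) observes ~93 % coverage
for nominal 95 % intervals, the mild undercoverage expected with few
replicates. Method-2 intervals are built on the $d'$ scale
($d' \pm 1.96\,u\,d'/100$) and mapped through the AUC relation; building them
on the AUC scale by the delta method changes the bounds by less than the
printed precision, so the $d'$-scale construction was kept. Method-3
uncertainty is the standard error of per-slice AUCs
($z_{0.95} = 1.959964$ throughout).

## What the simulator emulates — and what it does not

`simulate_ensemble()` produces $n$ repeats × $m$ slices of a noiseless
phantom rendering plus independent correlated Gaussian noise:

* **Features** are disks rendered by pixel-centre membership on a 4×
  supersampled grid (anti-aliasing keeps 1–2 mm features free of quantization
  bias), blurred by a Gaussian PSF that stands in for the system transfer;
  the blur conserves integrated signal. Default conditions: 0.4 mm pixels,
  0.6 mm PSF, features of 1–32 mm and 2–50 HU as configured.
* **Noise** is white Gaussian coloured in the frequency domain by a real
  radial filter (Hermitian by construction). The default
  `parametric-ramp` amplitude $\rho\,e^{-(\rho/\rho_c)^2}$ with
  $\rho_c = 0.35\,\mathrm{mm}^{-1}$ peaks near $0.25\,\mathrm{mm}^{-1}$, the
  texture of a typical filtered-backprojection body kernel; the target pixel
  standard deviation defaults to 10 HU, a standard-dose abdominal level. The
  ramp is a plausible stand-in, not a reconstruction of any particular
  scanner's spectrum. A `custom-radial-table` model accepts measured curves.
* **Nonstationarity** enters two ways: a linear left–right gradient of the
  noise standard deviation, and an edge-preserving denoiser surrogate — a
  mix of the image with a Gaussian-smoothed copy, weighted by
  $s\,e^{-(G/g_0)^2}$ for local gradient magnitude $G$ (defaults
  $s = 0.9$, smoothing $\sigma = 2.5$ px, $g_0 = 4$ HU/px). In flat regions
  it suppresses noise strongly; at high-contrast edges it preserves
  structure; faint low-contrast features sit in between and are partially
  smoothed — precisely the regime in which a TTF measured on a high-contrast
  edge fails to describe the task. No vendor algorithm is modelled; any
  nonlinearity with this signature exercises the Fourier/spatial divergence,
  which is the surrogate's entire purpose, and its strength was chosen so the
  effect is plainly measurable (flat-region noise roughly halved).

One master seed drives everything; per-image streams are derived
deterministically, so ensembles are bit-identical across reruns and across
partial reads.

The simulator does **not** emulate projection/reconstruction physics,
anatomical backgrounds, slice-direction correlations, non-Gaussian noise, or
any specific IR/DLIR product. Passing tests therefore demonstrate the
estimators' internal consistency and their behaviour under controlled
stationarity violations — not agreement with any particular scanner.

## Study conditions used by the consistency checks

The test suite fixes these problem sizes as the package's validation
conditions:

* **Cross-domain equivalence**: 6 mm / 10 HU disk, ramp noise at 10 HU,
  $110 \times 5$ images per ensemble, $d'$ averaged over three independent
  ensembles before comparison (a single ensemble's spatial estimate carries
  ~2.5 % statistical spread, and the annulus-background common mode under
  strongly correlated noise adds more; averaging makes the 5 % comparison a
  test of the methods rather than of one realization). Agreement is within
  5 %.
* **Divergence under denoising**: 4 mm / 10 HU disk (mid-AUC regime, where
  AUC differences are not compressed by saturation), denoiser surrogate on;
  the Fourier AUC exceeds both spatial AUCs.
* **Method 2 vs 3**: same 4 mm task, $\beta \in \{0, 3\}$, agreement within
  the combined reported uncertainties.
* **Uncertainty calibration**: 200 ROI-level Gaussian ensembles (the sampling
  model under which the formula is derived; simulating at the ROI level
  keeps 200 replicates cheap without changing the estimator surface) at a
  designed $d' = 2.79$, $n = 110$, $m = 5$, and again at $n = 10$: the
  empirical spread of $\hat d'$ matches $u$ within 15 %.

## Known limitations

* The absent-ROI mirror rule assumes a left–right symmetric background;
  asymmetric phantoms need explicit offsets.
* DICOM series are not read directly; convert to multi-page TIFF (HU-scaled)
  or supply arrays. Pixel spacing and HU scaling travel in the plain-text
  sidecar.
* The 2D treatment ignores slice-direction transfer and 3D NPS.
* Channelized Hotelling and prewhitening observers, and search/localization
  tasks, are out of scope.
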