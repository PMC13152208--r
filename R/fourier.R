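# 2D separable Hann taper, unit power scaling handled by the caller
nps_taper <- function(roi_size, window) {
  if (window == "none") return(matrix(1, roi_size, roi_size))
  w1 <- 0.5 * (1 - cos(2 * pi * seq(0, roi_size - 1) / (roi_size - 1)))
  outer(w1, w1)
}

# radial binning of a 2D spectrum sampled on the DFT grid
radial_bin <- function(values2d, fy, fx, bin_width, fmax = NULL) {
  rho <- sqrt(outer(fy^2, fx^2, "+"))
  if (is.null(fmax)) fmax <- max(abs(c(fy, fx)))  # bin up to the axis Nyquist
  bins <- floor(as.vector(rho) / bin_width)
  keep <- as.vector(rho) <= fmax + 1e-12
  v <- as.vector(values2d)[keep]; b <- bins[keep]
  agg <- rowsum(cbind(v, 1), b)
  centers <- (as.numeric(rownames(agg)) + 0.5) * bin_width
  list(freq = centers, values = agg[, 1] / agg[, 2])
}

#' Estimate the noise power spectrum from an ensemble
#'
#' Noise realizations are formed by subtracting the across-repeat mean image
#' (per slice) from each repeat, which removes the deterministic phantom
#' structure; the resulting spectra are scaled by `n/(n-1)` to undo the
#' variance removed with the mean. Square ROIs are tiled over the requested
#' region with 50 percent overlap (or placed at `roi_centers`), each ROI has
#' its own mean removed, and the 2D periodogram `dx*dy/(Nx*Ny) * |DFT|^2`
#' averaged over all ROIs and realizations is radially binned with bin width
#' `1/(roi_size * dx)`.
#'
#' @param ensemble an `image_ensemble` with >= 2 repeats.
#' @param roi_size side of the square NPS ROIs in pixels (default 64).
#' @param roi_centers optional list/matrix of c(row, col) ROI centres
#'   (0-based); by default ROIs are tiled over the whole image.
#' @param exclude optional logical matrix marking pixels (e.g. feature ROIs)
#'   no NPS ROI may touch; an explicitly supplied centre violating it is an
#'   error, tiled centres are silently dropped.
#' @param window `"hann"` (default) applies a power-normalized Hann taper to
#'   each patch before the DFT, suppressing spectral leakage from peaked
#'   spectra into the low-frequency band; `"none"` is the plain periodogram.
#' @return object of class `noise_power_spectrum`: `radial_freq` (1/mm bin
#'   centres), `values` (HU^2 mm^2), `pixel_size`, `n_rois`, plus the mean
#'   2D periodogram and the mean realization variance as attributes for
#'   Parseval checks.
#' @export
estimate_nps <- function(ensemble, roi_size = 64, roi_centers = NULL, exclude = NULL,
                         window = c("hann", "none")) {
  window <- match.arg(window)
  stopifnot(inherits(ensemble, "image_ensemble"))
  if (ensemble$n_repeats < 2L) stop_npwmf("NPS estimation needs at least 2 repeats")
  roi_size <- as.integer(roi_size)
  nr <- ensemble$grid_shape[1]; nc <- ensemble$grid_shape[2]
  if (roi_size > min(nr, nc)) stop_npwmf("roi_size exceeds the image")
  half <- roi_size / 2
  explicit <- !is.null(roi_centers)
  if (!explicit) {
    step <- max(1L, roi_size %/% 2L)  # 50% overlap tiling
    r0 <- seq(half, nr - half, by = step)
    c0 <- seq(half, nc - half, by = step)
    roi_centers <- as.matrix(expand.grid(row = r0 - 0.5, col = c0 - 0.5))
  } else if (is.list(roi_centers)) {
    roi_centers <- do.call(rbind, roi_centers)
  }
  # ROI pixel windows; 0-based centres -> 1-based index ranges
  windows <- list()
  for (i in seq_len(nrow(roi_centers))) {
    rs <- floor(roi_centers[i, 1] - half + 1) + 1
    cs <- floor(roi_centers[i, 2] - half + 1) + 1
    if (rs < 1 || cs < 1 || rs + roi_size - 1 > nr || cs + roi_size - 1 > nc) {
      if (explicit) stop_npwmf("NPS ROI centre out of bounds") else next
    }
    rows <- rs:(rs + roi_size - 1); cols <- cs:(cs + roi_size - 1)
    if (!is.null(exclude) && any(exclude[rows, cols])) {
      if (explicit) stop_npwmf("NPS ROI overlaps an excluded (feature) region") else next
    }
    windows[[length(windows) + 1L]] <- list(rows = rows, cols = cols)
  }
  if (length(windows) == 0L) stop_npwmf("no admissible NPS ROI positions")
  dx <- ensemble$pixel_size
  n <- ensemble$n_repeats; m <- ensemble$m_slices
  taper <- nps_taper(roi_size, window)
  acc <- matrix(0, roi_size, roi_size)
  var_acc <- 0; count <- 0L
  for (s in seq_len(m)) {
    msl <- slice_mean(ensemble, s)
    for (r in seq_len(n)) {
      noise <- ensemble$pixels[r, s, , ] - msl
      for (w in windows) {
        patch <- noise[w$rows, w$cols]
        patch <- patch - mean(patch)
        var_acc <- var_acc + var(as.vector(patch))
        acc <- acc + Mod(fft(patch * taper))^2
        count <- count + 1L
      }
    }
  }
  scale <- dx * dx / sum(taper^2) * n / (n - 1)
  nps2d <- acc / count * scale
  f <- fft_freq(roi_size, dx)
  rb <- radial_bin(nps2d, f, f, bin_width = 1 / (roi_size * dx))
  structure(list(radial_freq = rb$freq, values = rb$values, pixel_size = dx,
                 n_rois = length(windows), n_realizations = count),
            class = "noise_power_spectrum",
            nps2d = nps2d, realization_variance = var_acc / count * n / (n - 1))
}

#' Construct a noise power spectrum from a radial table
#'
#' @param radial_freq frequencies in 1/mm.
#' @param values NPS values in HU^2 mm^2, >= 0.
#' @param pixel_size pixel spacing in mm (used for Nyquist bookkeeping).
#' @return a `noise_power_spectrum`.
#' @export
nps_table <- function(radial_freq, values, pixel_size = NA_real_) {
  if (any(values < 0)) stop_npwmf("NPS values must be >= 0")
  structure(list(radial_freq = radial_freq, values = values,
                 pixel_size = pixel_size, n_rois = NA_integer_),
            class = "noise_power_spectrum")
}

#' @export
print.noise_power_spectrum <- function(x, ...) {
  cat(sprintf("Radial NPS: %d bins up to %.3g /mm; integral %.4g HU^2\n",
              length(x$radial_freq), max(x$radial_freq),
              2 * pi * trapz(x$radial_freq, x$radial_freq * x$values)))
  invisible(x)
}

#' Estimate the task transfer function from a disk edge
#'
#' Measures the contrast-specific modulation transfer via the circular-edge
#' technique on the across-repeat mean image: the edge-spread function is
#' accumulated in subpixel radial bins about the disk centre (found by
#' intensity-weighted centroid of the thresholded disk), differentiated to a
#' line-spread function, Fourier-transformed, and normalized to 1 at zero
#' frequency. Values beyond the first zero crossing of the transform are
#' truncated to zero (noise-floor truncation).
#'
#' @param ensemble an `image_ensemble`; the mean over all repeats and slices
#'   is used.
#' @param feature a [disk_feature()] describing the edge disk; at least
#'   ~15 px in diameter.
#' @param bin_px radial ESF bin width in pixels (default 0.1).
#' @param min_cnr minimum contrast-to-noise of the mean-image edge; below
#'   this an error recommends more repeats (default 5).
#' @param slices optional subset of slice indices to average over (used for
#'   per-slice TTF replicates).
#' @return object of class `task_transfer_function` with `radial_freq`
#'   (1/mm, up to Nyquist) and dimensionless `values`, `values[1] = 1` at
#'   zero frequency.
#' @export
estimate_ttf <- function(ensemble, feature, bin_px = 0.1, min_cnr = 5, slices = NULL) {
  stopifnot(inherits(ensemble, "image_ensemble"), inherits(feature, "disk_feature"))
  dx <- ensemble$pixel_size
  r_px <- feature$diameter_mm / 2 / dx
  if (2 * r_px < 15) stop_npwmf("disk too small for circular-edge analysis (need >= ~15 px diameter)")
  if (is.null(slices)) slices <- seq_len(ensemble$m_slices)
  sub <- ensemble$pixels[, slices, , , drop = FALSE]
  img <- apply(sub, c(3, 4), mean)
  nr <- nrow(img); nc <- ncol(img)
  c0 <- c(feature$center_y_mm, feature$center_x_mm) / dx  # (row, col), 0-based
  # refine centre: intensity-weighted centroid of the thresholded disk
  rows <- seq_len(nr) - 1; cols <- seq_len(nc) - 1
  win <- outer((rows - c0[1])^2, (cols - c0[2])^2, "+") <= (1.5 * r_px)^2
  bgring <- outer((rows - c0[1])^2, (cols - c0[2])^2, "+")
  bgmask <- bgring > (1.8 * r_px)^2 & bgring <= (2.5 * r_px)^2
  bg <- mean(img[bgmask])
  dimg <- (img - bg) * sign(feature$contrast_hu)
  thr <- dimg * (dimg > 0.5 * max(dimg[win])) * win
  if (sum(thr) <= 0) stop_npwmf("could not localize the disk for TTF estimation")
  cy <- sum(outer(rows, rep(1, nc)) * thr) / sum(thr)
  cx <- sum(outer(rep(1, nr), cols) * thr) / sum(thr)
  # edge CNR check on the mean image
  noise_sd <- sd(img[bgmask])
  cnr <- max(dimg[win]) / max(noise_sd, 1e-12)
  if (cnr < min_cnr) {
    stop_npwmf(sprintf(
      "mean-image CNR %.2f below %.2f: TTF unreliable, use more repeats", cnr, min_cnr))
  }
  # radial ESF in subpixel bins over r in [0, r_max]
  rad <- sqrt(outer((rows - cy)^2, (cols - cx)^2, "+"))
  r_max <- min(2 * r_px, (min(nr, nc) / 2 - 2))
  keep <- rad <= r_max
  b <- floor(rad[keep] / bin_px)
  agg <- rowsum(cbind(dimg[keep], 1), b)
  esf <- rep(NA_real_, max(as.numeric(rownames(agg))) + 1)
  esf[as.numeric(rownames(agg)) + 1] <- agg[, 1] / agg[, 2]
  rmid <- (seq_along(esf) - 0.5) * bin_px * dx  # bin centres in mm
  if (anyNA(esf)) {  # fill sparse inner bins by interpolation
    ok <- which(!is.na(esf))
    esf <- approx(rmid[ok], esf[ok], xout = rmid, rule = 2)$y
  }
  # LSF by central differences (edge is a falling profile: negate)
  n_e <- length(esf)
  lsf <- numeric(n_e)
  lsf[2:(n_e - 1)] <- -(esf[3:n_e] - esf[1:(n_e - 2)]) / (2 * bin_px * dx)
  # direct transform of the LSF on a radial frequency grid up to Nyquist
  nyq <- 1 / (2 * dx)
  freq <- seq(0, nyq, length.out = 128L)
  dr <- bin_px * dx
  # complex transform so the magnitude is invariant to the edge position
  mtf <- vapply(freq, function(f) Mod(sum(lsf * exp(-2i * pi * f * rmid)) * dr), 0)
  if (mtf[1] <= 0) stop_npwmf("degenerate edge profile: zero-frequency response vanished")
  mtf <- mtf / mtf[1]
  # monotone noise-floor truncation beyond the first near-zero dip
  dipped <- which(mtf < 0.005)
  if (length(dipped) > 0) mtf[min(dipped):length(mtf)] <- 0
  structure(list(radial_freq = freq, values = mtf, pixel_size = dx,
                 center = c(cy, cx), cnr = cnr),
            class = "task_transfer_function")
}

#' Construct a TTF from a radial table
#'
#' @param radial_freq frequencies in 1/mm starting at 0.
#' @param values dimensionless transfer values; `values[1]` must be 1.
#' @return a `task_transfer_function`.
#' @export
ttf_table <- function(radial_freq, values) {
  if (abs(values[1] - 1) > 1e-6) stop_npwmf("TTF must equal 1 at zero frequency")
  if (any(!is.finite(values))) stop_npwmf("TTF values must be finite")
  structure(list(radial_freq = radial_freq, values = values),
            class = "task_transfer_function")
}

#' @export
print.task_transfer_function <- function(x, ...) {
  f50 <- if (any(x$values <= 0.5)) x$radial_freq[which(x$values <= 0.5)[1]] else NA
  cat(sprintf("TTF: %d frequencies up to %.3g /mm; f50 ~ %.3g /mm\n",
              length(x$radial_freq), max(x$radial_freq), f50))
  invisible(x)
}

#' Analytic task spectrum of a uniform disk
#'
#' The 2D Fourier transform of a disk of diameter D and contrast C is the
#' radially symmetric Airy profile `C * pi (D/2)^2 * 2 J1(pi D rho) /
#' (pi D rho)`, with the rho -> 0 limit `C * pi (D/2)^2` handled
#' analytically. Its first zero sits at `rho = 3.8317 / (pi D)`.
#'
#' @param feature a [disk_feature()].
#' @return object of class `disk_task_spectrum`; element `profile` is a
#'   vectorized function of radial frequency in 1/mm.
#' @export
disk_spectrum <- function(feature) {
  stopifnot(inherits(feature, "disk_feature"))
  C <- feature$contrast_hu; D <- feature$diameter_mm
  dc <- C * pi * (D / 2)^2
  profile <- function(rho) {
    x <- pi * D * rho
    out <- rep(dc, length(x))
    nz <- x != 0
    out[nz] <- dc * 2 * besselJ(x[nz], 1) / x[nz]
    out
  }
  structure(list(contrast = C, diameter = D, profile = profile, dc = dc),
            class = "disk_task_spectrum")
}

#' Fourier-domain NPWMF detectability index
#'
#' Evaluates `d'^2 = [int |dF|^2 |T|^2 dnu]^2 / int |dF|^2 |T|^2 N dnu` as
#' 1D radial integrals with `2 pi rho drho` weighting, interpolating the
#' NPS and TTF onto a common radial grid up to the Nyquist frequency of the
#' coarser input (trapezoidal rule).
#'
#' @param nps a `noise_power_spectrum`.
#' @param ttf a `task_transfer_function`, or `NULL` for an ideal system
#'   (T = 1).
#' @param task a `disk_task_spectrum`.
#' @param n_grid number of radial quadrature nodes (default 1024).
#' @return d-prime (non-negative scalar).
#' @export
dprime_fourier <- function(nps, ttf, task, n_grid = 1024L) {
  stopifnot(inherits(nps, "noise_power_spectrum"), inherits(task, "disk_task_spectrum"))
  fmax <- max(nps$radial_freq)
  if (!is.null(ttf)) fmax <- min(fmax, max(ttf$radial_freq))
  if (fmax <= 0) stop_npwmf("frequency supports do not overlap")
  rho <- seq(0, fmax, length.out = n_grid)
  S <- task$profile(rho)^2
  Tv <- if (is.null(ttf)) rep(1, n_grid) else {
    pmax(approx(ttf$radial_freq, ttf$values, xout = rho, rule = 2)$y, 0)
  }
  Nv <- pmax(approx(nps$radial_freq, nps$values, xout = rho, rule = 2)$y, 0)
  w <- 2 * pi * rho
  num <- trapz(rho, S * Tv^2 * w)
  den <- trapz(rho, S * Tv^2 * Nv * w)
  if (den <= 0) stop_npwmf("non-positive noise integral: NPS is degenerate over the task band")
  sqrt(num^2 / den)
}

#' Per-slice TTF and per-repeat NPS replicate curves
#'
#' Builds the replicate sets consumed by [bootstrap_ci_fourier()]: one TTF
#' per slice position and one radial NPS per repeat scan, all on their
#' native common grids.
#'
#' @param ensemble an `image_ensemble`.
#' @param feature the edge disk for the TTF.
#' @param ... passed to [estimate_ttf()].
#' @return `ttf_replicates`: list with `freq` and a slices x frequencies
#'   `values` matrix.
#' @export
ttf_replicates <- function(ensemble, feature, ...) {
  curves <- lapply(seq_len(ensemble$m_slices), function(s)
    estimate_ttf(ensemble, feature, slices = s, ...))
  list(freq = curves[[1]]$radial_freq,
       values = do.call(rbind, lapply(curves, `[[`, "values")))
}

#' @rdname ttf_replicates
#' @param roi_size,roi_centers,exclude passed to [estimate_nps()].
#' @return `nps_replicates`: list with `freq` and a repeats x frequencies
#'   `values` matrix.
#' @export
nps_replicates <- function(ensemble, roi_size = 64, roi_centers = NULL, exclude = NULL) {
  n <- ensemble$n_repeats
  if (n < 3L) stop_npwmf("per-repeat NPS replicates need at least 3 repeats")
  roi_size <- as.integer(roi_size)
  dx <- ensemble$pixel_size
  half <- roi_size / 2
  nr <- ensemble$grid_shape[1]; nc <- ensemble$grid_shape[2]
  if (is.null(roi_centers)) {
    step <- max(1L, roi_size %/% 2L)
    r0 <- seq(half, nr - half, by = step)
    c0 <- seq(half, nc - half, by = step)
    roi_centers <- as.matrix(expand.grid(row = r0 - 0.5, col = c0 - 0.5))
  } else if (is.list(roi_centers)) roi_centers <- do.call(rbind, roi_centers)
  windows <- list()
  for (i in seq_len(nrow(roi_centers))) {
    rs <- floor(roi_centers[i, 1] - half + 1) + 1
    cs <- floor(roi_centers[i, 2] - half + 1) + 1
    if (rs < 1 || cs < 1 || rs + roi_size - 1 > nr || cs + roi_size - 1 > nc) next
    rows <- rs:(rs + roi_size - 1); cols <- cs:(cs + roi_size - 1)
    if (!is.null(exclude) && any(exclude[rows, cols])) next
    windows[[length(windows) + 1L]] <- list(rows = rows, cols = cols)
  }
  if (length(windows) == 0L) stop_npwmf("no admissible NPS ROI positions")
  means <- lapply(seq_len(ensemble$m_slices), function(s) slice_mean(ensemble, s))
  f <- fft_freq(roi_size, dx)
  taper <- nps_taper(roi_size, "hann")
  curves <- lapply(seq_len(n), function(r) {
    acc <- matrix(0, roi_size, roi_size); count <- 0L
    for (s in seq_len(ensemble$m_slices)) {
      noise <- ensemble$pixels[r, s, , ] - means[[s]]
      for (w in windows) {
        patch <- noise[w$rows, w$cols]
        patch <- (patch - mean(patch)) * taper
        acc <- acc + Mod(fft(patch))^2
        count <- count + 1L
      }
    }
    nps2d <- acc / count * dx * dx / sum(taper^2) * n / (n - 1)
    radial_bin(nps2d, f, f, bin_width = 1 / (roi_size * dx))
  })
  list(freq = curves[[1]]$freq,
       values = do.call(rbind, lapply(curves, `[[`, "values")))
}

#' Read / write radial curves as two-column CSV
#'
#' Allows externally measured NPS or TTF curves (columns `freq_mm^-1`,
#' `value`) to enter the Fourier pipeline, and estimated curves to leave it.
#'
#' @param x a `noise_power_spectrum` or `task_transfer_function`.
#' @param path CSV path.
#' @return `write_curve`: the path invisibly; `read_nps` / `read_ttf`: the
#'   reconstructed object.
#' @export
write_curve <- function(x, path) {
  df <- data.frame(freq = x$radial_freq, value = x$values)
  names(df) <- c("freq_mm^-1", "value")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_curve
#' @export
read_nps <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  nps_table(df[[1]], df[[2]])
}

#' @rdname write_curve
#' @export
read_ttf <- function(path) {
  df <- read.csv(path, check.names = FALSE)
  ttf_table(df[[1]], df[[2]])
}
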