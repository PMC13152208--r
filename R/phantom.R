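#' Disk feature description
#'
#' A circular low-contrast feature, the canonical detection task for CT
#' low-contrast detectability phantoms (drilled cavities filled with iodine
#' solution, or the supra-slice targets of a Catphan CTP515 module).
#'
#' @param center_x_mm,center_y_mm feature centre in mm (x = column direction,
#'   y = row direction, origin at the centre of pixel (0, 0)).
#' @param diameter_mm disk diameter in mm, > 0.
#' @param contrast_hu nominal contrast in HU relative to the background.
#' @return an object of class `disk_feature`.
#' @export
disk_feature <- function(center_x_mm, center_y_mm, diameter_mm, contrast_hu) {
  check_number(center_x_mm, "center_x_mm")
  check_number(center_y_mm, "center_y_mm")
  check_number(diameter_mm, "diameter_mm", lower = .Machine$double.eps)
  check_number(contrast_hu, "contrast_hu")
  structure(list(center_x_mm = center_x_mm, center_y_mm = center_y_mm,
                 diameter_mm = diameter_mm, contrast_hu = contrast_hu),
            class = "disk_feature")
}

#' Phantom specification
#'
#' Describes a noiseless phantom slice: a uniform background carrying disk
#' features, imaged through a Gaussian point-spread function that stands in
#' for the system's spatial transfer.
#'
#' @param grid_shape integer c(rows, cols) of the pixel grid.
#' @param pixel_size pixel spacing in mm (isotropic), > 0.
#' @param background_level background in HU.
#' @param features list of [disk_feature] objects (or a single one).
#' @param psf_sigma standard deviation of the Gaussian PSF in mm (0 = none).
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape, pixel_size, background_level = 0,
                         features = list(), psf_sigma = 0) {
  if (length(grid_shape) != 2L || any(grid_shape < 1)) {
    stop_npwmf("'grid_shape' must be c(rows, cols) with positive entries")
  }
  grid_shape <- as.integer(grid_shape)
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  check_number(background_level, "background_level")
  check_number(psf_sigma, "psf_sigma", lower = 0)
  if (inherits(features, "disk_feature")) features <- list(features)
  if (!all(vapply(features, inherits, logical(1), "disk_feature"))) {
    stop_npwmf("'features' must be a list of disk_feature objects")
  }
  extent <- (grid_shape - 1L) * pixel_size  # c(y, x) physical extent
  for (f in features) {
    r <- f$diameter_mm / 2
    if (f$center_x_mm - r < 0 || f$center_x_mm + r > extent[2] ||
        f$center_y_mm - r < 0 || f$center_y_mm + r > extent[1]) {
      stop_npwmf(sprintf(
        "feature at (%.2f, %.2f) mm with diameter %.2f mm extends outside the %.1f x %.1f mm grid",
        f$center_x_mm, f$center_y_mm, f$diameter_mm, extent[2], extent[1]))
    }
  }
  structure(list(grid_shape = grid_shape, pixel_size = pixel_size,
                 background_level = background_level, features = features,
                 psf_sigma = psf_sigma),
            class = "phantom_spec")
}

#' Noise model specification
#'
#' Parametric description of the stochastic part of the simulator: a radial
#' noise power spectrum shape, a target pixel standard deviation, an optional
#' left-right nonstationarity gradient, and an optional nonlinear denoiser
#' surrogate emulating the flat-region noise suppression of iterative /
#' deep-learning reconstruction.
#'
#' The `parametric-ramp` model uses the apodized-ramp amplitude
#' `|H(rho)| = rho * exp(-(rho/rho_c)^2)`, a standard stand-in for the
#' mid-frequency-peaked texture of filtered-backprojection body kernels.
#'
#' @param model one of `"white"`, `"parametric-ramp"`, `"custom-radial-table"`.
#' @param target_std target pixel standard deviation in HU (>= 0), defined
#'   before any denoiser or nonstationarity is applied.
#' @param ramp_cutoff cutoff `rho_c` in 1/mm for the ramp model; the resulting
#'   NPS peaks near `rho_c / sqrt(2)`. Default 0.35 /mm puts the peak around
#'   0.25 /mm, typical of an abdominal kernel.
#' @param radial_table data.frame with columns `freq` (1/mm) and `value`
#'   (relative NPS, >= 0) for the custom model.
#' @param nonstationary_gradient dimensionless left-right linear gradient of
#'   the noise standard deviation (0 = stationary; `g` means the std ramps
#'   from `1 - g/2` to `1 + g/2` times nominal across the image width).
#' @param denoiser `NULL`, or a list describing the edge-preserving denoiser
#'   surrogate, see [apply_denoiser()]; e.g.
#'   `list(kind = "edge_preserving", strength = 0.8)`.
#' @return an object of class `noise_spec`.
#' @export
noise_spec <- function(model = c("white", "parametric-ramp", "custom-radial-table"),
                       target_std = 10, ramp_cutoff = 0.35, radial_table = NULL,
                       nonstationary_gradient = 0, denoiser = NULL) {
  model <- match.arg(model)
  check_number(target_std, "target_std", lower = 0)
  check_number(ramp_cutoff, "ramp_cutoff", lower = .Machine$double.eps)
  check_number(nonstationary_gradient, "nonstationary_gradient", lower = 0)
  if (model == "custom-radial-table") {
    if (is.null(radial_table) || !all(c("freq", "value") %in% names(radial_table))) {
      stop_npwmf("'radial_table' with columns freq, value is required for the custom model")
    }
    if (any(radial_table$value < 0)) stop_npwmf("custom NPS values must be >= 0")
  }
  if (!is.null(denoiser)) {
    denoiser <- modifyList(list(kind = "edge_preserving", strength = 0.9,
                                smooth_sigma_px = 2.5, edge_hu_per_px = 4), denoiser)
    check_number(denoiser$strength, "denoiser$strength", lower = 0, upper = 1)
  }
  structure(list(model = model, target_std = target_std, ramp_cutoff = ramp_cutoff,
                 radial_table = radial_table,
                 nonstationary_gradient = nonstationary_gradient,
                 denoiser = denoiser),
            class = "noise_spec")
}

# separable "same" Gaussian convolution with zero padding, via banded matrices
blur_gaussian <- function(img, sigma_px) {
  if (sigma_px <= 0) return(img)
  half <- max(1L, ceiling(6 * sigma_px))
  k <- dnorm(seq(-half, half), sd = sigma_px)
  k <- k / sum(k)
  band <- function(n) {
    m <- matrix(0, n, n)
    for (j in seq(-half, half)) {
      idx <- seq_len(n)
      ok <- idx + j >= 1L & idx + j <= n
      m[cbind(idx[ok], (idx + j)[ok])] <- k[j + half + 1L]
    }
    m
  }
  br <- band(nrow(img))
  bc <- if (ncol(img) == nrow(img)) br else band(ncol(img))
  br %*% img %*% t(bc)
}

#' Render the noiseless phantom image
#'
#' Disks are rendered by pixel-centre-in-circle membership on a 4x
#' supersampled grid (subpixel anti-aliasing, so 1-2 mm features are not
#' biased by quantization), blurred by the Gaussian PSF at supersampled
#' resolution, then block-averaged back to the acquisition grid. The blur
#' conserves the integrated signal of each disk.
#'
#' @param spec a [phantom_spec()].
#' @param supersample integer supersampling factor (default 4).
#' @return rows x cols numeric matrix in HU.
#' @export
disk_image <- function(spec, supersample = 4L) {
  stopifnot(inherits(spec, "phantom_spec"))
  ss <- as.integer(supersample)
  nr <- spec$grid_shape[1]; nc <- spec$grid_shape[2]
  d <- spec$pixel_size / ss
  # subpixel centres: pixel i covers physical [i*px - px/2, i*px + px/2]
  ys <- (seq_len(nr * ss) - 1) * d - spec$pixel_size / 2 + d / 2
  xs <- (seq_len(nc * ss) - 1) * d - spec$pixel_size / 2 + d / 2
  img <- matrix(0, nr * ss, nc * ss)
  for (f in spec$features) {
    dy2 <- (ys - f$center_y_mm)^2
    dx2 <- (xs - f$center_x_mm)^2
    inside <- outer(dy2, dx2, "+") <= (f$diameter_mm / 2)^2
    img <- img + f$contrast_hu * inside
  }
  if (spec$psf_sigma > 0) img <- blur_gaussian(img, spec$psf_sigma / d)
  # block-average ss x ss subpixels down to the acquisition grid
  ri <- rep(seq_len(nr), each = ss)
  ci <- rep(seq_len(nc), each = ss)
  tmp <- rowsum(img, ri) / ss
  down <- t(rowsum(t(tmp), ci) / ss)
  dimnames(down) <- NULL
  down + spec$background_level
}

nps_filter_amplitude <- function(noise, rho) {
  switch(noise$model,
    "white" = rep(1, length(rho)),
    "parametric-ramp" = rho * exp(-(rho / noise$ramp_cutoff)^2),
    "custom-radial-table" = {
      v <- approx(noise$radial_table$freq, noise$radial_table$value,
                  xout = rho, rule = 2)$y
      sqrt(pmax(v, 0))
    })
}

#' Synthesize one correlated Gaussian noise field
#'
#' Colors white Gaussian noise in the frequency domain: the DFT of a unit
#' white field is multiplied by a real radial filter `|H(rho)|` (Hermitian
#' symmetric by construction, so the field is real), inverse-transformed, and
#' scaled so the stationary pixel standard deviation equals `target_std`.
#' With the gradient at 0 and no denoiser the field is jointly Gaussian and
#' stationary by construction.
#'
#' @param noise a [noise_spec()]. The denoiser, being signal-dependent, is
#'   not applied here; see [simulate_ensemble()].
#' @param shape c(rows, cols), each >= 16.
#' @param pixel_size pixel spacing in mm.
#' @param seed integer seed; the same seed reproduces the field bit for bit.
#' @return rows x cols numeric matrix, zero mean, in HU.
#' @export
synth_noise_field <- function(noise, shape, pixel_size, seed) {
  stopifnot(inherits(noise, "noise_spec"))
  if (length(shape) != 2L || any(shape < 16)) stop_npwmf("'shape' must be at least 16 x 16")
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  check_number(seed, "seed")
  if (noise$target_std == 0) return(matrix(0, shape[1], shape[2]))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  w <- matrix(rnorm(prod(shape)), shape[1], shape[2])
  if (noise$model != "white") {
    fy <- fft_freq(shape[1], pixel_size)
    fx <- fft_freq(shape[2], pixel_size)
    rho <- sqrt(outer(fy^2, fx^2, "+"))
    h <- matrix(nps_filter_amplitude(noise, as.vector(rho)), shape[1], shape[2])
    rms <- sqrt(mean(h^2))
    if (rms == 0) stop_npwmf("noise filter is identically zero")
    h <- h / rms  # mean(h^2) = 1, so the colored field keeps unit variance
    w <- Re(fft(fft(w) * h, inverse = TRUE)) / prod(shape)
  }
  field <- noise$target_std * w
  g <- noise$nonstationary_gradient
  if (g != 0) {
    ramp <- 1 + g * ((seq_len(shape[2]) - 1) / (shape[2] - 1) - 0.5)
    field <- sweep(field, 2, ramp, "*")
  }
  field
}

# DFT frequencies in 1/mm for an n-point axis with spacing delta
fft_freq <- function(n, delta) {
  k <- c(seq(0, floor((n - 1) / 2)), seq(-floor(n / 2), -1))
  k / (n * delta)
}

#' Edge-preserving denoiser surrogate
#'
#' A generic nonlinearity that suppresses noise in flat regions while
#' preserving edges: the image is mixed with a Gaussian-smoothed copy using a
#' weight that decays with local gradient magnitude (measured on the smoothed
#' copy). It emulates the qualitative behaviour of iterative / deep-learning
#' CT reconstruction denoising -- no specific vendor algorithm is modelled --
#' and is the fixture with which the divergence between Fourier- and
#' spatial-domain observer estimates is demonstrated.
#'
#' @param img numeric matrix in HU.
#' @param denoiser list with `strength` in 0..1 (mixing weight in flat
#'   regions), `smooth_sigma_px` (Gaussian sigma of the smoothed copy, px),
#'   `edge_hu_per_px` (gradient scale above which structure is preserved).
#' @return denoised matrix, same shape.
#' @export
apply_denoiser <- function(img, denoiser) {
  s <- denoiser$strength
  if (is.null(s) || s <= 0) return(img)
  sm <- blur_gaussian(img, denoiser$smooth_sigma_px)
  gy <- sm; gx <- sm
  nr <- nrow(sm); nc <- ncol(sm)
  gy[2:(nr - 1), ] <- (sm[3:nr, ] - sm[1:(nr - 2), ]) / 2
  gy[c(1, nr), ] <- 0
  gx[, 2:(nc - 1)] <- (sm[, 3:nc] - sm[, 1:(nc - 2)]) / 2
  gx[, c(1, nc)] <- 0
  grad <- sqrt(gy^2 + gx^2)
  w <- s * exp(-(grad / denoiser$edge_hu_per_px)^2)
  w * sm + (1 - w) * img
}

#' Simulate an ensemble of repeat scans
#'
#' Each repeat x slice image is the noiseless phantom rendering plus an
#' independent noise field (optionally passed through the denoiser
#' surrogate). One master seed drives everything; per-image streams are
#' derived deterministically, so ensembles are bit-identical across reruns.
#'
#' @param spec a [phantom_spec()].
#' @param noise a [noise_spec()].
#' @param n_repeats number of repeat scans (>= 1).
#' @param m_slices number of slices per scan (>= 1).
#' @param seed master seed.
#' @return an object of class `image_ensemble` with elements `pixels`
#'   (n_repeats x m_slices x rows x cols array, HU), `pixel_size`,
#'   `n_repeats`, `m_slices`, and `provenance`.
#' @export
simulate_ensemble <- function(spec, noise, n_repeats, m_slices = 1L, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"), inherits(noise, "noise_spec"))
  check_number(n_repeats, "n_repeats", lower = 1)
  check_number(m_slices, "m_slices", lower = 1)
  n_repeats <- as.integer(n_repeats); m_slices <- as.integer(m_slices)
  clean <- disk_image(spec)
  seeds <- derive_seeds(seed, n_repeats * m_slices)
  px <- array(NA_real_, c(n_repeats, m_slices, spec$grid_shape[1], spec$grid_shape[2]))
  k <- 0L
  for (r in seq_len(n_repeats)) {
    for (s in seq_len(m_slices)) {
      k <- k + 1L
      img <- clean + synth_noise_field(noise, spec$grid_shape, spec$pixel_size, seeds[k])
      if (!is.null(noise$denoiser)) img <- apply_denoiser(img, noise$denoiser)
      px[r, s, , ] <- img
    }
  }
  image_ensemble(px, spec$pixel_size,
                 provenance = list(seed = seed, model = noise$model,
                                   target_std = noise$target_std,
                                   denoised = !is.null(noise$denoiser)))
}

#' Construct an image ensemble container
#'
#' @param pixels n_repeats x m_slices x rows x cols array of HU values, or a
#'   rows x cols matrix (promoted to a 1 x 1 ensemble).
#' @param pixel_size pixel spacing in mm.
#' @param provenance free-form list recording how the ensemble was made.
#' @return an object of class `image_ensemble`.
#' @export
image_ensemble <- function(pixels, pixel_size, provenance = list()) {
  if (is.matrix(pixels)) pixels <- array(pixels, c(1L, 1L, dim(pixels)))
  if (length(dim(pixels)) != 4L) {
    stop_npwmf("'pixels' must be an n_repeats x m_slices x rows x cols array")
  }
  if (any(!is.finite(pixels))) stop_npwmf("ensemble contains non-finite pixel values")
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  structure(list(pixels = pixels, pixel_size = pixel_size,
                 n_repeats = dim(pixels)[1], m_slices = dim(pixels)[2],
                 grid_shape = dim(pixels)[3:4], provenance = provenance),
            class = "image_ensemble")
}

#' @export
print.image_ensemble <- function(x, ...) {
  cat(sprintf("CT image ensemble: %d repeats x %d slices of %d x %d px (%.4g mm/px)\n",
              x$n_repeats, x$m_slices, x$grid_shape[1], x$grid_shape[2], x$pixel_size))
  invisible(x)
}

# across-repeat mean image for one slice (rows x cols)
slice_mean <- function(ensemble, slice) {
  apply(ensemble$pixels[, slice, , , drop = FALSE], c(3, 4), mean)
}

# grand mean over repeats and slices
ensemble_mean <- function(ensemble) {
  apply(ensemble$pixels, c(3, 4), mean)
}

#' Write / read an ensemble as multi-page TIFF plus sidecar metadata
#'
#' Pixels are stored as 32-bit float TIFF pages ordered repeat-major
#' (repeat 1 slices 1..m, then repeat 2, ...). A plain-text sidecar
#' (`<stem>.meta`) records `pixel_size_mm`, `n_repeats`, `m_slices`, and
#' `seed`. DICOM input is not read directly; convert series to TIFF/HU first.
#'
#' @param ensemble an `image_ensemble`.
#' @param path TIFF file path; the sidecar is written next to it.
#' @return `write_ensemble`: the path, invisibly. `read_ensemble`: an
#'   `image_ensemble`.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "image_ensemble"))
  # TIFF pages must lie in [0, 1]: store normalized values, HU range in the sidecar
  lo <- min(ensemble$pixels); hi <- max(ensemble$pixels)
  span <- if (hi > lo) hi - lo else 1
  pages <- list()
  k <- 0L
  for (r in seq_len(ensemble$n_repeats)) for (s in seq_len(ensemble$m_slices)) {
    k <- k + 1L
    pages[[k]] <- (ensemble$pixels[r, s, , ] - lo) / span
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 32L, reduce = FALSE)
  meta <- c(sprintf("pixel_size_mm=%.10g", ensemble$pixel_size),
            sprintf("n_repeats=%d", ensemble$n_repeats),
            sprintf("m_slices=%d", ensemble$m_slices),
            sprintf("hu_min=%.10g", lo), sprintf("hu_span=%.10g", span),
            sprintf("seed=%s", if (is.null(ensemble$provenance$seed)) "NA" else ensemble$provenance$seed))
  writeLines(meta, paste0(tools::file_path_sans_ext(path), ".meta"))
  invisible(path)
}

#' @rdname write_ensemble
#' @param path TIFF file path written by [write_ensemble()].
#' @export
read_ensemble <- function(path) {
  metafile <- paste0(tools::file_path_sans_ext(path), ".meta")
  if (!file.exists(metafile)) stop_npwmf("sidecar metadata file not found: ", metafile)
  kv <- strsplit(readLines(metafile), "=", fixed = TRUE)
  meta <- stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  n <- as.integer(meta[["n_repeats"]]); m <- as.integer(meta[["m_slices"]])
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n * m) stop_npwmf("TIFF page count does not match sidecar n_repeats * m_slices")
  lo <- as.numeric(meta[["hu_min"]] %||% 0)
  span <- as.numeric(meta[["hu_span"]] %||% 1)
  dims <- dim(pages[[1]])
  px <- array(NA_real_, c(n, m, dims[1], dims[2]))
  k <- 0L
  for (r in seq_len(n)) for (s in seq_len(m)) {
    k <- k + 1L
    px[r, s, , ] <- pages[[k]] * span + lo
  }
  seed <- suppressWarnings(as.numeric(meta[["seed"]]))
  image_ensemble(px, as.numeric(meta[["pixel_size_mm"]]),
                 provenance = list(seed = if (is.na(seed)) NULL else seed, source = path))
}

#' Read a feature layout table
#'
#' @param path CSV file with columns `center_x_mm`, `center_y_mm`,
#'   `diameter_mm`, `contrast_hu`.
#' @return data.frame of features.
#' @export
read_layout <- function(path) {
  lay <- read.csv(path)
  need <- c("center_x_mm", "center_y_mm", "diameter_mm", "contrast_hu")
  if (!all(need %in% names(lay))) {
    stop_npwmf("layout must have columns: ", paste(need, collapse = ", "))
  }
  lay
}

layout_to_features <- function(layout) {
  lapply(seq_len(nrow(layout)), function(i)
    disk_feature(layout$center_x_mm[i], layout$center_y_mm[i],
                 layout$diameter_mm[i], layout$contrast_hu[i]))
}
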