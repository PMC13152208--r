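#' ROI placement parameters
#'
#' The feature-present ROI is the physical feature radius (in pixels,
#' unrounded) expanded by `n_exp` pixels; a gap of `n_gap` pixels separates
#' it from a background annulus `n_ann` pixels wide used to estimate the
#' local background level. The defaults (4, 4, 4) are the values used for an
#' in-house iodine-insert phantom at 0.469 mm pixels; `preset = "catphan"`
#' selects (3, 3, 3), used for the Catphan CTP515 module where features sit
#' closer together.
#'
#' @param n_exp,n_ann,n_gap non-negative pixel counts.
#' @param preset optional named preset, `"inhouse"` (default) or `"catphan"`.
#' @return list with class `roi_params`.
#' @export
roi_params <- function(n_exp = 4, n_ann = 4, n_gap = 4, preset = NULL) {
  if (!is.null(preset)) {
    preset <- match.arg(preset, c("inhouse", "catphan"))
    if (preset == "catphan") { n_exp <- 3; n_ann <- 3; n_gap <- 3 }
    else { n_exp <- 4; n_ann <- 4; n_gap <- 4 }
  }
  check_number(n_exp, "n_exp", lower = 0)
  check_number(n_ann, "n_ann", lower = 0)
  check_number(n_gap, "n_gap", lower = 0)
  structure(list(n_exp = n_exp, n_ann = n_ann, n_gap = n_gap), class = "roi_params")
}

#' Boolean circular mask on a pixel grid
#'
#' A pixel belongs to the mask iff its centre lies within Euclidean distance
#' `radius` of `center`. Coordinates are 0-based `(row, col)` with pixel
#' centres at integer coordinates.
#'
#' @param center numeric c(row, col), 0-based, possibly fractional.
#' @param radius radius in pixels, >= 0.
#' @param grid_shape c(rows, cols).
#' @return logical rows x cols matrix; errors if the mask is empty.
#' @export
circle_mask <- function(center, radius, grid_shape) {
  check_number(radius, "radius", lower = 0)
  rows <- seq_len(grid_shape[1]) - 1
  cols <- seq_len(grid_shape[2]) - 1
  m <- outer((rows - center[1])^2, (cols - center[2])^2, "+") <= radius^2 + 1e-12
  if (!any(m)) stop_npwmf("circle mask is empty (radius too small or centre outside grid)")
  m
}

#' Place feature-present, feature-absent and annulus ROIs
#'
#' For each feature in `layout`, the feature ROI is a circle of radius
#' `D/2/pixel_size + n_exp` pixels; the background annulus spans radii
#' `(r_roi + n_gap, r_roi + n_gap + n_ann]`. Annulus pixels overlapping any
#' neighbouring feature's ROI are excluded. The feature-absent ROI is an
#' exact copy of the present mask, either mirrored about the image vertical
#' midline (`absent_rule = "mirror"`) or translated by a user-supplied
#' per-feature offset in mm (`absent_rule` a list of c(dx_mm, dy_mm)), which
#' guarantees identical pixel counts in the two classes.
#'
#' @param layout data.frame with columns center_x_mm, center_y_mm,
#'   diameter_mm, contrast_hu (see [read_layout()]).
#' @param params a [roi_params()].
#' @param grid_shape c(rows, cols) of the images.
#' @param pixel_size pixel spacing in mm.
#' @param absent_rule `"mirror"` or a list of c(dx_mm, dy_mm) offsets, one
#'   per feature.
#' @return list of `roi_geometry` objects, one per feature, each holding
#'   index vectors `present_idx`, `absent_idx`, `annulus_idx`,
#'   `absent_annulus_idx`, the set of excluded annulus pixels, and the
#'   feature description.
#' @export
place_rois <- function(layout, params = roi_params(), grid_shape, pixel_size,
                       absent_rule = "mirror") {
  stopifnot(inherits(params, "roi_params"))
  check_number(pixel_size, "pixel_size", lower = .Machine$double.eps)
  nf <- nrow(layout)
  offsets <- NULL
  if (!identical(absent_rule, "mirror")) {
    if (!is.list(absent_rule) || length(absent_rule) != nf) {
      stop_npwmf("'absent_rule' must be \"mirror\" or a list of c(dx_mm, dy_mm), one per feature")
    }
    offsets <- absent_rule
  }
  centers <- cbind(layout$center_y_mm / pixel_size, layout$center_x_mm / pixel_size)
  r_roi <- layout$diameter_mm / 2 / pixel_size + params$n_exp  # unrounded physical radius + expansion
  roi_masks <- lapply(seq_len(nf), function(i)
    circle_mask(centers[i, ], r_roi[i], grid_shape))
  all_roi <- Reduce(`|`, roi_masks)

  shift_mask <- function(mask, drow, dcol) {
    out <- matrix(FALSE, nrow(mask), ncol(mask))
    src <- which(mask, arr.ind = TRUE)
    dst <- cbind(src[, 1] + drow, src[, 2] + dcol)
    if (any(dst[, 1] < 1 | dst[, 1] > nrow(mask) | dst[, 2] < 1 | dst[, 2] > ncol(mask))) {
      stop_npwmf("feature-absent ROI falls outside the image grid")
    }
    out[dst] <- TRUE
    out
  }

  lapply(seq_len(nf), function(i) {
    pres <- roi_masks[[i]]
    r_in <- r_roi[i] + params$n_gap
    r_out <- r_in + params$n_ann
    ann <- circle_mask(centers[i, ], r_out, grid_shape) &
      !circle_mask(centers[i, ], r_in, grid_shape)
    others <- if (nf > 1) Reduce(`|`, roi_masks[-i]) else matrix(FALSE, grid_shape[1], grid_shape[2])
    excl <- ann & others
    ann_keep <- ann & !others
    if (!any(ann_keep)) stop_npwmf(sprintf(
      "background annulus of feature %d is fully excluded by neighbouring ROIs", i))
    if (is.null(offsets)) {
      # exact mirror about the vertical midline: flip the mask's columns
      abs_mask <- pres[, rev(seq_len(grid_shape[2])), drop = FALSE]
      abs_ann <- ann_keep[, rev(seq_len(grid_shape[2])), drop = FALSE]
      abs_center <- c(centers[i, 1], (grid_shape[2] - 1) - centers[i, 2])
    } else {
      drow <- round(offsets[[i]][2] / pixel_size)
      dcol <- round(offsets[[i]][1] / pixel_size)
      abs_mask <- shift_mask(pres, drow, dcol)
      abs_ann <- shift_mask(ann_keep, drow, dcol)
      abs_center <- centers[i, ] + c(drow, dcol)
    }
    if (any(abs_mask & all_roi)) stop_npwmf(sprintf(
      "feature-absent ROI of feature %d overlaps a feature ROI; supply explicit offsets", i))
    abs_ann <- abs_ann & !all_roi
    structure(list(
      feature = layout[i, , drop = FALSE],
      feature_center = centers[i, ],
      feature_radius_px = r_roi[i],
      gap_px = params$n_gap, annulus_px = params$n_ann,
      absent_center = abs_center,
      present_idx = which(pres), absent_idx = which(abs_mask),
      annulus_idx = which(ann_keep), absent_annulus_idx = which(abs_ann),
      excluded_idx = which(excl),
      grid_shape = grid_shape, pixel_size = pixel_size
    ), class = "roi_geometry")
  })
}

#' @export
print.roi_geometry <- function(x, ...) {
  cat(sprintf(paste0(
    "ROI for %.3g mm / %.3g HU feature at (%.1f, %.1f) px:\n",
    "  present %d px (radius %.2f px), annulus %d px (%d excluded), absent at (%.1f, %.1f) px\n"),
    x$feature$diameter_mm, x$feature$contrast_hu,
    x$feature_center[2], x$feature_center[1],
    length(x$present_idx), x$feature_radius_px,
    length(x$annulus_idx), length(x$excluded_idx),
    x$absent_center[2], x$absent_center[1]))
  invisible(x)
}

#' Extract background-corrected ROI sample matrices
#'
#' For each repeat x slice, the feature-present and feature-absent pixel
#' vectors are extracted and the local background level -- the annulus mean
#' averaged over all repeat scans, computed per slice position -- is
#' subtracted. Observation order is repeat-major (repeat 1 slices 1..m,
#' repeat 2 slices 1..m, ...).
#'
#' @param ensemble an `image_ensemble`.
#' @param geom a `roi_geometry` from [place_rois()].
#' @return object of class `roi_samples` with matrices `present` and
#'   `absent` (n*m observations x p pixels, HU, background-subtracted) and a
#'   `slice_index` label per observation.
#' @export
extract_samples <- function(ensemble, geom) {
  stopifnot(inherits(ensemble, "image_ensemble"), inherits(geom, "roi_geometry"))
  if (!all(geom$grid_shape == ensemble$grid_shape)) {
    stop_npwmf("ROI geometry grid does not match the ensemble grid")
  }
  n <- ensemble$n_repeats; m <- ensemble$m_slices
  p <- length(geom$present_idx)
  present <- matrix(NA_real_, n * m, p)
  absent <- matrix(NA_real_, n * m, p)
  slice_index <- integer(n * m)
  # per-slice background: annulus mean of the across-repeat mean image
  bg_p <- bg_a <- numeric(m)
  for (s in seq_len(m)) {
    msl <- slice_mean(ensemble, s)
    if (any(!is.finite(msl))) stop_npwmf("non-finite pixels in slice ", s)
    bg_p[s] <- mean(msl[geom$annulus_idx])
    bg_a[s] <- mean(msl[geom$absent_annulus_idx])
  }
  k <- 0L
  for (r in seq_len(n)) for (s in seq_len(m)) {
    k <- k + 1L
    img <- ensemble$pixels[r, s, , ]
    present[k, ] <- img[geom$present_idx] - bg_p[s]
    absent[k, ] <- img[geom$absent_idx] - bg_a[s]
    slice_index[k] <- s
  }
  structure(list(present = present, absent = absent, slice_index = slice_index,
                 n_repeats = n, m_slices = m, geometry = geom),
            class = "roi_samples")
}

#' @export
print.roi_samples <- function(x, ...) {
  cat(sprintf("ROI samples: %d observations x %d pixels per class (%d repeats x %d slices)\n",
              nrow(x$present), ncol(x$present), x$n_repeats, x$m_slices))
  invisible(x)
}
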