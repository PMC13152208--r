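#' Fit NPWMF model observers to an image ensemble
#'
#' Runs up to three estimates of the nonprewhitening matched filter
#' observer for every feature of a phantom layout:
#' \describe{
#'   \item{`fourier`}{method 1 -- the detectability integral over the
#'     estimated NPS and TTF with the analytic disk task spectrum, assuming
#'     quasi-stationary noise and Gaussian responses;}
#'   \item{`spatial_gaussian`}{method 2 -- d-prime from ROI decision
#'     variables, mapped to AUC assuming Gaussian responses, with the
#'     analytic d-prime uncertainty interval;}
#'   \item{`spatial_general`}{method 3 -- the nonparametric pairwise AUC of
#'     the decision variables with Gaussian internal noise, assuming neither
#'     stationarity nor Gaussian responses, with a per-slice
#'     standard-error-of-the-mean interval.}
#' }
#' Methods whose prerequisites fail (e.g. degenerate variance at zero noise,
#' a single slice for method 3) are skipped with a warning and an `NA` row.
#'
#' @param ensemble an `image_ensemble`.
#' @param layout feature table (data.frame or CSV path, see [read_layout()]).
#' @param params a [roi_params()].
#' @param methods subset of `c("fourier", "spatial_gaussian",
#'   "spatial_general")`.
#' @param beta internal-noise parameter (default 3.0, calibrated against
#'   human 4-AFC readings).
#' @param template `"difference"` (empirical mean present - mean absent),
#'   `"present"` (empirical mean of background-subtracted present ROIs), or
#'   `"analytic"` (the known blurred profile; requires `spec`).
#' @param spec optional [phantom_spec()], required for the analytic template.
#' @param absent_rule passed to [place_rois()].
#' @param nps_roi_size NPS ROI side in pixels (default 64, reduced
#'   automatically for small grids).
#' @param ttf_feature index of the layout row used for the shared TTF when a
#'   feature is too small or too faint for edge analysis (default: the
#'   feature with the largest |contrast| * diameter).
#' @param bootstrap_B bootstrap resamples for the Fourier CI (0 = no CI).
#' @param level confidence level for all intervals.
#' @param seed seed for the bootstrap.
#' @return object of class `npwmf`: list with `outcomes` (one row per
#'   feature x method), `nps`, `ttf`, `decisions`, `templates`, and the call
#'   metadata.
#' @export
npwmf <- function(ensemble, layout, params = roi_params(),
                  methods = c("fourier", "spatial_gaussian", "spatial_general"),
                  beta = 3, template = c("difference", "present", "analytic"),
                  spec = NULL, absent_rule = "mirror", nps_roi_size = 64,
                  ttf_feature = NULL, bootstrap_B = 0, level = 0.95, seed = 1L) {
  stopifnot(inherits(ensemble, "image_ensemble"))
  if (is.character(layout)) layout <- read_layout(layout)
  methods <- match.arg(methods, several.ok = TRUE)
  template <- match.arg(template)
  check_number(beta, "beta", lower = 0)
  if (template == "analytic" && is.null(spec)) {
    stop_npwmf("the analytic template needs the phantom_spec ('spec' argument)")
  }
  geoms <- place_rois(layout, params, ensemble$grid_shape, ensemble$pixel_size,
                      absent_rule)
  nf <- nrow(layout)
  n <- ensemble$n_repeats; m <- ensemble$m_slices

  feature_mask <- matrix(FALSE, ensemble$grid_shape[1], ensemble$grid_shape[2])
  for (g in geoms) feature_mask[g$present_idx] <- TRUE

  out <- list(); dec <- vector("list", nf); tmpl <- vector("list", nf)
  nps <- NULL; ttf <- vector("list", nf)
  add_row <- function(method, i, d_prime = NA, u = NA, auc = NA,
                      ci_low = NA, ci_high = NA, note = "") {
    data.frame(method = method, feature = i,
               diameter_mm = layout$diameter_mm[i],
               contrast_hu = layout$contrast_hu[i],
               d_prime = d_prime, u_percent = u, auc = auc,
               ci_low = ci_low, ci_high = ci_high,
               beta = beta, n_repeats = n, m_slices = m, note = note,
               stringsAsFactors = FALSE)
  }

  if ("fourier" %in% methods) {
    nps_roi_size <- min(nps_roi_size, 2^floor(log2(min(ensemble$grid_shape) / 2)))
    nps <- tryCatch(estimate_nps(ensemble, nps_roi_size, exclude = feature_mask),
                    error = function(e) {
                      warning("fourier method skipped: ", conditionMessage(e), call. = FALSE)
                      NULL
                    })
    if (is.null(ttf_feature)) {
      ttf_feature <- which.max(abs(layout$contrast_hu) * layout$diameter_mm)
    }
    shared_ttf <- NULL
    if (!is.null(nps)) {
      shared_ttf <- tryCatch(
        estimate_ttf(ensemble, layout_to_features(layout)[[ttf_feature]]),
        error = function(e) {
          warning("shared TTF unavailable: ", conditionMessage(e), call. = FALSE)
          NULL
        })
    }
    for (i in seq_len(nf)) {
      feat <- layout_to_features(layout)[[i]]
      row <- tryCatch({
        if (is.null(nps)) stop_npwmf("NPS unavailable")
        t_i <- tryCatch(estimate_ttf(ensemble, feat), error = function(e) shared_ttf)
        ttf[[i]] <- t_i
        if (is.null(t_i)) stop_npwmf("no usable TTF")
        task <- disk_spectrum(feat)
        d <- dprime_fourier(nps, t_i, task)
        auc <- auc_from_dprime(d, beta)
        lo <- hi <- NA_real_
        if (bootstrap_B > 0 && m >= 2 && n >= 3) {
          tr <- ttf_replicates(ensemble, layout_to_features(layout)[[ttf_feature]])
          nr <- nps_replicates(ensemble, nps_roi_size, exclude = feature_mask)
          bs <- bootstrap_ci_fourier(tr, nr, task, beta, B = bootstrap_B,
                                     level = level, seed = seed)
          lo <- bs$ci_low; hi <- bs$ci_high
        }
        add_row("fourier", i, d_prime = d, auc = auc, ci_low = lo, ci_high = hi)
      }, error = function(e) {
        warning(sprintf("fourier method, feature %d: %s", i, conditionMessage(e)),
                call. = FALSE)
        add_row("fourier", i, note = conditionMessage(e))
      })
      out[[length(out) + 1L]] <- row
    }
  }

  if (any(c("spatial_gaussian", "spatial_general") %in% methods)) {
    z <- qnorm((1 + level) / 2)
    for (i in seq_len(nf)) {
      smp <- extract_samples(ensemble, geoms[[i]])
      tm <- tryCatch({
        if (template == "analytic") analytic_template(spec, geoms[[i]])
        else estimate_template(smp, source = if (template == "present") "present" else "difference")
      }, error = function(e) NULL)
      tmpl[[i]] <- tm
      ds <- if (is.null(tm)) NULL else
        tryCatch(decision_variables(smp, tm), error = function(e) NULL)
      dec[[i]] <- ds
      if ("spatial_gaussian" %in% methods) {
        row <- tryCatch({
          if (is.null(ds)) stop_npwmf("no decision variables")
          d <- as.numeric(dprime_spatial(ds))
          u <- dprime_rel_uncertainty(d, n, m)
          auc <- auc_from_dprime(d, beta)
          lo <- auc_from_dprime(d * (1 - z * u / 100), beta)
          hi <- auc_from_dprime(d * (1 + z * u / 100), beta)
          add_row("spatial_gaussian", i, d_prime = d, u = u, auc = auc,
                  ci_low = lo, ci_high = hi)
        }, error = function(e) {
          warning(sprintf("spatial_gaussian, feature %d: %s", i, conditionMessage(e)),
                  call. = FALSE)
          add_row("spatial_gaussian", i, note = conditionMessage(e))
        })
        out[[length(out) + 1L]] <- row
      }
      if ("spatial_general" %in% methods) {
        row <- tryCatch({
          if (is.null(ds)) stop_npwmf("no decision variables")
          sigma <- if (beta > 0) internal_noise_sigma(ds, beta) else 0
          m3 <- auc_sem_method3(ds, sigma, level)
          add_row("spatial_general", i, auc = m3$auc,
                  ci_low = m3$ci_low, ci_high = m3$ci_high)
        }, error = function(e) {
          warning(sprintf("spatial_general, feature %d: %s", i, conditionMessage(e)),
                  call. = FALSE)
          add_row("spatial_general", i, note = conditionMessage(e))
        })
        out[[length(out) + 1L]] <- row
      }
    }
  }

  structure(list(outcomes = do.call(rbind, out), layout = layout,
                 nps = nps, ttf = ttf, decisions = dec, templates = tmpl,
                 geometry = geoms, beta = beta, template = template,
                 methods = methods, level = level,
                 n_repeats = n, m_slices = m, seed = seed),
            class = "npwmf")
}

#' @export
print.npwmf <- function(x, digits = 3, ...) {
  cat(sprintf("NPWMF model observer fit: %d feature(s), beta = %.2g, n = %d repeats x m = %d slices\n\n",
              nrow(x$layout), x$beta, x$n_repeats, x$m_slices))
  fmt <- function(row) {
    if (is.na(row$auc)) return("--")
    ci <- if (!is.na(row$ci_low)) sprintf(" (%.*f, %.*f)", digits, row$ci_low, digits, row$ci_high) else ""
    sprintf("%.*f%s", digits, row$auc, ci)
  }
  hdr <- c(fourier = "Fourier", spatial_gaussian = "Spatial, Gaussian",
           spatial_general = "Spatial, general")
  cols <- intersect(names(hdr), unique(x$outcomes$method))
  tab <- data.frame(feature = sprintf("D=%g mm, C=%g HU",
                                      x$layout$diameter_mm, x$layout$contrast_hu))
  for (mth in cols) {
    tab[[hdr[[mth]]]] <- vapply(seq_len(nrow(x$layout)), function(i) {
      row <- x$outcomes[x$outcomes$method == mth & x$outcomes$feature == i, ]
      if (nrow(row) == 0) "--" else fmt(row[1, ])
    }, "")
  }
  print(tab, row.names = FALSE, right = FALSE)
  invisible(x)
}

#' @export
summary.npwmf <- function(object, ...) {
  structure(list(outcomes = object$outcomes, beta = object$beta,
                 template = object$template, level = object$level),
            class = "summary.npwmf")
}

#' @export
print.summary.npwmf <- function(x, ...) {
  cat(sprintf("NPWMF observer outcomes (beta = %.2g, %s template, %.0f%% intervals):\n",
              x$beta, x$template, 100 * x$level))
  print(x$outcomes, row.names = FALSE, digits = 4)
  invisible(x)
}

#' @export
coef.npwmf <- function(object, ...) {
  mths <- unique(object$outcomes$method)
  out <- sapply(mths, function(mth) {
    vapply(seq_len(nrow(object$layout)), function(i) {
      row <- object$outcomes[object$outcomes$method == mth & object$outcomes$feature == i, ]
      if (nrow(row) == 0) NA_real_ else row$auc[1]
    }, 0)
  })
  out <- matrix(out, nrow = nrow(object$layout),
                dimnames = list(sprintf("D%gmm", object$layout$diameter_mm), mths))
  out
}

#' Predict Fourier-domain detectability for new disk features
#'
#' Uses the NPS and (shared) TTF estimated by the fit to evaluate the
#' detectability integral for arbitrary disk diameters and contrasts -- the
#' transferability that motivates the Fourier approach.
#'
#' @param object a fitted `npwmf` with a Fourier component.
#' @param newdata data.frame with columns `diameter_mm` and `contrast_hu`.
#' @param beta internal-noise parameter (defaults to the fit's).
#' @param ... unused.
#' @return data.frame with `d_prime` and `auc` per row of `newdata`.
#' @export
predict.npwmf <- function(object, newdata, beta = object$beta, ...) {
  if (is.null(object$nps)) stop_npwmf("fit has no NPS: refit with the fourier method")
  t_use <- Filter(Negate(is.null), object$ttf)
  if (length(t_use) == 0) stop_npwmf("fit has no TTF: refit with the fourier method")
  t_use <- t_use[[1]]
  res <- lapply(seq_len(nrow(newdata)), function(i) {
    feat <- disk_feature(0, 0, newdata$diameter_mm[i], newdata$contrast_hu[i])
    feat$center_x_mm <- feat$center_y_mm <- 0  # position-free task
    d <- dprime_fourier(object$nps, t_use, disk_spectrum(feat))
    data.frame(d_prime = d, auc = auc_from_dprime(d, beta))
  })
  cbind(newdata, do.call(rbind, res))
}

#' Plot fitted AUC by feature and method
#'
#' @param x a fitted `npwmf`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.npwmf <- function(x, ...) {
  oc <- x$outcomes[!is.na(x$outcomes$auc), ]
  if (nrow(oc) == 0) stop_npwmf("nothing to plot: all methods failed")
  mths <- unique(oc$method)
  pch <- seq_along(mths) + 14
  xv <- oc$diameter_mm + 0.06 * (match(oc$method, mths) - (length(mths) + 1) / 2)
  ylim <- range(c(oc$auc, oc$ci_low, oc$ci_high), na.rm = TRUE)
  plot(xv, oc$auc, pch = pch[match(oc$method, mths)],
       xlab = "feature diameter (mm)", ylab = "AUC", ylim = ylim, ...)
  has_ci <- !is.na(oc$ci_low)
  if (any(has_ci)) {
    arrows(xv[has_ci], oc$ci_low[has_ci], xv[has_ci], oc$ci_high[has_ci],
           angle = 90, code = 3, length = 0.03)
  }
  legend("bottomright", legend = mths, pch = pch, bty = "n")
  invisible(x)
}
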