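#' Estimate the matched-filter template from ROI samples
#'
#' The template is the expected signal-present minus signal-absent image
#' over the ROI. With `source = "difference"` it is the elementwise mean of
#' the present vectors minus the mean of the absent vectors. With
#' `source = "present"` it is the mean of the background-subtracted present
#' vectors alone, using the fact that the absent-class expectation is zero
#' after background subtraction; this halves the noise in the template and
#' is the estimation route assumed by the analytic d-prime uncertainty
#' formula (see [dprime_rel_uncertainty()]).
#'
#' @param samples a `roi_samples` object.
#' @param source `"difference"` (default) or `"present"`.
#' @return object of class `npwmf_template` with the length-p `values`
#'   vector (HU) and its provenance. A warning flags a degenerate (all but
#'   zero) template.
#' @export
estimate_template <- function(samples, source = c("difference", "present")) {
  stopifnot(inherits(samples, "roi_samples"))
  source <- match.arg(source)
  if (nrow(samples$present) < 2L || nrow(samples$absent) < 2L) {
    stop_npwmf("need at least 2 observations per class to estimate a template")
  }
  if (ncol(samples$present) != ncol(samples$absent)) {
    stop_npwmf("present/absent sample matrices have different pixel counts")
  }
  v <- if (source == "difference") {
    colMeans(samples$present) - colMeans(samples$absent)
  } else {
    colMeans(samples$present)
  }
  if (any(!is.finite(v))) stop_npwmf("template contains non-finite values")
  degenerate <- sqrt(mean(v^2)) < 1e-12
  if (degenerate) warning("template is degenerate (identically zero)", call. = FALSE)
  structure(list(values = v, source = paste0("empirical-", source),
                 degenerate = degenerate),
            class = "npwmf_template")
}

#' Analytic template from a known noiseless scene
#'
#' When simulation ground truth is available, the template t * Delta-f (the
#' blurred disk profile over the ROI) can be formed directly from the
#' noiseless rendering, bypassing estimation noise entirely.
#'
#' @param spec a [phantom_spec()] (its background is subtracted).
#' @param geom a `roi_geometry`.
#' @return an `npwmf_template`.
#' @export
analytic_template <- function(spec, geom) {
  clean <- disk_image(spec) - spec$background_level
  structure(list(values = clean[geom$present_idx], source = "analytic",
                 degenerate = FALSE),
            class = "npwmf_template")
}

#' Compute NPWMF decision variables
#'
#' The decision variable of the nonprewhitening matched filter for an image
#' is the inner product of the template with the ROI pixel vector. It is
#' linear in the image: scaling all images by c scales every L by c.
#'
#' @param samples a `roi_samples`.
#' @param template an `npwmf_template` (length must equal the ROI pixel
#'   count).
#' @return object of class `decision_set` with `L_absent` (n1 values),
#'   `L_present` (n2 values) and the per-observation `slice_index`.
#' @export
decision_variables <- function(samples, template) {
  stopifnot(inherits(samples, "roi_samples"), inherits(template, "npwmf_template"))
  if (length(template$values) != ncol(samples$present)) {
    stop_npwmf("template length does not match the ROI pixel count")
  }
  L2 <- drop(samples$present %*% template$values)
  L1 <- drop(samples$absent %*% template$values)
  if (any(!is.finite(c(L1, L2)))) stop_npwmf("non-finite decision variables")
  decision_set(L1, L2, samples$slice_index)
}

#' Construct a decision set
#'
#' @param L_absent decision variables of the n1 signal-absent images.
#' @param L_present decision variables of the n2 signal-present images.
#' @param slice_index optional per-observation slice label (recycled to both
#'   classes; must match their common length when classes are paired).
#' @return object of class `decision_set`.
#' @export
decision_set <- function(L_absent, L_present, slice_index = NULL) {
  if (length(L_absent) < 1L || length(L_present) < 1L) {
    stop_npwmf("both classes must be non-empty")
  }
  if (any(!is.finite(c(L_absent, L_present)))) stop_npwmf("decision variables must be finite")
  structure(list(L_absent = as.numeric(L_absent), L_present = as.numeric(L_present),
                 slice_index = slice_index),
            class = "decision_set")
}

#' @export
print.decision_set <- function(x, ...) {
  cat(sprintf("Decision set: n1 = %d absent, n2 = %d present\n",
              length(x$L_absent), length(x$L_present)))
  invisible(x)
}

#' Detectability index from decision variables
#'
#' `d'^2 = (mean L_present - mean L_absent)^2 / (0.5 (var L_absent + var
#' L_present))` with unbiased (n-1) sample variances. The returned d-prime
#' is non-negative; the sign of the mean difference is kept in the
#' `"sign"` attribute.
#'
#' With `absent_mean = "zero"` the signal-absent expectation is taken as
#' known to be zero rather than estimated -- which it is, by construction,
#' for background-subtracted ROI vectors -- so the numerator is simply
#' `mean(L_present)`. This lower-variance variant is the estimation route
#' whose spread the analytic uncertainty formula
#' ([dprime_rel_uncertainty()]) describes; the default estimates both class
#' means from the data.
#'
#' @param decisions a `decision_set` with at least 2 observations per class.
#' @param absent_mean `"estimate"` (default) or `"zero"`.
#' @return single non-negative number with attribute `sign`.
#' @export
dprime_spatial <- function(decisions, absent_mean = c("estimate", "zero")) {
  stopifnot(inherits(decisions, "decision_set"))
  absent_mean <- match.arg(absent_mean)
  L1 <- decisions$L_absent; L2 <- decisions$L_present
  if (length(L1) < 2L || length(L2) < 2L) {
    stop_npwmf("need at least 2 observations per class")
  }
  pooled <- (var(L1) + var(L2)) / 2
  scale <- max(abs(c(L1, L2)))
  if (pooled <= (1e-10 * max(scale, 1))^2) {
    stop_npwmf("zero pooled variance: decision variables are degenerate")
  }
  diff <- mean(L2) - if (absent_mean == "zero") 0 else mean(L1)
  structure(abs(diff) / sqrt(pooled), sign = sign(diff))
}

#' Empirical AUC from decision variables
#'
#' Without internal noise this is the Mann-Whitney pairwise estimate of Pr(L2
#' > L1), with ties counted 1/2. With Gaussian internal noise of standard
#' deviation `sigma` added to the decision variable, the Heaviside kernel is
#' replaced by the normal CDF of the pairwise differences; the two forms
#' agree in the limit sigma -> 0.
#'
#' @param decisions a `decision_set`.
#' @param sigma internal-noise standard deviation in decision-variable
#'   units, >= 0 (default 0 = no internal noise).
#' @return AUC in `[0, 1]`.
#' @export
auc_empirical <- function(decisions, sigma = 0) {
  stopifnot(inherits(decisions, "decision_set"))
  check_number(sigma, "sigma", lower = 0)
  d <- outer(decisions$L_present, decisions$L_absent, "-")
  if (sigma == 0) {
    mean((d > 0) + 0.5 * (d == 0))
  } else {
    mean(pnorm(d / sigma))
  }
}

#' Internal-noise standard deviation from the efficiency parameter beta
#'
#' `sigma^2 = beta * (var L_absent + var L_present)`: with this choice the
#' internal-noise AUC of Gaussian decision variables equals the analytic
#' AUC `Phi(d' / sqrt(1 + beta) / sqrt(2))`.
#'
#' @param decisions a `decision_set` with non-degenerate variances.
#' @param beta dimensionless internal-noise parameter, >= 0.
#' @return sigma, in decision-variable units.
#' @export
internal_noise_sigma <- function(decisions, beta) {
  stopifnot(inherits(decisions, "decision_set"))
  check_number(beta, "beta", lower = 0)
  if (beta == 0) return(0)
  tot <- var(decisions$L_absent) + var(decisions$L_present)
  scale <- max(abs(c(decisions$L_absent, decisions$L_present)))
  if (!is.finite(tot) || tot <= (1e-10 * max(scale, 1))^2) {
    stop_npwmf("degenerate decision-variable variance; cannot set internal noise")
  }
  sqrt(beta * tot)
}
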