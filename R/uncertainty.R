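Z95 <- 1.959964  # two-sided 95% normal quantile used throughout

#' AUC from d-prime under Gaussian independent responses
#'
#' `AUC = Phi(d' / sqrt(1 + beta) / sqrt(2))`, where `beta` is the
#' internal-noise parameter degrading the ideal linear observer to human
#' efficiency. Strictly increasing in d-prime; for d-prime > 0, decreasing
#' in beta.
#'
#' @param d_prime detectability index.
#' @param beta internal-noise parameter, >= 0 (default 0).
#' @return AUC in (0, 1).
#' @export
auc_from_dprime <- function(d_prime, beta = 0) {
  check_number(beta, "beta", lower = 0)
  pnorm(d_prime / sqrt(1 + beta) / sqrt(2))
}

#' d-prime from AUC (exact inverse)
#'
#' @param auc AUC strictly inside (0, 1).
#' @param beta internal-noise parameter, >= 0.
#' @return d-prime such that [auc_from_dprime()] returns `auc`.
#' @export
dprime_from_auc <- function(auc, beta = 0) {
  check_number(auc, "auc")
  check_number(beta, "beta", lower = 0)
  if (auc <= 0 || auc >= 1) stop_npwmf("'auc' must lie strictly inside (0, 1)")
  qnorm(auc) * sqrt(1 + beta) * sqrt(2)
}

#' Analytic relative uncertainty of the ROI-based d-prime estimate
#'
#' One-standard-deviation percentage uncertainty of a d-prime estimated from
#' n repeat scans with m usable slices each, one feature-present and one
#' feature-absent ROI per slice and independent responses:
#' `u = 100 sqrt( 1/(nm) / d'^2 + 1/4 / ((n-1) m) )`.
#' As d-prime grows the first (template/mean) term vanishes and u tends to
#' `100 / sqrt(4 (n-1) m)`, the floor set by variance estimation.
#'
#' @param d_prime detectability index, > 0.
#' @param n_repeats number of repeat scans, >= 2.
#' @param m_slices number of slices per scan, >= 1.
#' @return u in percent.
#' @export
dprime_rel_uncertainty <- function(d_prime, n_repeats, m_slices) {
  check_number(d_prime, "d_prime", lower = .Machine$double.eps)
  check_number(n_repeats, "n_repeats", lower = 2)
  check_number(m_slices, "m_slices", lower = 1)
  100 * sqrt(1 / (n_repeats * m_slices) / d_prime^2 +
               0.25 / ((n_repeats - 1) * m_slices))
}

#' Analytic confidence interval for a Gaussian-response (method 2) AUC
#'
#' The AUC point estimate is inverted to d-prime, the analytic relative
#' uncertainty of d-prime is evaluated, a `level` confidence interval is
#' formed on the d-prime scale, and both endpoints are mapped back to the
#' AUC scale. (Propagating on the AUC scale by the delta method instead
#' agrees within typical printed rounding.)
#'
#' @param auc_point AUC point estimate strictly inside (0, 1).
#' @param beta internal-noise parameter used in the d-prime/AUC mapping.
#' @param n_repeats,m_slices ensemble dimensions for the uncertainty formula.
#' @param level confidence level (default 0.95).
#' @return named vector c(ci_low, ci_high) on the AUC scale.
#' @export
auc_ci_method2 <- function(auc_point, beta = 3, n_repeats, m_slices, level = 0.95) {
  check_number(level, "level", lower = 1e-6, upper = 1 - 1e-6)
  d <- dprime_from_auc(auc_point, beta)
  if (d <= 0) stop_npwmf("method-2 CI needs an AUC above 0.5 (positive d-prime)")
  u <- dprime_rel_uncertainty(d, n_repeats, m_slices) / 100
  z <- qnorm((1 + level) / 2)
  c(ci_low = auc_from_dprime(d - z * u * d, beta),
    ci_high = auc_from_dprime(d + z * u * d, beta))
}

#' Per-slice AUC with standard-error-of-the-mean uncertainty (method 3)
#'
#' The AUC is computed per slice position from the decision variables (with
#' the internal-noise kernel of [auc_empirical()]), the reported value is
#' the mean across slices, and its uncertainty is the standard error of
#' that mean. The CI is `mean +/- z * sem`, clipped to [0, 1].
#'
#' @param decisions a `decision_set` whose `slice_index` labels >= 2 slices.
#' @param sigma internal-noise standard deviation (see
#'   [internal_noise_sigma()]).
#' @param level confidence level (default 0.95).
#' @return list with `auc`, `sem`, `ci_low`, `ci_high`, `per_slice`.
#' @export
auc_sem_method3 <- function(decisions, sigma = 0, level = 0.95) {
  stopifnot(inherits(decisions, "decision_set"))
  si <- decisions$slice_index
  if (is.null(si)) stop_npwmf("decision set has no slice labels")
  slices <- sort(unique(si))
  if (length(slices) < 2L) {
    stop_npwmf("only one slice: use the analytic d-prime route (dprime_rel_uncertainty) instead")
  }
  n1 <- length(decisions$L_absent); n2 <- length(decisions$L_present)
  if (length(si) != n1 || n1 != n2) {
    stop_npwmf("per-slice AUC needs paired classes with one slice label per observation")
  }
  per <- vapply(slices, function(s) {
    ds <- decision_set(decisions$L_absent[si[seq_len(n1)] == s],
                       decisions$L_present[si[seq_len(n2)] == s])
    auc_empirical(ds, sigma)
  }, 0)
  m <- mean(per)
  sem <- sd(per) / sqrt(length(per))
  z <- qnorm((1 + level) / 2)
  list(auc = m, sem = sem,
       ci_low = max(0, m - z * sem), ci_high = min(1, m + z * sem),
       per_slice = per)
}

#' Percentile-bootstrap confidence interval for the Fourier AUC (method 1)
#'
#' Resamples the TTF slice replicates and the NPS repeat replicates with
#' replacement, recomputes the average curves, the Fourier-domain d-prime,
#' and the Gaussian-response AUC for each resample, and returns the
#' percentile interval. Deterministic for a fixed seed.
#'
#' @param ttf_replicates list with `freq` and a replicates x frequencies
#'   `values` matrix (see [ttf_replicates()]).
#' @param nps_replicates list with `freq` and a replicates x frequencies
#'   `values` matrix.
#' @param task a `disk_task_spectrum`.
#' @param beta internal-noise parameter for the AUC mapping.
#' @param B number of bootstrap resamples (default 1000; < 100 warns).
#' @param level confidence level (default 0.95).
#' @param seed integer seed.
#' @return list with `auc`, `ci_low`, `ci_high`, and the vector of
#'   bootstrap AUCs.
#' @export
bootstrap_ci_fourier <- function(ttf_replicates, nps_replicates, task, beta = 3,
                                 B = 1000L, level = 0.95, seed = 1L) {
  if (nrow(ttf_replicates$values) < 2L || nrow(nps_replicates$values) < 2L) {
    stop_npwmf("need at least 2 replicates of both TTF and NPS")
  }
  if (B < 100) warning("B < 100 bootstrap resamples: interval will be unstable", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  nt <- nrow(ttf_replicates$values); nn <- nrow(nps_replicates$values)
  one <- function(ti, ni) {
    tv <- colMeans(ttf_replicates$values[ti, , drop = FALSE])
    tv <- tv / tv[1]
    nv <- colMeans(nps_replicates$values[ni, , drop = FALSE])
    d <- dprime_fourier(nps_table(nps_replicates$freq, pmax(nv, 0)),
                        ttf_table(ttf_replicates$freq, tv), task)
    auc_from_dprime(d, beta)
  }
  point <- one(seq_len(nt), seq_len(nn))
  aucs <- vapply(seq_len(B), function(b)
    one(sample.int(nt, nt, replace = TRUE), sample.int(nn, nn, replace = TRUE)), 0)
  qs <- quantile(aucs, c((1 - level) / 2, (1 + level) / 2), names = FALSE)
  list(auc = point, ci_low = qs[1], ci_high = qs[2], boot = aucs)
}

# percent correct of an M-AFC task for a Gaussian observer at separation d':
# PC(d') = int phi(x - d') Phi(x)^(M-1) dx
mafc_pc <- function(d_prime, m_alternatives) {
  integrate(function(x) dnorm(x - d_prime) * pnorm(x)^(m_alternatives - 1),
            -Inf, Inf, rel.tol = 1e-10)$value
}

#' Convert M-AFC percent correct to AUC
#'
#' Solves the Gaussian-independent-responses forced-choice model
#' `PC(d') = int Phi(x)^(M-1) phi(x - d') dx` for d-prime by bracketed
#' root-finding (the integral is evaluated by adaptive quadrature), then
#' maps to `AUC = Phi(d'/sqrt(2))`. For M = 2 the identity AUC = PC holds
#' exactly. A PC at or below chance (1/M) yields d' <= 0 and an AUC <= 0.5
#' with a warning.
#'
#' @param pc proportion correct, strictly inside (0, 1).
#' @param m_alternatives number of alternatives M >= 2.
#' @return AUC.
#' @export
mafc_pc_to_auc <- function(pc, m_alternatives) {
  check_number(pc, "pc")
  check_number(m_alternatives, "m_alternatives", lower = 2)
  if (pc <= 0 || pc >= 1) stop_npwmf("'pc' must lie strictly inside (0, 1)")
  m_alternatives <- as.integer(m_alternatives)
  if (m_alternatives == 2L) return(pc)  # 2-AFC: PC equals AUC exactly
  if (pc <= 1 / m_alternatives) {
    warning(sprintf("pc = %.3f is at or below chance (1/%d): returning AUC <= 0.5",
                    pc, m_alternatives), call. = FALSE)
  }
  f <- function(d) mafc_pc(d, m_alternatives) - pc
  lo <- -10; hi <- 10
  d <- uniroot(f, c(lo, hi), tol = 1e-9)$root
  pnorm(d / sqrt(2))
}
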