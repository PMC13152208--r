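test_that("template estimation is the ensemble mean difference", {
  tmpl <- inhouse_geometry_template()
  smp <- simulate_roi_samples(tmpl, sigma = 3, n_repeats = 40, m_slices = 5, seed = 1)
  est <- estimate_template(smp)
  # CLT bound per pixel
  expect_true(all(abs(est$values - tmpl) < 4 * 3 * sqrt(2) / sqrt(200)))
  # present-only route halves the estimation noise source count
  est_p <- estimate_template(smp, source = "present")
  expect_true(all(abs(est_p$values - tmpl) < 4 * 3 / sqrt(200)))

  # identical ensembles: degenerate zero template, flagged
  smp0 <- simulate_roi_samples(tmpl * 0, sigma = 0.0, n_repeats = 2, m_slices = 1, seed = 2)
  smp0$present <- smp0$absent
  expect_warning(z <- estimate_template(smp0), "degenerate")
  expect_equal(z$values, rep(0, length(tmpl)))

  # noiseless ensemble: template equals the blurred profile exactly
  smpn <- simulate_roi_samples(tmpl, sigma = 0, n_repeats = 3, m_slices = 2, seed = 3)
  expect_equal(estimate_template(smpn)$values, tmpl)
})

test_that("decision variables are template inner products", {
  smp <- structure(list(
    present = matrix(c(4, -1, 7), 1, 3), absent = matrix(c(0, 0, 0), 1, 3),
    slice_index = 1L, n_repeats = 1L, m_slices = 1L, geometry = NULL),
    class = "roi_samples")
  tm <- structure(list(values = c(1, 2, 0), source = "analytic", degenerate = FALSE),
                  class = "npwmf_template")
  ds <- decision_variables(smp, tm)
  expect_equal(ds$L_present, 2)  # 4 - 2 + 0

  # template of ones sums the ROI; orthogonal image gives zero
  tm1 <- tm; tm1$values <- c(1, 1, 1)
  expect_equal(decision_variables(smp, tm1)$L_present, 10)
  tmo <- tm; tmo$values <- c(7, 0, -4)  # orthogonal to (4, -1, 7)
  expect_equal(decision_variables(smp, tmo)$L_present, 0)

  # linearity in the image
  smp2 <- smp; smp2$present <- smp$present * 3; smp2$absent <- smp$absent * 3
  expect_equal(decision_variables(smp2, tm)$L_present, 3 * ds$L_present)

  tm_bad <- tm; tm_bad$values <- c(1, 2)
  expect_error(decision_variables(smp, tm_bad), "length")
})

test_that("d-prime matches its definition and degenerates safely", {
  ds <- decision_set(c(-1, 1), c(1, 3))   # means 0 and 2, variances 2 and 2
  expect_equal(as.numeric(dprime_spatial(ds)), 2 / sqrt(2))
  ds2 <- decision_set(rnorm(50), rnorm(50) + 2)
  expect_gt(as.numeric(dprime_spatial(ds2)), 0)
  # identical classes: d-prime 0
  x <- rnorm(20, sd = 2)
  expect_equal(as.numeric(dprime_spatial(decision_set(x, x))), 0)
  # degenerate variance errors
  expect_error(dprime_spatial(decision_set(c(1, 1), c(2, 2))), "variance")
  # invariance: shifting or scaling decision variables
  ds3 <- decision_set(rnorm(30), rnorm(30) + 1.5)
  d0 <- as.numeric(dprime_spatial(ds3))
  shifted <- decision_set(ds3$L_absent + 7, ds3$L_present + 7)
  scaled <- decision_set(ds3$L_absent * 3, ds3$L_present * 3)
  expect_equal(as.numeric(dprime_spatial(shifted)), d0)
  expect_equal(as.numeric(dprime_spatial(scaled)), d0)
})

test_that("d-prime recovery from a designed ROI simulation is calibrated", {
  tmpl <- inhouse_geometry_template()
  target <- 2.0
  sigma <- sqrt(sum(tmpl^2)) / target  # white noise: d' = ||template|| / sigma
  smp <- simulate_roi_samples(tmpl, sigma, n_repeats = 110, m_slices = 5, seed = 77)
  ds <- decision_variables(smp, estimate_template(smp))
  d_hat <- as.numeric(dprime_spatial(ds))
  u <- dprime_rel_uncertainty(target, 110, 5) / 100
  expect_lt(abs(d_hat - target) / target, 2 * u + 0.025)  # 2u plus small-template bias
})

test_that("empirical AUC equals brute-force pair counting with H(0) = 1/2", {
  expect_equal(auc_empirical(decision_set(c(0, 1), c(2, 3))), 1)
  expect_equal(auc_empirical(decision_set(c(1, 3), c(2, 4))), 0.75)
  expect_equal(auc_empirical(decision_set(0, 0)), 0.5)
  expect_equal(auc_empirical(decision_set(0, 0), sigma = 2), 0.5)

  # brute-force oracle across sizes, including ties
  set.seed(31)
  for (k in 1:20) {
    n1 <- sample(1:12, 1); n2 <- sample(1:12, 1)
    L1 <- sample(seq(-3, 3, 0.5), n1, replace = TRUE)
    L2 <- sample(seq(-3, 3, 0.5), n2, replace = TRUE)
    brute <- 0
    for (i in seq_len(n1)) for (j in seq_len(n2)) {
      d <- L2[j] - L1[i]
      brute <- brute + (d > 0) + 0.5 * (d == 0)
    }
    expect_equal(auc_empirical(decision_set(L1, L2)), brute / (n1 * n2))
  }

  # invariance under shift; H-form invariance under scale
  ds <- decision_set(rnorm(40), rnorm(40) + 1)
  expect_equal(auc_empirical(decision_set(ds$L_absent + 5, ds$L_present + 5)),
               auc_empirical(ds))
  expect_equal(auc_empirical(decision_set(ds$L_absent * 2, ds$L_present * 2)),
               auc_empirical(ds))
  # smooth form approaches the H form as sigma shrinks
  expect_equal(auc_empirical(ds, sigma = 1e-9), auc_empirical(ds), tolerance = 1e-6)
  expect_error(auc_empirical(ds, sigma = -1), "sigma")
})

test_that("internal noise follows the beta relation", {
  ds <- decision_set(rnorm(100), rnorm(100))
  expect_equal(internal_noise_sigma(ds, 0), 0)
  ds1 <- decision_set(c(-1, 1) / sqrt(2), c(-1, 1) / sqrt(2))  # var 1 each
  expect_equal(internal_noise_sigma(ds1, 3), sqrt(6))
  # homogeneity: sigma scales with the decision-variable scale
  ds2 <- decision_set(ds$L_absent * 5, ds$L_present * 5)
  expect_equal(internal_noise_sigma(ds2, 2), 5 * internal_noise_sigma(ds, 2))
  expect_error(internal_noise_sigma(decision_set(c(1, 1), c(1, 1)), 3), "degenerate")
})

test_that("internal-noise AUC converges to the Gaussian-response prediction", {
  # method-2 / method-3 equivalence on large Gaussian decision sets
  set.seed(55)
  for (beta in c(0, 1, 3)) {
    d_true <- 1.8
    L1 <- rnorm(6000); L2 <- rnorm(6000, d_true)
    ds <- decision_set(L1, L2)
    sigma <- if (beta > 0) internal_noise_sigma(ds, beta) else 0
    expect_equal(auc_empirical(ds, sigma),
                 auc_from_dprime(d_true, beta), tolerance = 0.01)
  }
})
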