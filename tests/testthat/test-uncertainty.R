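test_that("d-prime / AUC conversions are exact and monotone", {
  expect_equal(auc_from_dprime(0, 0), 0.5)
  expect_equal(auc_from_dprime(2, 0), pnorm(sqrt(2)))
  # beta = 3 halves the effective d-prime
  expect_equal(auc_from_dprime(1.7, 3), auc_from_dprime(1.7 / 2, 0))
  # strictly increasing in d-prime, decreasing in beta
  d <- seq(0.1, 4, by = 0.1)
  expect_true(all(diff(auc_from_dprime(d, 1)) > 0))
  b <- seq(0, 5, by = 0.5)
  expect_true(all(diff(sapply(b, function(bb) auc_from_dprime(2, bb))) < 0))

  # exact inverse on a grid
  expect_equal(dprime_from_auc(0.5, 2), 0)
  for (a in c(0.51, 0.6, 0.75, 0.838, 0.9, 0.99)) {
    for (bb in c(0, 1, 3)) {
      expect_equal(auc_from_dprime(dprime_from_auc(a, bb), bb), a, tolerance = 1e-10)
    }
  }
  expect_equal(dprime_from_auc(0.838, 3), 2.79, tolerance = 0.001)
  expect_error(dprime_from_auc(1, 0), "strictly inside")
})

test_that("the analytic d-prime uncertainty evaluates correctly", {
  expect_equal(dprime_rel_uncertainty(1, 2, 1), 100 * sqrt(1 / 2 + 1 / 4))
  expect_equal(dprime_rel_uncertainty(2.79, 110, 5), 2.63, tolerance = 0.002)
  # large d-prime limit: the variance-estimation floor
  expect_equal(dprime_rel_uncertainty(1e6, 50, 4),
               100 * sqrt(1 / (4 * 49 * 4)), tolerance = 1e-6)
  expect_error(dprime_rel_uncertainty(2, 1, 5), "n_repeats")
})

test_that("the empirical spread of d-prime estimates matches the analytic u", {
  # calibration over many designed ROI-level ensembles, two ensemble sizes;
  # the formula describes the background-subtracted ROI route, where the
  # template comes from the present class and the absent mean is known zero
  tmpl <- inhouse_geometry_template()
  cases <- list(list(n = 110, m = 5, R = 200), list(n = 10, m = 5, R = 200))
  for (cs in cases) {
    target <- 2.79
    sigma <- sqrt(sum(tmpl^2)) / target
    est <- vapply(seq_len(cs$R), function(k) {
      smp <- simulate_roi_samples(tmpl, sigma, cs$n, cs$m, seed = 5000 + k)
      ds <- decision_variables(smp, estimate_template(smp, source = "present"))
      as.numeric(dprime_spatial(ds, absent_mean = "zero"))
    }, 0)
    u <- dprime_rel_uncertainty(target, cs$n, cs$m) / 100
    emp <- sd(est) / mean(est)
    expect_lt(abs(emp - u) / u, 0.15)
  }
})

test_that("method-2 intervals collapse with data and stay ordered", {
  ci <- auc_ci_method2(0.838, beta = 3, n_repeats = 110, m_slices = 5)
  expect_lt(ci[["ci_low"]], 0.838)
  expect_gt(ci[["ci_high"]], 0.838)
  big <- auc_ci_method2(0.838, beta = 3, n_repeats = 1e7, m_slices = 5)
  expect_equal(as.numeric(big), c(0.838, 0.838), tolerance = 1e-3)
  expect_error(auc_ci_method2(0.5, 3, 110, 5), "above 0.5")
})

test_that("per-slice AUC SEM behaves as a mean over slices", {
  # two slices engineered to identical per-slice AUCs: zero SEM
  ds <- decision_set(c(0, 1, 0, 1), c(0.5, 2, 10, 0.5), slice_index = c(1, 1, 2, 2))
  # slice 1: pairs (0,0.5),(0,2),(1,0.5),(1,2) -> 3/4 ; slice 2: (0,10),(0,0.5),(1,10),(1,0.5) -> 3/4
  res <- auc_sem_method3(ds, sigma = 0)
  expect_equal(res$per_slice, c(0.75, 0.75))
  expect_equal(res$sem, 0)
  expect_equal(res$ci_low, res$ci_high)

  ds2 <- decision_set(c(-10, -10, -10, 0), c(10, 0.4, 10, 10),
                      slice_index = c(1, 1, 2, 2))
  res2 <- auc_sem_method3(ds2, sigma = 0)
  expect_equal(res2$auc, mean(res2$per_slice))
  expect_equal(res2$sem, sd(res2$per_slice) / sqrt(2))

  expect_error(auc_sem_method3(decision_set(1:3, 1:3, slice_index = c(1, 1, 1))),
               "one slice")

  # simulated ensemble: mean-across-slices within 2 sem of the pooled AUC
  tmpl <- inhouse_geometry_template()
  smp <- simulate_roi_samples(tmpl, sqrt(sum(tmpl^2)) / 2, 60, 5, seed = 99)
  dsx <- decision_variables(smp, estimate_template(smp))
  pooled <- auc_empirical(dsx)
  r3 <- auc_sem_method3(dsx, sigma = 0)
  expect_lt(abs(r3$auc - pooled), 2 * r3$sem + 0.005)
})

test_that("the Fourier bootstrap is deterministic and degenerates to zero width", {
  task <- disk_spectrum(disk_feature(0, 0, 6, 10))
  rr <- seq(0, 1.2, length.out = 40)
  ttf_v <- exp(-2 * pi^2 * 0.36 * rr^2)
  # NPS scaled so the true AUC sits mid-range (~0.85) rather than saturating
  nps_v <- 2180 * (rr + 0.05) * exp(-(rr / 0.35)^2)
  # identical replicates: zero-width interval
  tr <- list(freq = rr, values = rbind(ttf_v, ttf_v, ttf_v))
  nr <- list(freq = rr, values = rbind(nps_v, nps_v, nps_v, nps_v))
  bs <- bootstrap_ci_fourier(tr, nr, task, beta = 3, B = 200, seed = 4)
  expect_equal(bs$ci_low, bs$ci_high)
  expect_equal(bs$ci_low, bs$auc)

  # jittered replicates (shape jitter for the TTF: scale jitter would cancel
  # under the zero-frequency normalization): reproducible non-trivial interval
  set.seed(8)
  trj <- list(freq = rr, values = t(sapply(1:6, function(i) ttf_v^(1 + rnorm(1, 0, 0.1)))))
  nrj <- list(freq = rr, values = t(sapply(1:8, function(i) nps_v * (1 + rnorm(1, 0, 0.1)))))
  b1 <- bootstrap_ci_fourier(trj, nrj, task, beta = 3, B = 300, seed = 21)
  b2 <- bootstrap_ci_fourier(trj, nrj, task, beta = 3, B = 300, seed = 21)
  expect_identical(b1[c("ci_low", "ci_high")], b2[c("ci_low", "ci_high")])
  expect_lt(b1$ci_low, b1$auc)
  expect_gt(b1$ci_high, b1$auc)
  expect_warning(bootstrap_ci_fourier(trj, nrj, task, B = 50, seed = 1), "unstable")
})

test_that("bootstrap intervals achieve near-nominal coverage", {
  # scaled-down coverage run: noisy TTF/NPS replicates around known truth
  task <- disk_spectrum(disk_feature(0, 0, 6, 10))
  rr <- seq(0, 1.2, length.out = 30)
  ttf_v <- exp(-2 * pi^2 * 0.36 * rr^2)
  nps_v <- 2180 * (rr + 0.05) * exp(-(rr / 0.35)^2)
  truth <- auc_from_dprime(
    dprime_fourier(nps_table(rr, nps_v), ttf_table(rr, ttf_v), task), 3)
  set.seed(2718)
  hits <- vapply(1:150, function(k) {
    tv <- t(sapply(1:6, function(i) ttf_v^(1 + rnorm(1, 0, 0.08))))
    nv <- t(sapply(1:10, function(i) nps_v * (1 + rnorm(1, 0, 0.08))))
    bs <- bootstrap_ci_fourier(list(freq = rr, values = tv),
                               list(freq = rr, values = nv), task, beta = 3,
                               B = 200, seed = 100 + k)
    bs$ci_low <= truth && truth <= bs$ci_high
  }, NA)
  expect_gt(mean(hits), 0.86)
  expect_lt(mean(hits), 0.995)
})

test_that("M-AFC percent correct converts to AUC via the Gaussian model", {
  expect_equal(mafc_pc_to_auc(0.75, 2), 0.75)  # 2-AFC identity
  # at exactly chance the conversion warns and returns 0.5
  expect_equal(suppressWarnings(mafc_pc_to_auc(0.25, 4)), 0.5, tolerance = 1e-6)
  expect_warning(a <- mafc_pc_to_auc(0.2, 4), "chance")
  expect_lt(a, 0.5)
  # monotone in pc
  pcs <- seq(0.3, 0.95, by = 0.05)
  aucs <- vapply(pcs, mafc_pc_to_auc, 0, m_alternatives = 4)
  expect_true(all(diff(aucs) > 0))

  # Monte-Carlo oracle: signal normal vs max of M-1 standard normals
  d_true <- 1.2
  set.seed(606)
  draws <- 1e6
  sig <- rnorm(draws, d_true)
  noise_max <- pmax(rnorm(draws), rnorm(draws), rnorm(draws))
  pc_mc <- mean(sig > noise_max)
  expect_equal(mafc_pc_to_auc(pc_mc, 4), pnorm(d_true / sqrt(2)), tolerance = 0.002)
})
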