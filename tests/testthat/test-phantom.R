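test_that("disk rendering follows the signal model", {
  # no blur: pixel-centre membership, sharp disk
  spec <- phantom_spec(c(40, 40), 0.5, 5, disk_feature(10, 10, 2, 2), psf_sigma = 0)
  img <- disk_image(spec, supersample = 1L)
  rows <- seq_len(40) - 1; cols <- seq_len(40) - 1
  inside <- outer((rows * 0.5 - 10)^2, (cols * 0.5 - 10)^2, "+") <= 1
  expect_equal(img[inside], rep(7, sum(inside)))
  expect_equal(img[!inside], rep(5, sum(!inside)))

  # zero contrast: uniform background
  spec0 <- phantom_spec(c(40, 40), 0.5, 5, disk_feature(10, 10, 2, 0))
  expect_equal(disk_image(spec0), matrix(5, 40, 40))

  # integral conservation under blur, for several PSF widths
  for (sg in c(0, 0.4, 1.0)) {
    spec_b <- phantom_spec(c(64, 64), 0.5, 0, disk_feature(16, 16, 6, 8), psf_sigma = sg)
    total <- sum(disk_image(spec_b)) * 0.5^2
    expect_equal(total, 8 * pi * 3^2, tolerance = 0.005)
  }

  # a disk leaking outside the grid is rejected
  expect_error(phantom_spec(c(40, 40), 0.5, 0, disk_feature(0.4, 10, 2, 5)),
               "outside")
})

test_that("noise fields are zero-mean, correctly scaled, and deterministic", {
  nz <- noise_spec("white", target_std = 10)
  expect_equal(synth_noise_field(noise_spec("white", target_std = 0), c(32, 32), 0.5, 1),
               matrix(0, 32, 32))
  f1 <- synth_noise_field(nz, c(256, 256), 0.5, seed = 11)
  expect_identical(f1, synth_noise_field(nz, c(256, 256), 0.5, seed = 11))
  expect_equal(sd(f1), 10, tolerance = 0.03)

  fr <- synth_noise_field(noise_spec("parametric-ramp", target_std = 10),
                          c(256, 256), 0.5, seed = 12)
  expect_equal(mean(fr), 0, tolerance = 1e-8)
  expect_equal(sd(fr), 10, tolerance = 0.03)

  expect_error(noise_spec("white", target_std = -1), "target_std")
  expect_error(synth_noise_field(nz, c(8, 8), 0.5, 1), "16")
})

test_that("generated noise matches the requested radial NPS model", {
  # stationary ramp noise: measured radial NPS vs the synthesis model,
  # band-averaged, away from the DC bin
  nz <- noise_spec("parametric-ramp", target_std = 10, ramp_cutoff = 0.35)
  px <- array(NA_real_, c(16, 1, 192, 192))
  for (r in 1:16) px[r, 1, , ] <- synth_noise_field(nz, c(192, 192), 0.4, seed = 300 + r)
  ens <- image_ensemble(px, 0.4)
  nps <- estimate_nps(ens, roi_size = 128)
  f_g <- npwmf:::fft_freq(192, 0.4)
  rho_g <- sqrt(outer(f_g^2, f_g^2, "+"))
  h2 <- (rho_g * exp(-(rho_g / 0.35)^2))^2
  model <- function(rho) (rho * exp(-(rho / 0.35)^2))^2 * 100 * 0.16 / mean(h2)
  # bands covering the bulk of the noise power (the relative scale is
  # meaningless where the model is near zero)
  bands <- cut(nps$radial_freq, c(0.05, 0.2, 0.35, 0.5))
  keep <- !is.na(bands)
  meas <- tapply(nps$values[keep], bands[keep], mean)
  ref <- tapply(model(nps$radial_freq)[keep], bands[keep], mean)
  expect_equal(as.numeric(meas), as.numeric(ref), tolerance = 0.05)
  # Parseval: NPS integral equals the pixel variance
  expect_equal(sum(attr(nps, "nps2d")) / (128 * 0.4)^2,
               attr(nps, "realization_variance"), tolerance = 0.03)
})

test_that("variance maps are uniform when stationary and not otherwise", {
  nz <- noise_spec("white", target_std = 10)
  fields <- sapply(1:60, function(k) synth_noise_field(nz, c(48, 48), 0.5, seed = k),
                   simplify = "array")
  vmap <- apply(fields, c(1, 2), sd)
  left <- mean(vmap[, 1:16]); right <- mean(vmap[, 33:48])
  expect_lt(abs(left - right) / 10, 0.05)

  nzg <- noise_spec("white", target_std = 10, nonstationary_gradient = 0.6)
  fieldsg <- sapply(1:60, function(k) synth_noise_field(nzg, c(48, 48), 0.5, seed = k),
                    simplify = "array")
  vmapg <- apply(fieldsg, c(1, 2), sd)
  expect_gt(mean(vmapg[, 33:48]) / mean(vmapg[, 1:16]), 1.3)
})

test_that("the denoiser surrogate suppresses flat-region noise but keeps edges", {
  spec <- small_spec()
  nz <- noise_spec("parametric-ramp", target_std = 10)
  nzd <- noise_spec("parametric-ramp", target_std = 10, denoiser = list(strength = 0.9))
  plain <- sapply(1:30, function(k) {
    simulate_ensemble(spec, nz, 1, 1, seed = k)$pixels[1, 1, , ]
  }, simplify = "array")
  den <- sapply(1:30, function(k) {
    simulate_ensemble(spec, nzd, 1, 1, seed = k)$pixels[1, 1, , ]
  }, simplify = "array")
  v_plain <- apply(plain, c(1, 2), sd)
  v_den <- apply(den, c(1, 2), sd)
  flat <- matrix(FALSE, 96, 96); flat[70:92, 70:92] <- TRUE
  expect_lt(mean(v_den[flat]), 0.6 * mean(v_plain[flat]))
  # the feature survives: mean denoised image still carries most of the contrast
  m_den <- apply(den, c(1, 2), mean)
  expect_gt(max(m_den), 6)
})

test_that("ensembles reduce to the clean image and obey the CLT", {
  spec <- small_spec()
  ens0 <- simulate_ensemble(spec, noise_spec("white", target_std = 0), 3, 2, seed = 1)
  clean <- disk_image(spec)
  for (r in 1:3) for (s in 1:2) expect_equal(ens0$pixels[r, s, , ], clean)

  nz <- noise_spec("white", target_std = 10)
  spec_s <- phantom_spec(c(32, 32), 0.5, 0, disk_feature(8, 8, 4, 10), 0.5)
  ens <- simulate_ensemble(spec_s, nz, 200, 1, seed = 5)
  m <- apply(ens$pixels[, 1, , ], c(2, 3), mean)
  dev <- abs(m - disk_image(spec_s))
  expect_gte(mean(dev <= 3 * 10 / sqrt(200)), 0.99)
})

test_that("ensemble TIFF round-trip preserves pixels and metadata", {
  ens <- simulate_ensemble(small_spec(), noise_spec("white", target_std = 5),
                           2, 2, seed = 9)
  path <- file.path(tempdir(), "ens.tif")
  write_ensemble(ens, path)
  back <- read_ensemble(path)
  expect_equal(back$pixels, ens$pixels, tolerance = 1e-6)  # float32 storage
  expect_equal(back$pixel_size, ens$pixel_size)
  expect_equal(back$n_repeats, 2)
  unlink(c(path, sub("\\.tif$", ".meta", path)))
})

test_that("layout CSV reading validates its columns", {
  path <- file.path(tempdir(), "layout.csv")
  write.csv(test_layout(), path, row.names = FALSE)
  lay <- read_layout(path)
  expect_equal(lay$diameter_mm, c(6, 12))
  write.csv(data.frame(x = 1), path, row.names = FALSE)
  expect_error(read_layout(path), "columns")
  unlink(path)
})
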