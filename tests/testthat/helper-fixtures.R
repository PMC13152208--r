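# Shared fixtures, built in code. Ensembles are cached per test file so the
# expensive simulations run once.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env)) assign(name, builder(), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# one faint disk task plus a high-contrast TTF rod, as in the default config
test_layout <- function(diameter = 6) {
  data.frame(center_x_mm = c(19.2, 57.6), center_y_mm = c(38.4, 19.2),
             diameter_mm = c(diameter, 12), contrast_hu = c(10, 50))
}

test_spec <- function(layout = test_layout(), grid = c(192L, 192L),
                      pixel_size = 0.4, psf_sigma = 0.6) {
  phantom_spec(grid, pixel_size, 0, npwmf:::layout_to_features(layout), psf_sigma)
}

# small single-feature phantom for fast unit tests
small_layout <- function(diameter = 4, contrast = 10) {
  data.frame(center_x_mm = 9.6, center_y_mm = 19.2,
             diameter_mm = diameter, contrast_hu = contrast)
}

small_spec <- function(layout = small_layout(), psf_sigma = 0.6) {
  phantom_spec(c(96L, 96L), 0.4, 0, npwmf:::layout_to_features(layout), psf_sigma)
}

small_ensemble <- function() {
  fixture("small_ens", function() {
    simulate_ensemble(small_spec(), noise_spec("parametric-ramp", target_std = 10),
                      n_repeats = 30, m_slices = 4, seed = 2024)
  })
}

# Gaussian ROI-level sample simulator: white pixel noise around a known
# template, the sampling model under which the analytic d-prime uncertainty
# holds. Returns a roi_samples object usable by the estimation chain.
simulate_roi_samples <- function(template, sigma, n_repeats, m_slices, seed) {
  set.seed(seed)
  p <- length(template)
  N <- n_repeats * m_slices
  present <- matrix(rnorm(N * p, 0, sigma), N, p) + rep(template, each = N)
  absent <- matrix(rnorm(N * p, 0, sigma), N, p)
  structure(list(present = present, absent = absent,
                 slice_index = rep(seq_len(m_slices), n_repeats),
                 n_repeats = n_repeats, m_slices = m_slices, geometry = NULL),
            class = "roi_samples")
}

# blurred 2 mm disk profile over its ROI at the in-house phantom geometry
inhouse_geometry_template <- function() {
  fixture("inhouse_tmpl", function() {
    lay <- data.frame(center_x_mm = 7, center_y_mm = 15, diameter_mm = 2, contrast_hu = 10)
    spec <- phantom_spec(c(64L, 64L), 0.469, 0, npwmf:::layout_to_features(lay), 0.6)
    geom <- place_rois(lay, roi_params(), c(64L, 64L), 0.469)[[1]]
    npwmf:::analytic_template(spec, geom)$values
  })
}
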