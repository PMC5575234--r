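test_that("probe constructors obey normalization and aperture invariants", {
  geom <- test_geom(32L)
  probes <- list(
    make_defocused_probe(geom, 400, electrons = 123, grid = 32L),
    make_fzp_probe(geom, 600, electrons = 5, grid = 32L),
    make_random_probe(geom, 4, seed = 3, electrons = 8.5, grid = 32L)
  )
  lam <- geom$wavelength_pm * 1e-2
  for (p in probes) {
    psi <- p$field$values
    expect_equal(sum(Mod(psi)^2), p$total_electrons, tolerance = 1e-8)
    spec <- Mod(fft2u(psi))
    theta <- lam * eptycho:::radial_freq_grid(32, geom$image_pixel_size) * 1e3
    outside <- spec[theta > p$aperture_half_angle + 1e-9]
    expect_lt(max(outside) / max(spec), 1e-12)
  }
  expect_error(make_defocused_probe(geom, 0, half_angle_mrad = 50), "Nyquist")
})

test_that("zero-defocus probes focus to a central intensity maximum", {
  geom <- test_geom(32L)
  for (p in list(make_defocused_probe(geom, 0, grid = 32L),
                 make_fzp_probe(geom, 0, grid = 32L))) {
    intensity <- Mod(p$field$values)^2
    expect_equal(which.max(intensity), 16L * 32L + 17L) # centre pixel (17, 17)
  }
})

test_that("defocused probe size matches the geometric-optics estimate", {
  # 400 nm defocus at 9.2 mrad needs sampling finer than 1.07 A
  geom <- default_geometry(pixel_size = 0.9, detector_pixels = 256L)
  p <- make_defocused_probe(geom, 400, half_angle_mrad = 9.2, grid = 256L)
  diam <- 2 * sqrt(probe_support_area(p) / pi)
  geometric <- 2 * 4000 * 9.2e-3 # 2 * Df * alpha in Angstrom
  expect_lt(abs(diam - geometric) / geometric, 0.2)
})

test_that("random probe is deterministic per seed and fully developed speckle", {
  geom <- test_geom(64L)
  p1 <- make_random_probe(geom, 2, seed = 11, grid = 64L)
  p2 <- make_random_probe(geom, 2, seed = 11, grid = 64L)
  expect_identical(p1$field$values, p2$field$values)
  p3 <- make_random_probe(geom, 2, seed = 12, grid = 64L)
  expect_false(identical(p1$field$values, p3$field$values))
  expect_error(make_random_probe(geom, 0.5), "at least 1")
  # speckle contrast ~ 1 after envelope normalization, across seeds
  contrast <- sapply(1:4, function(s) {
    p <- make_random_probe(geom, 2, seed = s, grid = 64L)
    intensity <- Mod(p$field$values)^2
    fq <- eptycho:::radial_freq_grid(64L, 1)
    envelope <- Re(stats::fft(stats::fft(intensity) * exp(-2 * pi^2 * 36 * fq^2),
                              inverse = TRUE)) / length(intensity)
    sel <- envelope > 0.1 * max(envelope)
    r <- intensity[sel] / envelope[sel]
    stats::sd(r) / mean(r)
  })
  expect_true(all(contrast > 0.7 & contrast < 1.3))
})

test_that("Fresnel propagation is reversible for band-limited fields", {
  geom <- test_geom(32L)
  p <- make_defocused_probe(geom, 100, half_angle_mrad = 3, grid = 32L)
  lam <- geom$wavelength_pm * 1e-2
  back <- fresnel_propagate(fresnel_propagate(p$field, 6000, lam), -6000, lam)
  expect_equal(back$values, p$field$values, tolerance = 1e-8)
})

test_that("probe support area matches counting and Gaussian closed forms", {
  # uniform disc of radius R: area within one pixel ring of pi R^2
  n <- 64L
  cx <- (n + 1) / 2
  r2 <- outer((seq_len(n) - cx)^2, (seq_len(n) - cx)^2, `+`)
  R <- 12
  disc <- complex_field((r2 <= R^2) + 0i, 1)
  area <- probe_support_area(disc)
  expect_lt(abs(sqrt(area / pi) - R), 1)
  # threshold 1 keeps only the arg-max set (here the whole flat disc)
  expect_equal(probe_support_area(disc, threshold = 1), sum(r2 <= R^2))
  # isotropic Gaussian intensity, std s: 1%-of-max level set area = pi (2 ln 100) s^2
  s <- 5
  gauss <- complex_field(sqrt(exp(-r2 / (2 * s^2))) + 0i, 1)
  expect_equal(probe_support_area(gauss), pi * 2 * log(100) * s^2, tolerance = 0.05)
  expect_error(probe_support_area(complex_field(matrix(0i, 4, 4), 1)), "zero")
})

test_that("scan step from overlap solves the circle-overlap equation", {
  geom <- test_geom(32L)
  p <- make_defocused_probe(geom, 400, grid = 32L)
  R <- sqrt(probe_support_area(p) / pi) / geom$image_pixel_size
  # independent root of the lens-area equation 2 acos(x/2) - (x/2) sqrt(4 - x^2) = 0.75 pi
  f <- function(x) 2 * acos(x / 2) - (x / 2) * sqrt(4 - x^2) - 0.75 * pi
  x_star <- uniroot(f, c(0, 2), tol = 1e-12)$root
  expect_equal(step_from_overlap(p, 0.75), max(1L, as.integer(round(R * x_star))))
  # overlap 0: tangent circles at the support diameter
  expect_equal(step_from_overlap(p, 0), max(1L, as.integer(round(2 * R))))
  # monotone non-increasing in overlap; clamped at 1 near full overlap
  steps <- sapply(c(0, 0.25, 0.5, 0.75, 0.9, 0.999), function(o) step_from_overlap(p, o))
  expect_true(all(diff(steps) <= 0))
  expect_equal(steps[length(steps)], 1L)
  expect_error(step_from_overlap(p, 1), "overlap")
})

test_that("default defocused probe yields a nanometre-scale 75% overlap step", {
  geom <- default_geometry(detector_pixels = 64L)
  p <- make_defocused_probe(geom, 400, grid = 64L)
  step_nm <- step_from_overlap(p, 0.75) * geom$image_pixel_size / 10
  expect_gt(step_nm, 0.5)
  expect_lt(step_nm, 5)
})

test_that("scan plans keep every patch inside the object with unique positions", {
  plan <- scan_plan(c(16, 16), 8L, 4L)
  expect_equal(plan$K, 9L)
  expect_true(all(plan$positions >= 0 & plan$positions <= 8))
  expect_false(anyDuplicated(plan$positions) > 0)
  plan2 <- scan_plan(c(16, 16), 8L, 3L, k_per_axis = 2L)
  expect_equal(plan2$K, 4L)
  expect_error(scan_plan(c(8, 8), 16L, 2L), "fit")
  expect_error(scan_plan(c(16, 16), 8L, 5L, k_per_axis = 3L), "fit")
})
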