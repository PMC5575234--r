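test_that("thin-object exit wave is the probe times the object patch", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  psi <- tp$probe$field$values
  ones <- matrix(1 + 0i, 8, 8)
  expect_identical(thin_object_exit_wave(tp$probe, ones, c(2L, 1L))$values, psi)
  # brute-force elementwise oracle on a random instance
  obj <- random_object(8, seed = 3)
  ew <- thin_object_exit_wave(tp$probe, obj, c(3L, 4L))$values
  expect_equal(ew, psi * obj[4:7, 5:8])
  # passivity: |T| <= 1 cannot amplify
  expect_lte(sum(Mod(ew)^2), sum(Mod(psi)^2) + 1e-10)
  expect_error(thin_object_exit_wave(tp$probe, obj, c(6L, 0L)), "outside")
})

test_that("far-field intensity conserves energy and is shift invariant", {
  set.seed(4)
  w <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  intensity <- far_field_intensity(w)
  expect_equal(sum(intensity), sum(Mod(w)^2), tolerance = 1e-10)
  # single-pixel exit wave: flat intensity
  d <- matrix(0i, 8, 8); d[3, 5] <- 2
  expect_equal(far_field_intensity(d), matrix(4 / 64, 8, 8), tolerance = 1e-12)
  # circular real-space shift leaves the intensity unchanged
  ws <- w[c(3:8, 1:2), c(6:8, 1:5)]
  expect_equal(far_field_intensity(ws), intensity, tolerance = 1e-10)
})

test_that("CTF imaging reduces to plain intensity and gives linear phase contrast", {
  geom <- test_geom(32L)
  set.seed(5)
  w <- matrix(complex(real = rnorm(1024), imaginary = rnorm(1024)), 32, 32)
  expect_equal(ctf_image(w, matrix(1 + 0i, 32, 32)), Mod(w)^2, tolerance = 1e-10)
  ctf <- make_ctf(geom, defocus_um = 1.6, grid = 32L)
  expect_true(all(Mod(ctf$pupil) <= 1 + 1e-12))
  # Zernike phase plate on a weak-phase object: contrast linear in phase
  phase <- 1e-3 * matrix(sin(2 * pi * (1:32) / 8), 32, 32, byrow = TRUE)
  exit <- exp(1i * phase)
  pp <- make_ctf(geom, defocus_um = 0, additional_phase = pi / 2, grid = 32L)
  img <- ctf_image(exit, pp)
  # first-order expansion: I ~ 1 + 2 phase
  expect_equal(img, 1 + 2 * phase, tolerance = 1e-5)
  expect_error(ctf_image(w, matrix(1 + 0i, 16, 16)), "grid")
})

test_that("forward operator passes the adjoint and dense design-matrix tests", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  op <- tp$op
  set.seed(6)
  x <- matrix(complex(real = rnorm(64), imaginary = rnorm(64)), 8, 8)
  y <- array(complex(real = rnorm(op$M * op$K), imaginary = rnorm(op$M * op$K)),
             c(4, 4, op$K))
  lhs <- sum(Conj(op_forward(op, x)) * y)
  rhs <- sum(Conj(x) * op_adjoint(op, y))
  expect_lt(Mod(lhs - rhs) / Mod(lhs), 1e-8)
  # dense design-matrix equivalence
  P <- dense_design_matrix(op)
  obj <- random_object(8, seed = 9)
  expect_equal(as.vector(forward_apply(obj, op)$data),
               Mod(P %*% as.vector(obj))[, 1]^2, tolerance = 1e-10)
  expect_equal(as.vector(op_adjoint(op, y)),
               (Conj(t(P)) %*% as.vector(y))[, 1], tolerance = 1e-10)
})

test_that("full-field unit probe reproduces the plain power spectrum", {
  plan <- scan_plan(c(8, 8), 8L, 1L)
  probe <- eptycho:::new_probe_field(matrix(1 + 0i, 8, 8), 1.7, 64, NA_real_)
  op <- forward_operator(probe, plan)
  obj <- random_object(8, seed = 2)
  expect_equal(op$K, 1L)
  expect_equal(forward_apply(obj, op)$data[, , 1], Mod(fft2u(obj))^2,
               tolerance = 1e-10)
})

test_that("patterns of a passive object never exceed the probe electrons", {
  geom <- test_geom(16L)
  probe <- make_random_probe(geom, 2, seed = 1, electrons = 50, grid = 16L)
  plan <- scan_plan(c(32, 32), 16L, 8L)
  obj <- generate_phantom(phantom_spec(grid = 32L, seed = 2))$object
  stack <- forward_apply(obj, forward_operator(probe, plan))
  expect_true(all(apply(stack$data, 3, sum) <= 50 + 1e-8))
})

test_that("multislice reduces to the thin object and converges with slicing", {
  geom <- test_geom(32L)
  probe <- make_defocused_probe(geom, 100, half_angle_mrad = 3, grid = 32L)
  # zero potential: free-space propagation conserves intensity
  zero_pot <- potential_map(array(0, c(32, 32, 3)), voxel_size = 1.7,
                            slice_thickness = 100)
  e0 <- multislice_exit_wave(probe, zero_pot, geom)
  expect_equal(sum(Mod(e0$values)^2), sum(Mod(probe$field$values)^2),
               tolerance = 1e-8)
  # single slice without propagation equals the thin-object product with
  # T = exp(i sigma V dz - W dz)
  ph <- generate_phantom(phantom_spec(grid = 32L, seed = 3), n_slices = 1L)
  sigma <- interaction_constant(geom$energy_kev)
  dz <- ph$potential$slice_thickness
  t_full <- exp(1i * sigma * ph$potential$real[, , 1] * dz -
                  ph$potential$imag[, , 1] * dz)
  e_thin <- thin_object_exit_wave(probe, t_full, c(0L, 0L))
  e_ms <- multislice_exit_wave(probe, ph$potential, geom, propagate = FALSE)
  expect_equal(e_ms$values, e_thin$values, tolerance = 1e-12)
  # slice-refinement convergence: halving the slice thickness shrinks the change
  ph1 <- generate_phantom(phantom_spec(grid = 32L, seed = 3), n_slices = 1L)
  ph2 <- generate_phantom(phantom_spec(grid = 32L, seed = 3), n_slices = 2L)
  ph4 <- generate_phantom(phantom_spec(grid = 32L, seed = 3), n_slices = 4L)
  e1 <- multislice_exit_wave(probe, ph1$potential, geom)$values
  e2 <- multislice_exit_wave(probe, ph2$potential, geom)$values
  e4 <- multislice_exit_wave(probe, ph4$potential, geom)$values
  d12 <- sqrt(sum(Mod(e1 - e2)^2))
  d24 <- sqrt(sum(Mod(e2 - e4)^2))
  expect_lt(d24, d12)
  expect_error(multislice_exit_wave(probe, potential_map(array(0, c(8, 8, 1)),
    voxel_size = 1.7, slice_thickness = 1), geom), "grid")
})
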