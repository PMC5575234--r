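# Exit-wave formation and the ptychographic forward (design-matrix) operator
# P = F Q: per scan position, crop an m x m patch of the transmission
# function, multiply by the probe, and take the unitary 2D DFT. Measurements
# are the squared moduli of P T.

#' Specimen transmission function
#'
#' Wraps a complex field as a passive specimen: |T| may not exceed 1.
#'
#' @param values Complex matrix (n1 x n2).
#' @param pixel_size Pixel size in Angstrom.
#' @return An object of class `object_field` (also a `complex_field`).
#' @export
object_field <- function(values, pixel_size) {
  f <- complex_field(values, pixel_size)
  if (any(Mod(f$values) > 1 + 1e-9)) {
    stop("transmission amplitude exceeds 1: specimen must be passive", call. = FALSE)
  }
  class(f) <- c("object_field", class(f))
  f
}

patch_indices <- function(position, m, object_dim) {
  r0 <- position[1]; c0 <- position[2]
  if (r0 < 0 || c0 < 0 || r0 + m > object_dim[1] || c0 + m > object_dim[2]) {
    stop(sprintf("probe patch at (%d, %d) lies outside the %d x %d object",
                 r0, c0, object_dim[1], object_dim[2]), call. = FALSE)
  }
  list(rows = seq.int(r0 + 1L, r0 + m), cols = seq.int(c0 + 1L, c0 + m))
}

#' Thin-object exit wave
#'
#' Pointwise product of the probe with the object patch at a scan position
#' (multiplicative thin-specimen approximation).
#'
#' @param probe A `probe_field` (or complex matrix).
#' @param object An `object_field` / `complex_field` (or complex matrix).
#' @param position Integer 0-based (row, col) top-left offset of the patch.
#' @return A `complex_field` with the probe's grid.
#' @export
thin_object_exit_wave <- function(probe, object, position = c(0L, 0L)) {
  psi <- probe_values(probe)
  t_v <- field_values(object)
  m <- nrow(psi)
  idx <- patch_indices(as.integer(position), m, dim(t_v))
  px <- if (inherits(probe, "probe_field")) probe$field$pixel_size
        else if (inherits(object, "complex_field")) object$pixel_size else 1
  complex_field(psi * t_v[idx$rows, idx$cols], px)
}

#' Far-field intensity of an exit wave
#'
#' `|F[psi_exit]|^2` with the unitary transform, so the total intensity equals
#' the total exit-wave intensity (Parseval). Zero frequency at index (1,1).
#'
#' @param exit_wave A `complex_field` or complex matrix.
#' @return Numeric matrix of intensities.
#' @export
far_field_intensity <- function(exit_wave) {
  Mod(fft2u(field_values(exit_wave)))^2
}

# ---- design-matrix operator -------------------------------------------------

#' Ptychographic forward operator P = F Q
#'
#' Matrix-free representation of the design matrix: `op_forward()` maps an
#' object to the K complex far-field amplitudes, `op_adjoint()` applies the
#' conjugate transpose. The adjoint satisfies `<Px, y> = <x, P^H y>`.
#'
#' @param probe A `probe_field`.
#' @param scanplan A `scan_plan`.
#' @return An object of class `forward_operator`.
#' @export
forward_operator <- function(probe, scanplan) {
  stopifnot(inherits(scanplan, "scan_plan"))
  psi <- probe_values(probe)
  m <- nrow(psi)
  if (m != scanplan$probe_dim) stop("probe grid does not match scan plan", call. = FALSE)
  # summed illumination intensity per object pixel (the diagonal of Q^H Q)
  w <- matrix(0, scanplan$object_dim[1], scanplan$object_dim[2])
  ai <- Mod(psi)^2
  for (k in seq_len(scanplan$K)) {
    idx <- patch_indices(scanplan$positions[k, ], m, scanplan$object_dim)
    w[idx$rows, idx$cols] <- w[idx$rows, idx$cols] + ai
  }
  structure(list(probe = psi,
                 pixel_size = probe_pixel_size(probe),
                 positions = scanplan$positions,
                 K = scanplan$K, m = m,
                 object_dim = scanplan$object_dim,
                 illumination = w,
                 N = prod(scanplan$object_dim),
                 M = as.integer(m * m)),
            class = "forward_operator")
}

#' @export
print.forward_operator <- function(x, ...) {
  cat(sprintf("<forward_operator> K = %d, M = %d, N = %d (KM = %d)\n",
              x$K, x$M, x$N, x$K * x$M))
  invisible(x)
}

#' Apply the complex forward map F Q
#'
#' @param op A `forward_operator`.
#' @param object Object values (complex matrix or field).
#' @return Complex array of dim (m, m, K): the K far-field amplitudes.
#' @export
op_forward <- function(op, object) {
  t_v <- field_values(object)
  if (!all(dim(t_v) == op$object_dim)) stop("object shape mismatch", call. = FALSE)
  out <- array(0i, c(op$m, op$m, op$K))
  for (k in seq_len(op$K)) {
    idx <- patch_indices(op$positions[k, ], op$m, op$object_dim)
    out[, , k] <- fft2u(op$probe * t_v[idx$rows, idx$cols])
  }
  out
}

#' Apply the adjoint map (F Q)^H
#'
#' @param op A `forward_operator`.
#' @param waves Complex array of dim (m, m, K).
#' @return Complex matrix on the object grid.
#' @export
op_adjoint <- function(op, waves) {
  out <- matrix(0i, op$object_dim[1], op$object_dim[2])
  cp <- Conj(op$probe)
  for (k in seq_len(op$K)) {
    idx <- patch_indices(op$positions[k, ], op$m, op$object_dim)
    out[idx$rows, idx$cols] <- out[idx$rows, idx$cols] + cp * ifft2u(waves[, , k])
  }
  out
}

#' Noise-free diffraction stack
#'
#' Computes the K far-field intensity patterns `|F Q T|^2`.
#'
#' @param object Object values (complex matrix or field).
#' @param op A `forward_operator`.
#' @return A `diffraction_stack` whose `data` is an (m, m, K) array.
#' @export
forward_apply <- function(object, op) {
  a <- op_forward(op, object)
  diffraction_stack(Mod(a)^2, pixel_size = op$pixel_size)
}

#' Diffraction measurement stack
#'
#' @param data Nonnegative array of dim (m, m, K): noise-free intensities or
#'   detector counts.
#' @param dose Optional dose in electrons per square Angstrom.
#' @param electrons_per_pattern Optional electrons per pattern.
#' @param pixel_size Image pixel size r_d in Angstrom.
#' @return An object of class `diffraction_stack`.
#' @export
diffraction_stack <- function(data, dose = NA_real_,
                              electrons_per_pattern = NA_real_,
                              pixel_size = NA_real_) {
  if (length(dim(data)) == 2L) data <- array(data, c(dim(data), 1L))
  if (length(dim(data)) != 3L) stop("`data` must be an (m, m, K) array", call. = FALSE)
  if (any(data < 0)) stop("diffraction intensities must be nonnegative", call. = FALSE)
  structure(list(data = data, dose = dose,
                 electrons_per_pattern = electrons_per_pattern,
                 pixel_size = pixel_size,
                 K = dim(data)[3], M = as.integer(dim(data)[1] * dim(data)[2])),
            class = "diffraction_stack")
}

#' @export
print.diffraction_stack <- function(x, ...) {
  cat(sprintf("<diffraction_stack> K = %d patterns of %d x %d, mean total %.4g e-\n",
              x$K, dim(x$data)[1], dim(x$data)[2], mean(apply(x$data, 3, sum))))
  invisible(x)
}

stack_values <- function(y) {
  if (inherits(y, "diffraction_stack")) y$data else y
}

# ---- conventional TEM imaging (CTF arm) ------------------------------------

#' Contrast transfer function (pupil) of a conventional TEM
#'
#' Complex pupil `exp(-i chi(q))` with
#' `chi = pi lambda Df q^2 - (pi/2) Cs lambda^3 q^4`, an optional radial
#' envelope, and an `additional_phase` applied to the unscattered (q = 0)
#' beam — `pi/2` models a Zernike phase plate.
#'
#' @param geom An `experiment_geometry`.
#' @param defocus_um Defocus in micrometres (positive = underfocus).
#' @param cs_mm Spherical aberration in mm (default 0).
#' @param additional_phase Phase in rad added to the unscattered beam
#'   (0 for defocus contrast, pi/2 for a Zernike phase plate).
#' @param envelope Optional function of |q| (1/Angstrom) returning an
#'   amplitude in [0, 1].
#' @param grid Grid side on which to sample (default the detector side).
#' @param pixel_size Real-space pixel size (default the geometry's r_d).
#' @return An object of class `ctf` holding the complex pupil on the
#'   unshifted frequency grid.
#' @export
make_ctf <- function(geom, defocus_um, cs_mm = 0, additional_phase = 0,
                     envelope = NULL, grid = geom$detector_pixels,
                     pixel_size = geom$image_pixel_size) {
  lambda <- geom$wavelength_pm * 1e-2
  q <- radial_freq_grid(grid, pixel_size)
  chi <- pi * lambda * (defocus_um * 1e4) * q^2 -
    (pi / 2) * (cs_mm * 1e7) * lambda^3 * q^4
  pupil <- exp(-1i * chi)
  if (!is.null(envelope)) {
    env <- envelope(q)
    if (any(env < -1e-12) || any(env > 1 + 1e-12)) {
      stop("CTF envelope must lie in [0, 1]", call. = FALSE)
    }
    pupil <- pupil * env
  }
  pupil[1, 1] <- pupil[1, 1] * exp(1i * additional_phase)
  structure(list(pupil = pupil, defocus_um = defocus_um, cs_mm = cs_mm,
                 additional_phase = additional_phase, pixel_size = pixel_size),
            class = "ctf")
}

#' Conventional (CTF-filtered) TEM image of an exit wave
#'
#' `|F^-1[F[psi_exit] * CTF(q)]|^2`; with `CTF == 1` this reduces to the plain
#' exit-wave intensity.
#'
#' @param exit_wave A `complex_field` or complex matrix.
#' @param ctf A `ctf` (or a complex matrix sampled on the exit-wave grid,
#'   unshifted frequency order).
#' @return Numeric intensity matrix on the image grid.
#' @export
ctf_image <- function(exit_wave, ctf) {
  v <- field_values(exit_wave)
  pupil <- if (inherits(ctf, "ctf")) ctf$pupil else ctf
  if (!all(dim(pupil) == dim(v))) stop("CTF grid does not match exit wave", call. = FALSE)
  Mod(ifft2u(fft2u(v) * pupil))^2
}

# ---- multislice -------------------------------------------------------------

#' Energy-dependent interaction constant
#'
#' sigma = (2 pi / (lambda V)) * (m0 c^2 + E) / (2 m0 c^2 + E), in
#' rad / (Volt * Angstrom), with E the kinetic energy.
#'
#' @param energy_kev Electron energy in keV.
#' @return Interaction constant in rad / (V * Angstrom).
#' @export
interaction_constant <- function(energy_kev) {
  lambda <- wavelength_from_energy(energy_kev) * 1e-2 # Angstrom
  v_volt <- energy_kev * 1e3
  (2 * pi / (lambda * v_volt)) *
    (.ELECTRON_REST_KEV + energy_kev) / (2 * .ELECTRON_REST_KEV + energy_kev)
}

#' Multislice exit wave
#'
#' Propagates the probe through a sliced potential by alternating per-slice
#' transmission `exp(i sigma V_s dz - W_s dz)` (V_s the real, W_s the
#' imaginary/absorptive part of the slice potential) with band-limited Fresnel
#' propagation over the slice thickness. Used on the simulation side only; the
#' reconstruction forward model is the thin-object product.
#'
#' @param probe A `probe_field`.
#' @param potential A `potential_map` (see [potential_map()]).
#' @param geom An `experiment_geometry` (supplies wavelength and sigma).
#' @param propagate Apply the inter-slice Fresnel propagation (default TRUE);
#'   FALSE gives the pure projection (thin-object) limit.
#' @return The exit `complex_field` at the bottom of the specimen.
#' @export
multislice_exit_wave <- function(probe, potential, geom, propagate = TRUE) {
  stopifnot(inherits(potential, "potential_map"))
  psi <- probe_values(probe)
  px <- probe_pixel_size(probe)
  if (abs(potential$voxel_size - px) > 1e-9 * px) {
    stop("potential voxel size must equal the probe pixel size", call. = FALSE)
  }
  if (!all(dim(potential$real)[1:2] == dim(psi))) {
    stop("potential grid does not match the probe grid", call. = FALSE)
  }
  lambda <- geom$wavelength_pm * 1e-2
  sigma <- interaction_constant(geom$energy_kev)
  dz <- potential$slice_thickness
  field <- complex_field(psi, px)
  for (s in seq_len(dim(potential$real)[3])) {
    trans <- exp(1i * sigma * potential$real[, , s] * dz -
                   potential$imag[, , s] * dz)
    field <- complex_field(field$values * trans, px)
    if (propagate && dz > 0) field <- fresnel_propagate(field, dz, lambda)
  }
  field
}
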