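# Illumination (probe) engineering: defocused, Fresnel-zone-plate and
# randomized probes, plus the support-area / scan-step rules used for the
# 75% real-space overlap convention.

# Aperture-plane angular grids for an m x m probe sampled at r_d:
# scattering angle theta(q) = lambda * |q|, with q in cycles/Angstrom.
aperture_mask <- function(m, pixel_size, wavelength, half_angle_mrad) {
  q <- radial_freq_grid(m, pixel_size)
  theta <- wavelength * q * 1e3 # mrad
  theta_ny <- wavelength / (2 * pixel_size) * 1e3
  if (half_angle_mrad > theta_ny) {
    stop(sprintf(
      "aperture half-angle %.2f mrad exceeds the detector Nyquist angle %.2f mrad",
      half_angle_mrad, theta_ny), call. = FALSE)
  }
  theta <= half_angle_mrad
}

new_probe_field <- function(values, pixel_size, electrons, half_angle_mrad) {
  values <- values * sqrt(electrons / sum(Mod(values)^2))
  structure(
    list(field = complex_field(values, pixel_size),
         total_electrons = electrons,
         aperture_half_angle = half_angle_mrad),
    class = "probe_field"
  )
}

#' @export
print.probe_field <- function(x, ...) {
  cat(sprintf("<probe_field> %d x %d px @ %.4f A, %.4g e-/exposure, aperture %.2f mrad\n",
              nrow(x$field$values), ncol(x$field$values), x$field$pixel_size,
              x$total_electrons, x$aperture_half_angle))
  invisible(x)
}

probe_values <- function(probe) {
  if (inherits(probe, "probe_field")) probe$field$values else field_values(probe)
}

probe_pixel_size <- function(probe) {
  if (inherits(probe, "probe_field")) probe$field$pixel_size
  else if (inherits(probe, "complex_field")) probe$pixel_size
  else stop("cannot determine pixel size of probe", call. = FALSE)
}

#' Defocused probe
#'
#' Aperture-limited wave with the quadratic defocus phase
#' chi(q) = pi * lambda * Df * |q|^2 applied in the probe-forming aperture,
#' inverse-transformed to the sample plane and normalized to carry
#' `electrons` per exposure. The reference illumination uses a defocus of
#' 400 nm; at zero defocus the probe is an Airy-like focused spot.
#'
#' @param geom An `experiment_geometry`.
#' @param defocus_nm Defocus in nm.
#' @param half_angle_mrad Aperture half-angle in mrad (default from `geom`).
#' @param electrons Electrons per exposure (default 1).
#' @param grid Probe grid side m (default the detector side).
#' @return A `probe_field`.
#' @export
make_defocused_probe <- function(geom, defocus_nm = 400,
                                 half_angle_mrad = geom$probe_half_angle_mrad,
                                 electrons = 1, grid = geom$detector_pixels) {
  stopifnot(inherits(geom, "experiment_geometry"), is.finite(defocus_nm))
  r_d <- geom$image_pixel_size
  lambda <- geom$wavelength_pm * 1e-2 # Angstrom
  a <- aperture_mask(grid, r_d, lambda, half_angle_mrad)
  q <- radial_freq_grid(grid, r_d)
  chi <- pi * lambda * (defocus_nm * 10) * q^2
  pupil <- a * exp(-1i * chi)
  psi <- fftshift2(ifft2u(pupil))
  new_probe_field(psi, r_d, electrons, half_angle_mrad)
}

#' Fresnel-zone-plate probe
#'
#' Models an ideal binary (0/pi) zone plate in the probe-forming aperture:
#' the zones binarize the quadratic phase corresponding to a plane
#' `distance_from_focus_nm` from focus, so that the sample sits out of the
#' plate's focal plane. With zero distance the plate is inactive and the probe
#' reduces to the focused Airy-like spot.
#'
#' @inheritParams make_defocused_probe
#' @param distance_from_focus_nm Distance of the sample plane from focus in nm.
#' @return A `probe_field`.
#' @export
make_fzp_probe <- function(geom, distance_from_focus_nm = 600,
                           half_angle_mrad = geom$probe_half_angle_mrad,
                           electrons = 1, grid = geom$detector_pixels) {
  stopifnot(inherits(geom, "experiment_geometry"), is.finite(distance_from_focus_nm))
  r_d <- geom$image_pixel_size
  lambda <- geom$wavelength_pm * 1e-2
  a <- aperture_mask(grid, r_d, lambda, half_angle_mrad)
  q <- radial_freq_grid(grid, r_d)
  chi <- pi * lambda * (distance_from_focus_nm * 10) * q^2
  zones <- (floor(chi / pi) %% 2) # 0/1 Fresnel zones of the defocus chirp
  pupil <- a * exp(1i * pi * zones)
  psi <- fftshift2(ifft2u(pupil))
  new_probe_field(psi, r_d, electrons, half_angle_mrad)
}

#' Randomized probe (holographic phase plate + lens)
#'
#' Aperture-limited wave whose aperture-plane phase is a band-limited random
#' screen: i.i.d. uniform phases smoothed with a Gaussian kernel of the given
#' correlation length and rescaled to a standard deviation of pi, then focused
#' to the sample plane by the lens (inverse Fourier) transform. For
#' correlation lengths much smaller than the aperture the sample-plane
#' intensity is fully developed speckle (contrast ~ 1). Deterministic per
#' seed.
#'
#' @inheritParams make_defocused_probe
#' @param correlation_length_px Correlation length of the phase screen in
#'   aperture-plane pixels (>= 1; default 4).
#' @param seed Integer seed for the phase screen.
#' @return A `probe_field`.
#' @export
make_random_probe <- function(geom, correlation_length_px = 4, seed = 1,
                              half_angle_mrad = geom$probe_half_angle_mrad,
                              electrons = 1, grid = geom$detector_pixels) {
  stopifnot(inherits(geom, "experiment_geometry"))
  if (correlation_length_px < 1) {
    stop("`correlation_length_px` must be at least 1 pixel", call. = FALSE)
  }
  r_d <- geom$image_pixel_size
  lambda <- geom$wavelength_pm * 1e-2
  a <- aperture_mask(grid, r_d, lambda, half_angle_mrad)
  set.seed(seed)
  raw <- matrix(stats::runif(grid * grid, -pi, pi), grid, grid)
  # Gaussian smoothing via the (periodic) Fourier multiplier
  fpx <- radial_freq_grid(grid, 1) # cycles per pixel
  kernel <- exp(-2 * pi^2 * correlation_length_px^2 * fpx^2)
  smooth <- Re(stats::fft(stats::fft(raw) * kernel, inverse = TRUE)) / (grid * grid)
  s <- stats::sd(smooth)
  if (s > 0) smooth <- smooth * (pi / s)
  pupil <- a * exp(1i * smooth)
  psi <- fftshift2(ifft2u(pupil))
  new_probe_field(psi, r_d, electrons, half_angle_mrad)
}

#' Rescale a probe to a given electron budget
#'
#' @param probe A `probe_field`.
#' @param electrons Target electrons per exposure.
#' @return The rescaled `probe_field`.
#' @export
set_probe_electrons <- function(probe, electrons) {
  stopifnot(inherits(probe, "probe_field"), electrons > 0)
  new_probe_field(probe$field$values, probe$field$pixel_size, electrons,
                  probe$aperture_half_angle)
}

#' Probe support area
#'
#' Area of the real-space probe support, defined as all pixels whose intensity
#' exceeds `threshold` (default 1%) of the maximum intensity, times the pixel
#' area.
#'
#' @param probe A `probe_field` (or `complex_field`).
#' @param threshold Fraction of the maximum intensity (default 0.01).
#' @return Support area in square Angstrom.
#' @export
probe_support_area <- function(probe, threshold = 0.01) {
  v <- probe_values(probe)
  intensity <- Mod(v)^2
  mx <- max(intensity)
  if (mx == 0) stop("probe is identically zero", call. = FALSE)
  px <- probe_pixel_size(probe)
  # tiny slack so that threshold = 1 keeps the arg-max set itself
  sum(intensity > threshold * mx * (1 - 1e-12)) * px^2
}

# Fractional area overlap of two equal circles of radius R at centre distance d.
circle_overlap_fraction <- function(d, R) {
  if (d >= 2 * R) return(0)
  x <- d / (2 * R)
  (2 * acos(x) - 2 * x * sqrt(1 - x^2)) / pi
}

#' Scan step from a target probe-area overlap
#'
#' Finds the integer pixel step at which two copies of the probe's
#' circular-equivalent support (radius from [probe_support_area()]) share the
#' requested fraction of their area. Overlap is *area* overlap of the 1%
#' support; the result is rounded to the nearest pixel and clamped at 1.
#'
#' @param probe A `probe_field`.
#' @param overlap Target area-overlap fraction in [0, 1).
#' @param threshold Support threshold passed to [probe_support_area()].
#' @return Step in pixels (integer, >= 1).
#' @export
step_from_overlap <- function(probe, overlap = 0.75, threshold = 0.01) {
  if (!is.numeric(overlap) || overlap < 0 || overlap >= 1) {
    stop("`overlap` must lie in [0, 1)", call. = FALSE)
  }
  area <- probe_support_area(probe, threshold)
  px <- probe_pixel_size(probe)
  R_px <- sqrt(area / pi) / px
  if (overlap == 0) return(max(1L, as.integer(round(2 * R_px))))
  f <- function(d) circle_overlap_fraction(d, R_px) - overlap
  d <- stats::uniroot(f, c(0, 2 * R_px), tol = 1e-10)$root
  max(1L, as.integer(round(d)))
}

#' Raster scan plan
#'
#' Places an m x m probe patch at integer pixel offsets on a regular grid such
#' that every patch lies fully inside the n1 x n2 object.
#'
#' @param object_dim Integer vector (n1, n2) of the object grid.
#' @param probe_dim Integer probe side m (square probes).
#' @param step Scan step in pixels.
#' @param k_per_axis Optional number of positions per axis; by default as many
#'   as fit. When given, the scan is centred on the object.
#' @return An object of class `scan_plan` with `positions` (K x 2 matrix of
#'   0-based top-left offsets, rows then columns), `step` and `K`.
#' @export
scan_plan <- function(object_dim, probe_dim, step, k_per_axis = NULL) {
  object_dim <- rep(as.integer(object_dim), length.out = 2L)
  m <- as.integer(probe_dim)
  step <- as.integer(step)
  if (step < 1L) stop("`step` must be at least 1 pixel", call. = FALSE)
  if (any(object_dim < m)) stop("probe does not fit inside the object", call. = FALSE)
  offsets <- function(n, k) {
    if (is.null(k)) {
      seq.int(0L, n - m, by = step)
    } else {
      span <- (k - 1L) * step
      if (span > n - m) stop("scan plan does not fit inside the object", call. = FALSE)
      start <- as.integer(floor((n - m - span) / 2))
      seq.int(start, by = step, length.out = k)
    }
  }
  r <- offsets(object_dim[1], k_per_axis)
  c_ <- offsets(object_dim[2], k_per_axis)
  pos <- as.matrix(expand.grid(row = r, col = c_))
  storage.mode(pos) <- "integer"
  if (anyDuplicated(pos)) stop("scan positions must be unique", call. = FALSE)
  structure(list(positions = pos, step = step, K = nrow(pos), probe_dim = m,
                 object_dim = object_dim),
            class = "scan_plan")
}

#' @export
print.scan_plan <- function(x, ...) {
  cat(sprintf("<scan_plan> K = %d positions, step = %d px, patch %d x %d in %d x %d\n",
              x$K, x$step, x$probe_dim, x$probe_dim, x$object_dim[1], x$object_dim[2]))
  invisible(x)
}
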