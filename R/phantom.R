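# Synthetic specimens: weak-phase pseudo-atom phantoms emulating a
# macromolecule embedded in vitreous ice, and sliced potential maps.

#' Sliced specimen potential
#'
#' Real (phase-shifting, in Volt) and imaginary (absorptive, in 1/Angstrom)
#' potential on a 3D voxel grid. The projected phase of a column is
#' sigma * sum_s V_s * dz and the projected attenuation exponent is
#' sum_s W_s * dz.
#'
#' @param real 3D numeric array (n1, n2, n_slices) of the real potential (V).
#' @param imag 3D numeric array of the absorptive part (1/Angstrom), >= 0.
#' @param voxel_size In-plane voxel size in Angstrom.
#' @param slice_thickness Slice thickness dz in Angstrom.
#' @return An object of class `potential_map`.
#' @export
potential_map <- function(real, imag = NULL, voxel_size, slice_thickness) {
  if (length(dim(real)) == 2L) real <- array(real, c(dim(real), 1L))
  if (is.null(imag)) imag <- array(0, dim(real))
  if (length(dim(imag)) == 2L) imag <- array(imag, c(dim(imag), 1L))
  stopifnot(all(dim(real) == dim(imag)))
  if (any(imag < 0)) stop("the imaginary potential must be nonnegative", call. = FALSE)
  if (voxel_size <= 0 || slice_thickness < 0) {
    stop("voxel size must be positive and slice thickness nonnegative", call. = FALSE)
  }
  structure(list(real = real, imag = imag, voxel_size = voxel_size,
                 slice_thickness = slice_thickness,
                 thickness = slice_thickness * dim(real)[3]),
            class = "potential_map")
}

#' Phantom specification
#'
#' Parameters of the pseudo-atom macromolecule-in-ice phantom. Defaults
#' emulate a ~50 nm thick vitrified specimen at 300 keV: a compact particle
#' of Gaussian pseudo-atoms with a peak phase shift of 0.3 rad on a weakly
#' fluctuating ice background, with amplitude contrast from the inelastic
#' mean free path (`exp(-t / 2 Lambda)`, slightly lower Lambda inside the
#' protein than in ice).
#'
#' @param grid Object grid side (n1 = n2).
#' @param pixel_size Pixel size in Angstrom.
#' @param n_pseudo_atoms Number of Gaussian pseudo-atoms.
#' @param atom_sigma Gaussian width of one pseudo-atom in Angstrom.
#' @param peak_phase Maximum phase shift in rad, in (0, pi).
#' @param ice_phase_std Standard deviation of the ice background phase (rad).
#' @param thickness Specimen thickness t in Angstrom (default 500 A = 50 nm).
#' @param mfp_ice Inelastic mean free path in ice (Angstrom).
#' @param mfp_protein Inelastic mean free path in protein (Angstrom).
#' @param seed Integer seed.
#' @return A list of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = 64L, pixel_size = 1.7, n_pseudo_atoms = 40L,
                         atom_sigma = 3.5, peak_phase = 0.3,
                         ice_phase_std = 0.02, thickness = 500,
                         mfp_ice = 3500, mfp_protein = 2800, seed = 1L) {
  if (peak_phase <= 0 || peak_phase >= pi) stop("`peak_phase` must lie in (0, pi)", call. = FALSE)
  if (any(c(pixel_size, atom_sigma, thickness, mfp_ice, mfp_protein) <= 0)) {
    stop("all phantom lengths must be positive", call. = FALSE)
  }
  structure(list(grid = as.integer(grid), pixel_size = pixel_size,
                 n_pseudo_atoms = as.integer(n_pseudo_atoms),
                 atom_sigma = atom_sigma, peak_phase = peak_phase,
                 ice_phase_std = ice_phase_std, thickness = thickness,
                 mfp_ice = mfp_ice, mfp_protein = mfp_protein,
                 seed = as.integer(seed)),
            class = "phantom_spec")
}

# Smooth periodic Gaussian random field with unit variance, correlation
# length `corr_px` pixels.
smooth_noise_field <- function(n, corr_px) {
  raw <- matrix(stats::rnorm(n * n), n, n)
  f <- radial_freq_grid(n, 1)
  kern <- exp(-2 * pi^2 * corr_px^2 * f^2)
  sm <- Re(stats::fft(stats::fft(raw) * kern, inverse = TRUE)) / (n * n)
  s <- stats::sd(sm)
  if (s > 0) sm / s else sm
}

#' Generate a macromolecule-in-ice phantom
#'
#' Places Gaussian pseudo-atoms inside a compact circular particle mask on a
#' weakly fluctuating ice background. The total phase is rescaled so its
#' maximum equals `peak_phase`; the amplitude is `exp(-t / 2 Lambda(r))`
#' with the mean free path interpolating between ice and protein following
#' the normalized pseudo-atom density, which creates the minimal amplitude
#' contrast of a vitrified specimen. Deterministic per seed.
#'
#' @param spec A `phantom_spec`.
#' @param n_slices Number of slices of the returned potential map (default 5).
#' @return A list with elements `object` (an `object_field`) and
#'   `potential` (a `potential_map` consistent with the object under
#'   [potential_to_transmission()]), plus `phase` and `amplitude` matrices
#'   and the atom centres.
#' @export
generate_phantom <- function(spec, n_slices = 5L) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$grid
  set.seed(spec$seed)
  # compact particle mask: disc of radius 0.35 n centred in the grid
  cx <- (n + 1) / 2
  rr <- outer(seq_len(n) - cx, rep(1, n)) # row offsets
  cc <- outer(rep(1, n), seq_len(n) - cx)
  radius_px <- 0.35 * n
  # atom centres uniform in the disc (rejection-free: polar with sqrt radius)
  u <- stats::runif(spec$n_pseudo_atoms)
  th <- stats::runif(spec$n_pseudo_atoms, 0, 2 * pi)
  ar <- cx + radius_px * sqrt(u) * cos(th)
  ac <- cx + radius_px * sqrt(u) * sin(th)
  sig_px <- spec$atom_sigma / spec$pixel_size
  atoms <- matrix(0, n, n)
  for (a in seq_len(spec$n_pseudo_atoms)) {
    atoms <- atoms + exp(-((rr + cx - ar[a])^2 + (cc + cx - ac[a])^2) / (2 * sig_px^2))
  }
  density <- if (max(atoms) > 0) atoms / max(atoms) else atoms
  ice <- smooth_noise_field(n, corr_px = max(2, sig_px)) * spec$ice_phase_std
  phase_raw <- density * spec$peak_phase + ice
  phase <- phase_raw * (spec$peak_phase / max(phase_raw))
  # amplitude: mean free path interpolates ice -> protein with density
  mfp <- spec$mfp_ice + (spec$mfp_protein - spec$mfp_ice) * density
  amplitude <- exp(-spec$thickness / (2 * mfp))
  t_v <- amplitude * exp(1i * phase)
  obj <- object_field(t_v, spec$pixel_size)
  # consistent sliced potential: equal share of projected phase/attenuation
  sigma <- interaction_constant(300)
  dz <- spec$thickness / n_slices
  v_slice <- phase / (sigma * spec$thickness) # Volt, uniform across slices
  w_slice <- (-log(amplitude)) / spec$thickness # 1/Angstrom
  pot <- potential_map(
    real = array(rep(v_slice, n_slices), c(n, n, n_slices)),
    imag = array(rep(w_slice, n_slices), c(n, n, n_slices)),
    voxel_size = spec$pixel_size, slice_thickness = dz
  )
  list(object = obj, potential = pot, phase = phase, amplitude = amplitude,
       atom_centres = cbind(row = ar, col = ac), spec = spec)
}

#' Transmission function of a projected potential
#'
#' `T = exp(i sigma P_re - P_im)` with `P_re` the projected real potential
#' (V * Angstrom) and `P_im` the projected absorptive part (dimensionless).
#' A zero potential yields T identical to 1.
#'
#' @param potential A `potential_map`.
#' @param geom An `experiment_geometry` (supplies the interaction constant).
#' @return An `object_field`.
#' @export
potential_to_transmission <- function(potential, geom) {
  stopifnot(inherits(potential, "potential_map"))
  sigma <- interaction_constant(geom$energy_kev)
  dz <- potential$slice_thickness
  p_re <- apply(potential$real, c(1, 2), sum) * dz
  p_im <- apply(potential$imag, c(1, 2), sum) * dz
  object_field(exp(1i * sigma * p_re - p_im), potential$voxel_size)
}
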