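#' Complex field on a square raster
#'
#' Carrier for probes, transmission functions and exit waves: a complex matrix
#' with a pixel size in Angstrom. Index (1,1) is the top-left corner; positions
#' are row-major pixel offsets.
#'
#' @param values Complex (or numeric) matrix; all entries must be finite.
#' @param pixel_size Pixel size in Angstrom, > 0.
#' @return An object of class `complex_field`.
#' @export
complex_field <- function(values, pixel_size) {
  if (!is.matrix(values)) stop("`values` must be a matrix", call. = FALSE)
  values <- matrix(as.complex(values), nrow(values), ncol(values))
  if (any(!is.finite(Re(values))) || any(!is.finite(Im(values)))) {
    stop("field values must be finite", call. = FALSE)
  }
  if (!is.numeric(pixel_size) || length(pixel_size) != 1L || pixel_size <= 0) {
    stop("`pixel_size` must be a single positive number", call. = FALSE)
  }
  structure(list(values = values, pixel_size = pixel_size),
            class = "complex_field")
}

#' @export
print.complex_field <- function(x, ...) {
  cat(sprintf("<complex_field> %d x %d px @ %.4f A, total |.|^2 = %.6g\n",
              nrow(x$values), ncol(x$values), x$pixel_size,
              sum(Mod(x$values)^2)))
  invisible(x)
}

field_values <- function(x) {
  if (inherits(x, "complex_field")) x$values else x
}

#' Band-limited Fresnel (angular-spectrum paraxial) propagation
#'
#' Propagates a complex field by a distance `z` using the Fourier-space
#' Fresnel transfer function H(q) = exp(-i pi lambda z |q|^2). Frequencies
#' beyond `band_limit` of Nyquist are zeroed to suppress aliasing of the
#' chirp; a field whose spectrum lies inside the band propagates unitarily and
#' exactly reversibly (propagating by +z then -z recovers the input).
#'
#' @param field A `complex_field`.
#' @param z Propagation distance in Angstrom (may be negative).
#' @param wavelength Electron wavelength in Angstrom.
#' @param band_limit Fraction of Nyquist retained (default 2/3).
#' @return The propagated `complex_field`.
#' @export
fresnel_propagate <- function(field, z, wavelength, band_limit = 2 / 3) {
  stopifnot(inherits(field, "complex_field"))
  n <- nrow(field$values)
  q <- radial_freq_grid(n, field$pixel_size)
  h <- exp(-1i * pi * wavelength * z * q^2)
  q_ny <- 1 / (2 * field$pixel_size)
  h[q > band_limit * q_ny] <- 0
  out <- ifft2u(fft2u(field$values) * h)
  complex_field(out, field$pixel_size)
}

#' Crop a margin from a field
#'
#' Removes `margin` pixels from every edge. Used as the evaluation window for
#' reconstruction metrics: the border of the scanned region receives far less
#' illumination than the interior (single-patch coverage with weak probe
#' tails), so its pixels are poorly constrained by the data and are excluded
#' from quantitative comparisons by convention.
#'
#' @param x A `complex_field` or matrix.
#' @param margin Pixels to remove per edge.
#' @return Same type as the input.
#' @export
crop_field <- function(x, margin) {
  margin <- as.integer(margin)
  v <- field_values(x)
  if (2 * margin >= min(dim(v))) stop("margin too large", call. = FALSE)
  idx_r <- seq.int(margin + 1L, nrow(v) - margin)
  idx_c <- seq.int(margin + 1L, ncol(v) - margin)
  out <- v[idx_r, idx_c, drop = FALSE]
  if (inherits(x, "complex_field")) complex_field(out, x$pixel_size) else out
}

# Align the global complex scale of `model` to `truth`: returns c*model with
# c = <model, truth> / ||model||^2, the least-squares optimal gauge.
align_global_scale <- function(truth, model) {
  t_v <- field_values(truth); m_v <- field_values(model)
  denom <- sum(Mod(m_v)^2)
  if (denom == 0) return(m_v)
  c_opt <- sum(Conj(m_v) * t_v) / denom
  c_opt * m_v
}
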