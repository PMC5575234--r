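# Dose calibration and the detector measurement model: DQE shaping in Fourier
# space, Poisson shot noise, NTF convolution.

#' Detector response (DQE / NTF radial tables)
#'
#' Radial tables of the detective quantum efficiency and the noise transfer
#' function on fractional-Nyquist frequency (0 = DC, 1 = Nyquist; the table
#' must extend to sqrt(2) to cover array corners). Values are interpolated
#' linearly. The bundled default is a smooth parametric counting-detector-like
#' curve stored as editable CSV (`system.file("extdata",
#' "detector_response_k2like_synthetic.csv", package = "eptycho")`); published
#' curves for a specific camera can be dropped in the same format.
#'
#' @param table Data frame with columns `freq`, `dqe`, `ntf`; `NULL` loads the
#'   bundled table.
#' @return An object of class `detector_response`.
#' @export
detector_response <- function(table = NULL) {
  if (is.null(table)) {
    path <- system.file("extdata", "detector_response_k2like_synthetic.csv",
                        package = "eptycho")
    table <- utils::read.csv(path)
  }
  stopifnot(all(c("freq", "dqe", "ntf") %in% names(table)))
  if (max(table$freq) < sqrt(2) - 1e-9) {
    stop("response table must cover frequencies up to sqrt(2) * Nyquist", call. = FALSE)
  }
  with_range <- function(x) all(x >= 0 & x <= 1)
  if (!with_range(table$dqe) || !with_range(table$ntf)) {
    stop("DQE and NTF values must lie in [0, 1]", call. = FALSE)
  }
  if (table$dqe[1] <= 0 || table$ntf[1] <= 0) {
    stop("DQE(0) and NTF(0) must be positive", call. = FALSE)
  }
  structure(list(freq = table$freq, dqe = table$dqe, ntf = table$ntf),
            class = "detector_response")
}

#' Identity detector response
#'
#' DQE and NTF identical to 1 — the default on the reconstruction path, where
#' heavy detector binning makes the response near-ideal.
#'
#' @return A `detector_response`.
#' @export
identity_response <- function() {
  detector_response(data.frame(freq = c(0, sqrt(2)), dqe = c(1, 1), ntf = c(1, 1)))
}

response_on_grid <- function(response, n, what = c("dqe", "ntf")) {
  what <- match.arg(what)
  f <- radial_freq_grid(n, 1) / 0.5 # fractional Nyquist
  vals <- stats::approx(response$freq, response[[what]], xout = as.vector(f),
                        rule = 2)$y
  matrix(vals, n, n)
}

#' Scale a noise-free stack to a target dose
#'
#' Rescales the stack by a single factor so that the mean electrons per
#' pattern equals `dose * (step * r_d)^2`, i.e. the dose times the specimen
#' area advanced per scan position. Also records the mean electrons per
#' detector pixel and the electrons per image pixel (`dose * r_d^2`).
#'
#' @param stack A noise-free `diffraction_stack`.
#' @param dose Electron dose in e-/A^2, >= 0.
#' @param scanplan The `scan_plan` used (supplies the step).
#' @param geom The `experiment_geometry` (supplies r_d).
#' @param probe Optional `probe_field`: when given, the target counts refer to
#'   the electrons incident on the specimen (the probe total), preserving the
#'   specimen's attenuation contrast; otherwise the mean pattern total is
#'   normalized to the target.
#' @return The rescaled `diffraction_stack` with dose attributes filled in,
#'   including `e_per_detector_pixel` and `e_per_image_pixel`.
#' @export
scale_to_dose <- function(stack, dose, scanplan, geom, probe = NULL) {
  stopifnot(inherits(stack, "diffraction_stack"), inherits(scanplan, "scan_plan"))
  if (!is.numeric(dose) || length(dose) != 1L || dose < 0) {
    stop("`dose` must be a single nonnegative number", call. = FALSE)
  }
  r_d <- geom$image_pixel_size
  target <- dose * (scanplan$step * r_d)^2
  ref_total <- if (is.null(probe)) mean(apply(stack$data, 3, sum))
               else sum(Mod(probe_values(probe))^2)
  data <- if (ref_total > 0) stack$data * (target / ref_total)
          else stack$data * 0
  out <- diffraction_stack(data, dose = dose, electrons_per_pattern = target,
                           pixel_size = r_d)
  out$e_per_detector_pixel <- target / out$M
  out$e_per_image_pixel <- dose * r_d^2
  out
}

#' Apply the detector model to a noise-free stack
#'
#' Per pattern: filter the intensity by sqrt(DQE) in Fourier space (clipping
#' small negative ringing to zero), draw Poisson counts, and convolve with the
#' NTF in Fourier space. Each pattern uses an independent random substream
#' derived from `seed`, so results are reproducible per (seed, pattern).
#'
#' @param stack A noise-free `diffraction_stack`.
#' @param response A `detector_response` (default identity).
#' @param seed Integer seed.
#' @return A `diffraction_stack` of measured counts.
#' @export
apply_detector <- function(stack, response = identity_response(), seed = 1L) {
  stopifnot(inherits(stack, "diffraction_stack"))
  n <- dim(stack$data)[1]
  dqe_f <- sqrt(response_on_grid(response, n, "dqe"))
  ntf_f <- response_on_grid(response, n, "ntf")
  identity_dqe <- all(abs(dqe_f - 1) < 1e-12)
  identity_ntf <- all(abs(ntf_f - 1) < 1e-12)
  set.seed(seed)
  substreams <- sample.int(.Machine$integer.max - 1L, stack$K)
  out <- stack$data
  for (k in seq_len(stack$K)) {
    i0 <- stack$data[, , k]
    if (!identity_dqe) {
      i0 <- Re(stats::fft(stats::fft(i0) * dqe_f, inverse = TRUE)) / length(i0)
      i0[i0 < 0] <- 0
    }
    set.seed(substreams[k])
    counts <- matrix(stats::rpois(length(i0), as.vector(i0)), n, n)
    if (!identity_ntf) {
      counts <- Re(stats::fft(stats::fft(counts) * ntf_f, inverse = TRUE)) / length(counts)
      counts[counts < 0] <- 0
    }
    out[, , k] <- counts
  }
  diffraction_stack(out, dose = stack$dose,
                    electrons_per_pattern = stack$electrons_per_pattern,
                    pixel_size = stack$pixel_size)
}
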