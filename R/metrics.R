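# Quantitative evaluation: Fourier ring correlation with information-theoretic
# thresholds, spectral SNR, gauge-aligned NRMSE, and averaging of independent
# reconstructions.

ring_index <- function(n, ring_width = 1) {
  c0 <- floor(n / 2) + 1L
  rr <- outer((seq_len(n) - c0)^2, (seq_len(n) - c0)^2, `+`)
  as.integer(round(sqrt(rr) / ring_width))
}

#' Fourier ring correlation of two images
#'
#' Per-ring normalized cross-correlation of the two spectra, with the 1-bit
#' and 1/2-bit information threshold curves computed from the per-ring sample
#' counts. Rings are `ring_width` reciprocal pixels wide. The inputs may be
#' real or complex matrices or `complex_field`s with equal shapes and pixel
#' sizes.
#'
#' @param a,b Matrices or `complex_field`s.
#' @param ring_width Ring width in reciprocal pixels (default 1).
#' @param pixel_size Pixel size in Angstrom (taken from the fields if
#'   available).
#' @return An object of class `frc_curve`: a data frame with columns `freq`
#'   (1/Angstrom), `frc`, `n` (pixels per ring), `one_bit`, `half_bit`.
#' @export
frc <- function(a, b, ring_width = 1, pixel_size = NULL) {
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(a, "complex_field")) a$pixel_size else 1
  }
  av <- field_values(a); bv <- field_values(b)
  if (!all(dim(av) == dim(bv))) stop("images must have equal shapes", call. = FALSE)
  n <- nrow(av)
  fa <- fftshift2(fft2u(as.matrix(av)))
  fb <- fftshift2(fft2u(as.matrix(bv)))
  ring <- ring_index(n, ring_width)
  rmax <- floor(n / 2)
  keep <- ring <= rmax
  idx <- factor(ring[keep], levels = 0:rmax)
  num <- tapply(Re(fa[keep] * Conj(fb[keep])), idx, sum)
  pa <- tapply(Mod(fa[keep])^2, idx, sum)
  pb <- tapply(Mod(fb[keep])^2, idx, sum)
  count <- as.integer(table(idx))
  denom <- sqrt(pa * pb)
  corr <- ifelse(denom > 0, num / denom, 0)
  nn <- pmax(count, 1L)
  one_bit <- (0.5 + 2.4142 / sqrt(nn)) / (1.5 + 1.4142 / sqrt(nn))
  half_bit <- (0.2071 + 1.9102 / sqrt(nn)) / (1.2071 + 0.9102 / sqrt(nn))
  out <- data.frame(freq = (0:rmax) * ring_width / (n * pixel_size),
                    frc = as.numeric(corr), n = count,
                    one_bit = one_bit, half_bit = half_bit)
  class(out) <- c("frc_curve", class(out))
  attr(out, "pixel_size") <- pixel_size
  out
}

#' Resolution from an FRC curve
#'
#' Half-period resolution at the first crossing of the chosen threshold,
#' linearly interpolated between rings. Without a crossing the
#' diffraction-limit ring is returned and flagged; a curve already below
#' threshold at the first ring returns `Inf` (no resolution information).
#'
#' @param curve An `frc_curve`.
#' @param criterion `"half_bit"`, `"one_bit"` or `"fixed"`.
#' @param fixed_value Threshold used when `criterion = "fixed"`.
#' @return A list with `resolution` (Angstrom), `frequency` (1/Angstrom) and
#'   `no_crossing` (logical).
#' @export
resolution_from_frc <- function(curve, criterion = c("half_bit", "one_bit", "fixed"),
                                fixed_value = 0.5) {
  criterion <- match.arg(criterion)
  if (!inherits(curve, "frc_curve") || nrow(curve) == 0) {
    stop("`curve` must be a non-empty frc_curve", call. = FALSE)
  }
  thr <- switch(criterion,
                half_bit = curve$half_bit,
                one_bit = curve$one_bit,
                fixed = rep(fixed_value, nrow(curve)))
  diffv <- curve$frc - thr
  # ring 0 (n = 1) has a degenerate threshold and is excluded; a curve
  # already below threshold at the first ring carries no resolution
  # information and scores Inf (callers cap at their field extent)
  if (nrow(curve) >= 2 && diffv[2] < 0) {
    return(list(resolution = Inf, frequency = 0, no_crossing = FALSE))
  }
  below <- which(diffv < 0 & seq_len(nrow(curve)) > 2L)
  if (length(below) == 0) {
    fmax <- max(curve$freq)
    return(list(resolution = 1 / fmax, frequency = fmax, no_crossing = TRUE))
  }
  k <- below[1]
  f0 <- curve$freq[k - 1]; f1 <- curve$freq[k]
  d0 <- diffv[k - 1]; d1 <- diffv[k]
  fx <- f0 + (f1 - f0) * d0 / (d0 - d1)
  list(resolution = 1 / fx, frequency = fx, no_crossing = FALSE)
}

#' Spectral signal-to-noise ratio in dB
#'
#' Per-ring `10 log10( sum |F[T]|^2 / sum |F[T] - F[T_model]|^2 )`, capped at
#' +/- `cap` dB. The model's global complex scale is aligned to the truth
#' first (the metric is gauge-dependent otherwise); set `align = FALSE` for
#' the raw ratio.
#'
#' @param truth,model Matrices or `complex_field`s of equal shape.
#' @param ring_width Ring width in reciprocal pixels.
#' @param align Align the global complex scale first (default TRUE).
#' @param cap Cap in dB (default 120).
#' @param pixel_size Pixel size in Angstrom.
#' @return An `snr_curve` data frame with columns `freq` and `snr_db`.
#' @export
snr_db <- function(truth, model, ring_width = 1, align = TRUE, cap = 120,
                   pixel_size = NULL) {
  if (is.null(pixel_size)) {
    pixel_size <- if (inherits(truth, "complex_field")) truth$pixel_size else 1
  }
  tv <- field_values(truth)
  mv <- if (align) align_global_scale(truth, model) else field_values(model)
  if (!all(dim(tv) == dim(mv))) stop("images must have equal shapes", call. = FALSE)
  n <- nrow(tv)
  ft <- fftshift2(fft2u(as.matrix(tv)))
  fd <- ft - fftshift2(fft2u(as.matrix(mv)))
  ring <- ring_index(n, ring_width)
  rmax <- floor(n / 2)
  keep <- ring <= rmax
  idx <- factor(ring[keep], levels = 0:rmax)
  sig <- tapply(Mod(ft[keep])^2, idx, sum)
  noise <- tapply(Mod(fd[keep])^2, idx, sum)
  val <- ifelse(noise > 0, 10 * log10(sig / noise), cap)
  val[sig == 0 & noise == 0] <- cap
  val <- pmin(pmax(val, -cap), cap)
  out <- data.frame(freq = (0:rmax) * ring_width / (n * pixel_size),
                    snr_db = as.numeric(val))
  class(out) <- c("snr_curve", class(out))
  out
}

#' Gauge-aligned normalized root-mean-square error
#'
#' `min over complex c of ||truth - c model|| / ||truth||` with the
#' closed-form optimal scale; invariant to a global phase and scale of the
#' model.
#'
#' @param truth,model Matrices or `complex_field`s of equal shape.
#' @return Scalar NRMSE.
#' @export
nrmse <- function(truth, model) {
  tv <- field_values(truth); mv <- field_values(model)
  if (!all(dim(tv) == dim(mv))) stop("images must have equal shapes", call. = FALSE)
  t_norm <- sqrt(sum(Mod(tv)^2))
  if (t_norm == 0) stop("truth is identically zero", call. = FALSE)
  aligned <- align_global_scale(tv, mv)
  sqrt(sum(Mod(tv - aligned)^2)) / t_norm
}

#' Average independent reconstructions
#'
#' Aligns each field's global complex scale to the first, averages, and also
#' returns the split-half FRC between the averages of the two halves of the
#' list (the resolution estimate used when averaging many independent
#' low-dose reconstructions).
#'
#' @param fields List of >= 2 complex matrices or `complex_field`s of equal
#'   shape.
#' @param ring_width Ring width for the split-half FRC.
#' @return List with `average` (a `complex_field`), `frc` (the split-half
#'   `frc_curve`) and `n` (number of fields averaged).
#' @export
average_reconstructions <- function(fields, ring_width = 1) {
  if (!is.list(fields) || length(fields) < 2) {
    stop("need at least two fields to average", call. = FALSE)
  }
  px <- if (inherits(fields[[1]], "complex_field")) fields[[1]]$pixel_size else 1
  ref <- field_values(fields[[1]])
  aligned <- lapply(fields, function(f) align_global_scale(ref, f))
  dims <- dim(aligned[[1]])
  if (!all(vapply(aligned, function(a) all(dim(a) == dims), logical(1)))) {
    stop("fields must have equal shapes", call. = FALSE)
  }
  avg <- Reduce(`+`, aligned) / length(aligned)
  h <- floor(length(aligned) / 2)
  avg1 <- Reduce(`+`, aligned[seq_len(h)]) / h
  avg2 <- Reduce(`+`, aligned[seq.int(h + 1, length(aligned))]) / (length(aligned) - h)
  list(average = complex_field(avg, px),
       frc = frc(avg1, avg2, ring_width = ring_width, pixel_size = px),
       n = length(aligned))
}
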