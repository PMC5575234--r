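# Sparse-prior denoiser plug-in: the complex iterate is mapped to three real
# channels by domain coloring (phase -> hue, amplitude -> value,
# saturation = 1), each channel is denoised in RGB space, and the result is
# mapped back to a complex field. The bundled default denoiser is Haar
# wavelet soft-thresholding; an external denoiser (e.g. a full BM3D binding)
# can be plugged in as a plain matrix -> matrix function.

hsv_to_rgb <- function(h, s, v) {
  # vectorized standard HSV -> RGB on [0,1] channels
  h6 <- (h %% 1) * 6
  i <- floor(h6)
  f <- h6 - i
  p <- v * (1 - s); q <- v * (1 - s * f); t <- v * (1 - s * (1 - f))
  r <- ifelse(i == 0, v, ifelse(i == 1, q, ifelse(i == 2, p,
       ifelse(i == 3, p, ifelse(i == 4, t, v)))))
  g <- ifelse(i == 0, t, ifelse(i == 1, v, ifelse(i == 2, v,
       ifelse(i == 3, q, ifelse(i == 4, p, p)))))
  b <- ifelse(i == 0, p, ifelse(i == 1, p, ifelse(i == 2, t,
       ifelse(i == 3, v, ifelse(i == 4, v, q)))))
  list(r = r, g = g, b = b)
}

#' Domain-coloring channels of a complex field
#'
#' Maps a complex matrix to RGB channel matrices: hue = (Arg + pi) / 2 pi,
#' value = |z| / max |z|, saturation = 1.
#'
#' @param z Complex matrix.
#' @return List with matrices `r`, `g`, `b` and the scale `vmax`.
#' @export
domain_color_channels <- function(z) {
  vmax <- max(Mod(z))
  if (vmax == 0) vmax <- 1
  h <- (Arg(z) + pi) / (2 * pi)
  v <- Mod(z) / vmax
  rgb <- hsv_to_rgb(as.vector(h), 1, as.vector(v))
  d <- dim(z)
  list(r = matrix(rgb$r, d[1], d[2]), g = matrix(rgb$g, d[1], d[2]),
       b = matrix(rgb$b, d[1], d[2]), vmax = vmax)
}

#' Reassemble a complex field from domain-coloring channels
#'
#' Inverse of [domain_color_channels()]: hue and value are recovered through
#' the RGB -> HSV conversion and mapped back to phase and amplitude.
#'
#' @param channels List with `r`, `g`, `b`, `vmax`.
#' @return Complex matrix.
#' @export
channels_to_field <- function(channels) {
  d <- dim(channels$r)
  rgb <- rbind(as.vector(channels$r), as.vector(channels$g), as.vector(channels$b))
  rgb[rgb < 0] <- 0; rgb[rgb > 1] <- 1
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 1)
  amp <- hsv["v", ] * channels$vmax
  phase <- hsv["h", ] * 2 * pi - pi
  matrix(complex(modulus = amp, argument = phase), d[1], d[2])
}

# ---- Haar wavelet soft-thresholding ----------------------------------------

haar_step <- function(x) {
  # one analysis level along both axes; x must have even dimensions
  er <- seq(1, nrow(x), by = 2); or_ <- er + 1
  lo <- (x[er, , drop = FALSE] + x[or_, , drop = FALSE]) / sqrt(2)
  hi <- (x[er, , drop = FALSE] - x[or_, , drop = FALSE]) / sqrt(2)
  ec <- seq(1, ncol(lo), by = 2); oc <- ec + 1
  list(ll = (lo[, ec, drop = FALSE] + lo[, oc, drop = FALSE]) / sqrt(2),
       lh = (lo[, ec, drop = FALSE] - lo[, oc, drop = FALSE]) / sqrt(2),
       hl = (hi[, ec, drop = FALSE] + hi[, oc, drop = FALSE]) / sqrt(2),
       hh = (hi[, ec, drop = FALSE] - hi[, oc, drop = FALSE]) / sqrt(2))
}

haar_unstep <- function(w) {
  lo <- matrix(0, nrow(w$ll), 2 * ncol(w$ll))
  hi <- lo
  ec <- seq(1, ncol(lo), by = 2); oc <- ec + 1
  lo[, ec] <- (w$ll + w$lh) / sqrt(2); lo[, oc] <- (w$ll - w$lh) / sqrt(2)
  hi[, ec] <- (w$hl + w$hh) / sqrt(2); hi[, oc] <- (w$hl - w$hh) / sqrt(2)
  x <- matrix(0, 2 * nrow(lo), ncol(lo))
  er <- seq(1, nrow(x), by = 2); or_ <- er + 1
  x[er, ] <- (lo + hi) / sqrt(2); x[or_, ] <- (lo - hi) / sqrt(2)
  x
}

soft_threshold <- function(x, lambda) sign(x) * pmax(abs(x) - lambda, 0)

#' Haar wavelet soft-thresholding denoiser
#'
#' Multi-level 2D Haar decomposition with soft thresholding of the detail
#' subbands at the universal threshold `sigma * sqrt(2 log N)`; the noise
#' level sigma is estimated from the median absolute deviation of the finest
#' diagonal subband. Arbitrary sizes are handled by symmetric padding to the
#' next power of two.
#'
#' @param x Numeric matrix.
#' @param nlevels Number of decomposition levels (default 5, capped by the
#'   grid size); deep decompositions also regularize the coarse, weakly
#'   constrained spatial frequencies.
#' @param sigma Optional noise standard deviation; estimated if `NULL`.
#' @return The denoised matrix.
#' @export
denoise_wavelet <- function(x, nlevels = 5L, sigma = NULL) {
  d <- dim(x)
  n2 <- 2^ceiling(log2(max(d)))
  pad <- function(v, n) {
    idx <- seq_len(n)
    # symmetric (reflect) extension
    period <- c(seq_len(length(v)), rev(seq_len(length(v))))
    period[(idx - 1L) %% length(period) + 1L]
  }
  xp <- x[pad(seq_len(d[1]), n2), pad(seq_len(d[2]), n2)]
  nlevels <- min(nlevels, floor(log2(n2)) - 1L)
  coeffs <- list()
  ll <- xp
  for (l in seq_len(nlevels)) {
    w <- haar_step(ll)
    coeffs[[l]] <- w[c("lh", "hl", "hh")]
    ll <- w$ll
  }
  if (is.null(sigma)) {
    sigma <- stats::median(abs(coeffs[[1]]$hh)) / 0.6745
  }
  lambda <- sigma * sqrt(2 * log(n2 * n2))
  for (l in seq_len(nlevels)) {
    coeffs[[l]] <- lapply(coeffs[[l]], soft_threshold, lambda = lambda)
  }
  for (l in rev(seq_len(nlevels))) {
    ll <- haar_unstep(c(list(ll = ll), coeffs[[l]]))
  }
  ll[seq_len(d[1]), seq_len(d[2])]
}

#' Refresh the sparse-prior reference (denoiser state)
#'
#' Produces `T_sparse`, the denoised version of the current iterate used by
#' the sparse prior: the complex field is domain-colored into RGB channels,
#' each channel is denoised, and the channels are mapped back.
#'
#' @param object Complex matrix or field (the current iterate).
#' @param denoiser_id `"wavelet"` (default), `"identity"`, or a function
#'   taking and returning a numeric matrix (a plugged-in channel denoiser).
#' @param refresh_interval Iterations between refreshes (stored in the state).
#' @return An object of class `denoiser_state` with elements `t_sparse`,
#'   `denoiser_id`, `refresh_interval`.
#' @export
refresh_denoiser <- function(object, denoiser_id = "wavelet",
                             refresh_interval = 10L) {
  z <- field_values(object)
  den <- if (is.function(denoiser_id)) {
    denoiser_id
  } else if (identical(denoiser_id, "identity")) {
    identity
  } else if (identical(denoiser_id, "wavelet")) {
    denoise_wavelet
  } else {
    stop(sprintf("unknown denoiser '%s'", denoiser_id), call. = FALSE)
  }
  ch <- domain_color_channels(z)
  ch$r <- den(ch$r); ch$g <- den(ch$g); ch$b <- den(ch$b)
  structure(list(t_sparse = channels_to_field(ch),
                 denoiser_id = denoiser_id,
                 refresh_interval = as.integer(refresh_interval)),
            class = "denoiser_state")
}
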