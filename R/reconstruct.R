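# Non-convex Bayesian reconstruction of the transmission function from
# Poisson-distributed diffraction counts: truncated Poisson-likelihood
# Wirtinger gradients, Tikhonov or sparse-denoiser priors, Polak-Ribiere
# conjugate-gradient updates with Armijo backtracking, and spectral or
# random initialization.

#' Reconstruction configuration
#'
#' @param mu0 Tikhonov prior weight (default 1e-2).
#' @param mu1 Sparse-prior weight (default 8e-2).
#' @param alpha_h Gradient-truncation parameter (default 5; `Inf` disables
#'   truncation).
#' @param alpha0 Optional parameter of the alternative count-based spectral
#'   truncation rule (unused by the default percentile rule).
#' @param max_iters Maximum CG iterations (default 200).
#' @param rel_tol Relative objective-change stopping tolerance (default 1e-7).
#' @param init_mode `"random"` (recommended below ~100 e-/A^2) or
#'   `"spectral"`.
#' @param power_iters Power iterations for spectral initialization (default 70).
#' @param spectral_percentile Intensity percentile above which measurements
#'   contribute to the spectral initializer (default 80: the top 20%).
#' @param seed Seed for the initializer.
#' @param prior `"none"`, `"tikhonov"` or `"sparse"`.
#' @param denoiser_id Denoiser for the sparse prior (see [refresh_denoiser()]).
#' @param refresh_interval Iterations between denoiser refreshes (default 10).
#' @return A list of class `recon_config`.
#' @export
recon_config <- function(mu0 = 1e-2, mu1 = 8e-2, alpha_h = 5, alpha0 = NULL,
                         max_iters = 200L, rel_tol = 1e-7,
                         init_mode = c("random", "spectral"),
                         power_iters = 70L, spectral_percentile = 80,
                         seed = 1L, prior = c("tikhonov", "none", "sparse"),
                         denoiser_id = "wavelet", refresh_interval = 10L) {
  stopifnot(mu0 >= 0, mu1 >= 0, alpha_h > 0,
            spectral_percentile > 0, spectral_percentile < 100)
  structure(list(mu0 = mu0, mu1 = mu1, alpha_h = alpha_h, alpha0 = alpha0,
                 max_iters = as.integer(max_iters), rel_tol = rel_tol,
                 init_mode = match.arg(init_mode),
                 power_iters = as.integer(power_iters),
                 spectral_percentile = spectral_percentile,
                 seed = as.integer(seed), prior = match.arg(prior),
                 denoiser_id = denoiser_id,
                 refresh_interval = as.integer(refresh_interval)),
            class = "recon_config")
}

# Small positive floor inside log(): 1e-12 of the mean nonzero model intensity.
intensity_floor <- function(intensity) {
  pos <- intensity[intensity > 0]
  if (length(pos) == 0) return(1e-300)
  1e-12 * mean(pos)
}

#' Poisson negative log-likelihood of the measurements
#'
#' `sum_i [ I_i - y_i log(I_i) ]` over all KM measurements, with the model
#' intensity floored at a small epsilon inside the log to remain finite at
#' zero model intensity. Terms with `y_i = 0` reduce to `I_i` exactly.
#'
#' @param object Complex matrix or field (the transmission iterate).
#' @param y Measured counts: a `diffraction_stack` or (m, m, K) array.
#' @param op A `forward_operator`.
#' @return The scalar negative log-likelihood.
#' @export
poisson_nll <- function(object, y, op) {
  yv <- stack_values(y)
  a <- op_forward(op, object)
  if (!all(dim(yv) == dim(a))) stop("measurement shape mismatch", call. = FALSE)
  intensity <- Mod(a)^2
  ifl <- pmax(intensity, intensity_floor(intensity))
  sum(ifl - yv * log(ifl))
}

# Shared plumbing: forward pass and floored intensities.
forward_state <- function(object, y, op) {
  yv <- stack_values(y)
  a <- op_forward(op, object)
  if (!all(dim(yv) == dim(a))) stop("measurement shape mismatch", call. = FALSE)
  intensity <- Mod(a)^2
  list(y = yv, a = a, intensity = intensity,
       ifl = pmax(intensity, intensity_floor(intensity)))
}

#' Wirtinger gradient of the Poisson negative log-likelihood
#'
#' `P^H [ (1 - y / |P T|^2) (P T) ]`, assembled through the operator adjoint.
#' The gradient vanishes when the measurements equal the model intensities.
#' (Real/imaginary partial derivatives of the objective equal twice the real
#' and imaginary parts of this gradient.)
#'
#' @inheritParams poisson_nll
#' @return Complex gradient matrix on the object grid.
#' @export
likelihood_gradient <- function(object, y, op) {
  st <- forward_state(object, y, op)
  op_adjoint(op, (1 - st$y / st$ifl) * st$a)
}

#' Measurement-truncation set
#'
#' Boolean mask over the KM measurements retaining those compatible with the
#' current iterate:
#' `|y_i - I_i| <= (alpha_h / KM) * ||y - I||_1 * sqrt(I_i) / ||T||_2`.
#' Exactly consistent measurements are always retained, and the retained
#' fraction is non-decreasing in `alpha_h`.
#'
#' @inheritParams poisson_nll
#' @param alpha_h Truncation parameter (>= 5 recommended).
#' @return Logical (m, m, K) array with attribute `retained_fraction`.
#' @export
truncation_set <- function(object, y, op, alpha_h = 5) {
  t_v <- field_values(object)
  t_norm <- sqrt(sum(Mod(t_v)^2))
  if (t_norm == 0) stop("truncation is undefined for a zero object", call. = FALSE)
  st <- forward_state(object, y, op)
  resid <- abs(st$y - st$intensity)
  km <- length(st$y)
  bound <- (alpha_h / km) * sum(resid) * sqrt(st$intensity) / t_norm
  mask <- resid <= bound
  attr(mask, "retained_fraction") <- mean(mask)
  mask
}

#' Truncated likelihood gradient
#'
#' The likelihood gradient restricted to the truncation set; equals the full
#' gradient when every measurement is retained. An empty set yields a zero
#' gradient with a warning.
#'
#' @inheritParams truncation_set
#' @return Complex gradient matrix with attribute `retained_fraction`.
#' @export
truncated_likelihood_gradient <- function(object, y, op, alpha_h = 5) {
  mask <- truncation_set(object, y, op, alpha_h)
  if (!any(mask)) {
    warning("truncation set is empty; returning a zero gradient", call. = FALSE)
    g <- matrix(0i, op$object_dim[1], op$object_dim[2])
    attr(g, "retained_fraction") <- 0
    return(g)
  }
  st <- forward_state(object, y, op)
  w <- (1 - st$y / st$ifl)
  w[!mask] <- 0
  g <- op_adjoint(op, w * st$a)
  attr(g, "retained_fraction") <- attr(mask, "retained_fraction")
  g
}

# ---- priors -----------------------------------------------------------------

fdiff_rows <- function(x) {
  d <- x[-1, , drop = FALSE] - x[-nrow(x), , drop = FALSE]
  rbind(d, matrix(0, 1, ncol(x))) # replicate boundary: zero last difference
}

fdiff_rows_adj <- function(u) {
  # adjoint of fdiff_rows (with the zero last row convention)
  n <- nrow(u)
  out <- matrix(0i, n, ncol(u))
  out[1, ] <- -u[1, ]
  if (n > 2) out[2:(n - 1), ] <- u[1:(n - 2), , drop = FALSE] - u[2:(n - 1), , drop = FALSE]
  out[n, ] <- u[n - 1, ]
  out
}

#' Scaling constant of the Tikhonov prior
#'
#' `kappa = 8 N_pix^2 / (N_m ||I||_1)` with `N_pix^2` the detector pixel
#' count M, `N_m = K M` the number of valid measurements and `||I||_1` the
#' total measured intensity. This scales the prior to the numerical range of
#' the likelihood so that `mu0` can stay in the 1e-2 to 1e-1 range.
#'
#' @param y A `diffraction_stack` or (m, m, K) array of measurements.
#' @return The scalar kappa.
#' @export
kappa_scale <- function(y) {
  yv <- stack_values(y)
  m_pix <- dim(yv)[1] * dim(yv)[2]
  n_m <- length(yv)
  8 * m_pix / (n_m * sum(yv))
}

#' Tikhonov (gradient-penalty) prior
#'
#' Penalty `(mu0 / kappa) * sum(|D_x T|^2 + |D_y T|^2)` with forward
#' differences and replicate boundary, and its Wirtinger gradient
#' `(mu0 / kappa) (D_x^H D_x + D_y^H D_y) T` (the discrete-Laplacian form
#' that is the true gradient of the penalty).
#'
#' @param object Complex matrix or field.
#' @param mu0 Prior weight.
#' @param kappa Scaling constant from [kappa_scale()].
#' @return List with `penalty` (scalar) and `gradient` (complex matrix).
#' @export
tikhonov_prior <- function(object, mu0, kappa) {
  if (kappa <= 0) stop("`kappa` must be positive", call. = FALSE)
  t_v <- field_values(object)
  dx <- fdiff_rows(t_v)
  dy <- t(fdiff_rows(t(t_v)))
  c0 <- mu0 / kappa
  penalty <- c0 * sum(Mod(dx)^2 + Mod(dy)^2)
  grad <- c0 * (fdiff_rows_adj(dx) + t(fdiff_rows_adj(t(dy))))
  list(penalty = penalty, gradient = grad)
}

#' Sparse (denoiser-reference) prior
#'
#' Penalty `mu1 ||T - T_sparse||^2` and Wirtinger gradient
#' `mu1 (T - T_sparse)` (partial derivatives with respect to the real and
#' imaginary parts are twice the corresponding parts of this gradient, the
#' same convention as the likelihood gradient).
#'
#' @param object Complex matrix or field.
#' @param denoiser_state A `denoiser_state` from [refresh_denoiser()].
#' @param mu1 Prior weight.
#' @return List with `penalty` and `gradient`.
#' @export
sparse_prior <- function(object, denoiser_state, mu1) {
  t_v <- field_values(object)
  ts <- denoiser_state$t_sparse
  if (!all(dim(ts) == dim(t_v))) stop("denoiser state shape mismatch", call. = FALSE)
  delta <- t_v - ts
  list(penalty = mu1 * sum(Mod(delta)^2), gradient = mu1 * delta)
}

# ---- initialization ---------------------------------------------------------

#' Truncated spectral initialization
#'
#' Power iteration on the object-space composition of the masked forward
#' operator, `(Q^H Q)^{-1} Q^H F^H M F Q` with M the indicator of the
#' strongest measurements (those above the configured intensity percentile;
#' exactly `ceiling((1 - p/100) * KM)` entries are retained). The diagonal
#' `(Q^H Q)^{-1}` is the reciprocal summed illumination per object pixel,
#' floored at 1e-6 of its maximum to handle unilluminated pixels. Returns a
#' unit-amplitude transmission carrying the dominant eigenvector's phase;
#' the raw eigenvector is attached as attribute `eigenvector`.
#'
#' @param y Measured counts (`diffraction_stack` or array).
#' @param op A `forward_operator`.
#' @param config A `recon_config` (uses `power_iters`, `spectral_percentile`,
#'   `seed`).
#' @return A `complex_field` initial transmission.
#' @export
spectral_initialize <- function(y, op, config = recon_config()) {
  yv <- stack_values(y)
  if (all(yv <= 0)) stop("spectral initialization needs positive measurements",
                         call. = FALSE)
  km <- length(yv)
  n_keep <- as.integer(ceiling((1 - config$spectral_percentile / 100) * km))
  keep_idx <- order(as.vector(yv), decreasing = TRUE)[seq_len(n_keep)]
  mask <- array(FALSE, dim(yv))
  mask[keep_idx] <- TRUE
  w <- op$illumination
  wf <- pmax(w, 1e-6 * max(w))
  set.seed(config$seed)
  v <- matrix(complex(real = stats::rnorm(op$N), imaginary = stats::rnorm(op$N)),
              op$object_dim[1], op$object_dim[2])
  v <- v / sqrt(sum(Mod(v)^2))
  for (it in seq_len(config$power_iters)) {
    u <- op_forward(op, v)
    u[!mask] <- 0i
    g <- op_adjoint(op, u) / wf
    v <- g / sqrt(sum(Mod(g)^2))
  }
  t0 <- complex_field(exp(1i * Arg(v)), op$pixel_size)
  attr(t0, "eigenvector") <- v
  attr(t0, "n_retained") <- n_keep
  t0
}

#' Random initialization
#'
#' Unity transmission with normally distributed phase (mean 0.1, variance
#' 0.1); the recommended start below about 100 e-/A^2 where the spectral
#' initializer is no longer reliable. Deterministic per seed.
#'
#' @param shape Integer (n1, n2) object shape.
#' @param seed Integer seed.
#' @param phase_mean Mean of the phase distribution (rad).
#' @param phase_var Variance of the phase distribution (rad^2).
#' @param pixel_size Pixel size of the returned field.
#' @return A `complex_field` with |T| = 1 everywhere.
#' @export
random_initialize <- function(shape, seed = 1L, phase_mean = 0.1,
                              phase_var = 0.1, pixel_size = 1) {
  shape <- rep(as.integer(shape), length.out = 2L)
  set.seed(seed)
  phase <- matrix(stats::rnorm(prod(shape), phase_mean, sqrt(phase_var)),
                  shape[1], shape[2])
  complex_field(exp(1i * phase), pixel_size)
}

# ---- the solver -------------------------------------------------------------

#' Reconstruct the transmission function by truncated Poisson MAP
#'
#' Minimizes the MAP objective (Poisson negative log-likelihood plus the
#' selected prior) with Polak-Ribiere conjugate gradients. The search
#' direction is built from the truncated likelihood gradient plus the prior
#' gradient; the Armijo backtracking line search acts on the full objective,
#' so the recorded objective trace is non-increasing (for the sparse prior,
#' within each denoiser-refresh epoch). Falls back to steepest descent when
#' the conjugate direction fails the descent test.
#'
#' @param y Measured counts (`diffraction_stack` or (m, m, K) array).
#' @param probe The known `probe_field`.
#' @param scanplan The `scan_plan` of the measurement.
#' @param config A `recon_config`.
#' @param init Optional initial transmission (complex matrix or field);
#'   otherwise chosen per `config$init_mode`.
#' @return An object of class `recon_state` with fields `object` (a
#'   `complex_field`), `objective_trace`, `truncated_fraction_trace`,
#'   `iterations`, `converged`.
#' @export
reconstruct <- function(y, probe, scanplan, config = recon_config(),
                        init = NULL) {
  op <- forward_operator(probe, scanplan)
  yv <- stack_values(y)
  if (is.null(init)) {
    init <- switch(config$init_mode,
      random = random_initialize(op$object_dim, seed = config$seed,
                                 pixel_size = op$pixel_size),
      spectral = spectral_initialize(yv, op, config)
    )
  }
  t_cur <- field_values(init)
  kappa <- kappa_scale(yv)
  den_state <- NULL
  prior_eval <- function(t_v) {
    switch(config$prior,
      none = list(penalty = 0, gradient = matrix(0i, nrow(t_v), ncol(t_v))),
      tikhonov = tikhonov_prior(t_v, config$mu0, kappa),
      sparse = sparse_prior(t_v, den_state, config$mu1)
    )
  }
  objective <- function(t_v) {
    st <- forward_state(t_v, yv, op)
    sum(st$ifl - yv * log(st$ifl)) + prior_eval(t_v)$penalty
  }
  trace_obj <- numeric(0)
  trace_frac <- numeric(0)
  g_prev <- NULL
  d_prev <- NULL
  alpha <- NULL
  f_cur <- NULL
  iter_done <- 0L
  for (iter in seq_len(config$max_iters)) {
    if (config$prior == "sparse" &&
        (is.null(den_state) || (iter - 1L) %% config$refresh_interval == 0L)) {
      den_state <- refresh_denoiser(t_cur, config$denoiser_id,
                                    config$refresh_interval)
      f_cur <- NULL # objective changes with the refreshed reference
    }
    st <- forward_state(t_cur, yv, op)
    if (is.null(f_cur)) {
      f_cur <- sum(st$ifl - yv * log(st$ifl)) + prior_eval(t_cur)$penalty
    }
    if (!is.finite(f_cur)) {
      stop(structure(class = c("eptycho_divergence", "error", "condition"),
                     list(message = "objective diverged (non-finite value)",
                          call = sys.call(-1), trace = trace_obj)))
    }
    w_full <- 1 - yv / st$ifl
    if (is.finite(config$alpha_h)) {
      t_norm <- sqrt(sum(Mod(t_cur)^2))
      resid <- abs(yv - st$intensity)
      bound <- (config$alpha_h / length(yv)) * sum(resid) *
        sqrt(st$intensity) / t_norm
      mask <- resid <= bound
    } else {
      mask <- array(TRUE, dim(yv))
    }
    frac <- mean(mask)
    pr <- prior_eval(t_cur)
    g_full <- op_adjoint(op, w_full * st$a) + pr$gradient
    w_tr <- w_full
    w_tr[!mask] <- 0
    g_tr <- if (all(mask)) g_full else op_adjoint(op, w_tr * st$a) + pr$gradient
    # Polak-Ribiere direction on the truncated gradient
    if (is.null(d_prev)) {
      d <- -g_tr
    } else {
      beta <- Re(sum(Conj(g_tr) * (g_tr - g_prev))) / sum(Mod(g_prev)^2)
      beta <- max(0, beta)
      d <- -g_tr + beta * d_prev
    }
    slope <- 2 * Re(sum(Conj(g_full) * d))
    if (!is.finite(slope) || slope >= 0) { # restart on non-descent
      d <- -g_full
      slope <- -2 * sum(Mod(g_full)^2)
    }
    if (slope == 0) {
      trace_obj <- c(trace_obj, f_cur); trace_frac <- c(trace_frac, frac)
      iter_done <- iter
      break
    }
    if (is.null(alpha)) {
      alpha <- 0.1 * sqrt(sum(Mod(t_cur)^2)) / sqrt(sum(Mod(d)^2))
    } else {
      alpha <- alpha * 2
    }
    f_new <- Inf
    accepted <- FALSE
    for (ls in seq_len(40L)) {
      t_try <- t_cur + alpha * d
      f_new <- objective(t_try)
      if (is.finite(f_new) && f_new <= f_cur + 1e-4 * alpha * slope) {
        accepted <- TRUE
        break
      }
      alpha <- alpha / 2
    }
    trace_frac <- c(trace_frac, frac)
    if (!accepted) { # no admissible step: converged to line-search precision
      trace_obj <- c(trace_obj, f_cur)
      iter_done <- iter
      break
    }
    t_cur <- t_try
    rel_change <- abs(f_cur - f_new) / max(abs(f_new), 1e-300)
    f_cur <- f_new
    trace_obj <- c(trace_obj, f_cur)
    g_prev <- g_tr
    d_prev <- d
    iter_done <- iter
    if (rel_change < config$rel_tol) break
  }
  structure(list(object = complex_field(t_cur, op$pixel_size),
                 objective_trace = trace_obj,
                 truncated_fraction_trace = trace_frac,
                 iterations = iter_done,
                 converged = iter_done < config$max_iters,
                 config = config),
            class = "recon_state")
}

#' @export
print.recon_state <- function(x, ...) {
  cat(sprintf("<recon_state> %d iterations, objective %.6g -> %.6g, prior '%s'\n",
              x$iterations,
              if (length(x$objective_trace)) x$objective_trace[1] else NA,
              if (length(x$objective_trace)) utils::tail(x$objective_trace, 1) else NA,
              x$config$prior))
  invisible(x)
}
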