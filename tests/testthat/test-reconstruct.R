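test_that("Poisson negative log-likelihood matches the dense oracle", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  op <- tp$op
  obj <- random_object(8, seed = 3)
  y <- Mod(op_forward(op, random_object(8, seed = 4) * 0.9))^2 * 1.2
  # dense brute-force loop over the design-matrix rows
  P <- dense_design_matrix(op)
  iv <- Mod(P %*% as.vector(obj))[, 1]^2
  eps <- 1e-12 * mean(iv[iv > 0])
  ifl <- pmax(iv, eps)
  expect_equal(poisson_nll(obj, y, op), sum(ifl - as.vector(y) * log(ifl)),
               tolerance = 1e-10)
  # y = 0 terms reduce to the model intensity exactly
  expect_equal(poisson_nll(obj, y * 0, op), sum(ifl), tolerance = 1e-10)
  # single consistent measurement: I = y = 1 contributes 1 - log(1) = 1
  one_plan <- scan_plan(c(1, 1), 1L, 1L)
  one_probe <- eptycho:::new_probe_field(matrix(1 + 0i, 1, 1), 1, 1, NA_real_)
  one_op <- forward_operator(one_probe, one_plan)
  expect_equal(poisson_nll(matrix(1 + 0i, 1, 1), array(1, c(1, 1, 1)), one_op), 1)
})

test_that("likelihood gradient matches finite differences and is stationary", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  op <- tp$op
  obj <- random_object(8, seed = 3)
  y <- Mod(op_forward(op, obj * exp(0.1i) + 0.02))^2 * 1.2
  g <- likelihood_gradient(obj, y, op)
  h <- 1e-6
  for (idx in c(1L, 13L, 29L, 40L, 52L, 64L)) {
    e <- matrix(0i, 8, 8); e[idx] <- 1
    fd_re <- (poisson_nll(obj + h * e, y, op) - poisson_nll(obj - h * e, y, op)) / (2 * h)
    fd_im <- (poisson_nll(obj + 1i * h * e, y, op) -
                poisson_nll(obj - 1i * h * e, y, op)) / (2 * h)
    expect_equal(2 * Re(g[idx]), fd_re, tolerance = 1e-5)
    expect_equal(2 * Im(g[idx]), fd_im, tolerance = 1e-5)
  }
  # exact data: gradient vanishes
  y_exact <- Mod(op_forward(op, obj))^2
  expect_lt(max(Mod(likelihood_gradient(obj, y_exact, op))), 1e-10)
  # joint scaling y -> c y, I -> c I scales the gradient by c
  c0 <- 3.7
  g2 <- likelihood_gradient(obj * sqrt(c0), c0 * y, op)
  g1 <- likelihood_gradient(obj, y, op)
  # (1 - y/I) is invariant; the c enters through |p T| = sqrt(c) |p T_0|
  expect_equal(g2, sqrt(c0) * g1, tolerance = 1e-8)
})

test_that("measurement truncation matches the inequality and is monotone", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  op <- tp$op
  obj <- random_object(8, seed = 3)
  y_exact <- Mod(op_forward(op, obj))^2
  m_all <- truncation_set(obj, y_exact, op, 5)
  expect_true(all(m_all))
  expect_equal(attr(m_all, "retained_fraction"), 1)
  y <- y_exact * 1.5 + 0.01
  expect_true(all(truncation_set(obj, y, op, 1e9)))
  # brute-force evaluation of the inequality on a tiny instance
  one_plan <- scan_plan(c(2, 2), 1L, 1L) # 4 positions of a 1x1 probe
  pv <- matrix(2 + 0i, 1, 1)
  one_op <- forward_operator(eptycho:::new_probe_field(pv, 1, 4, NA_real_),
                             structure(list(positions = matrix(c(0L, 0L, 0L, 1L, 1L, 0L),
                                                               3, 2, byrow = TRUE),
                                            step = 1L, K = 3L, probe_dim = 1L,
                                            object_dim = c(2L, 2L)),
                                       class = "scan_plan"))
  tv <- matrix(c(0.5 + 0i, 0.8i, 0.3, 0.9), 2, 2)
  yv <- array(c(0.2, 0.9, 0.05), c(1, 1, 3))
  a_h <- 5
  intens <- as.vector(Mod(op_forward(one_op, tv))^2)
  resid <- abs(as.vector(yv) - intens)
  bound <- (a_h / 3) * sum(resid) * sqrt(intens) / sqrt(sum(Mod(tv)^2))
  manual <- resid <= bound
  got <- truncation_set(tv, yv, one_op, a_h)
  expect_equal(as.vector(got), manual)
  # retained fraction is non-decreasing in alpha_h
  fr <- sapply(c(0.5, 1, 2, 5, 20, 1e6),
               function(a) attr(truncation_set(obj, y, op, a), "retained_fraction"))
  expect_true(all(diff(fr) >= 0))
  expect_error(truncation_set(matrix(0i, 8, 8), y, op), "zero object")
})

test_that("truncated gradient restricts the sum to the retained set", {
  tp <- tiny_operator(n = 8L, m = 4L, step = 2L)
  op <- tp$op
  obj <- random_object(8, seed = 3)
  y <- Mod(op_forward(op, obj * 0.95 + 0.01))^2 * 1.1
  g_full <- likelihood_gradient(obj, y, op)
  g_all <- truncated_likelihood_gradient(obj, y, op, 1e9)
  expect_equal(matrix(g_all, 8, 8), g_full, tolerance = 1e-12)
  # masked dense-oracle comparison
  alpha <- 3
  mask <- truncation_set(obj, y, op, alpha)
  P <- dense_design_matrix(op)
  a <- P %*% as.vector(obj)
  iv <- Mod(a)[, 1]^2
  ifl <- pmax(iv, 1e-12 * mean(iv[iv > 0]))
  w <- (1 - as.vector(y) / ifl) * as.vector(mask)
  g_dense <- Conj(t(P)) %*% (w * a[, 1])
  g_tr <- truncated_likelihood_gradient(obj, y, op, alpha)
  expect_equal(as.vector(g_tr), g_dense[, 1], tolerance = 1e-10)
  # empty retained set: zero gradient with a warning
  expect_warning(g0 <- truncated_likelihood_gradient(obj, y * 50 + 10, op, 1e-12),
                 "empty")
  expect_equal(max(Mod(g0)), 0)
})

test_that("Tikhonov prior gradient is exact and kappa follows its closed form", {
  obj <- random_object(8, seed = 5)
  mu0 <- 0.01; kappa <- 2e-4
  pr <- tikhonov_prior(obj, mu0, kappa)
  pen <- function(t) tikhonov_prior(t, mu0, kappa)$penalty
  h <- 1e-6
  for (idx in c(1L, 9L, 36L, 57L, 64L)) {
    e <- matrix(0i, 8, 8); e[idx] <- 1
    fd_re <- (pen(obj + h * e) - pen(obj - h * e)) / (2 * h)
    fd_im <- (pen(obj + 1i * h * e) - pen(obj - 1i * h * e)) / (2 * h)
    expect_equal(2 * Re(pr$gradient[idx]), fd_re, tolerance = 1e-6)
    expect_equal(2 * Im(pr$gradient[idx]), fd_im, tolerance = 1e-6)
  }
  # constant object: zero penalty and gradient
  const <- matrix(0.7 + 0.2i, 8, 8)
  prc <- tikhonov_prior(const, mu0, kappa)
  expect_equal(prc$penalty, 0)
  expect_equal(max(Mod(prc$gradient)), 0)
  # kappa = 8 N_pix^2 / (N_m ||I||_1) by direct arithmetic
  y <- array(8540 / (128 * 128), c(128, 128, 4))
  expect_equal(kappa_scale(y), 8 * 128^2 / ((128^2 * 4) * (8540 * 4)),
               tolerance = 1e-12)
})

test_that("sparse prior is the quadratic distance to the denoised reference", {
  obj <- random_object(8, seed = 6)
  st <- refresh_denoiser(obj, "identity")
  same <- sparse_prior(obj, st, 0.08)
  expect_equal(same$penalty, 0)
  expect_equal(max(Mod(same$gradient)), 0)
  ref <- refresh_denoiser(random_object(8, seed = 7), "identity")
  p1 <- sparse_prior(obj, ref, 0.08)
  p2 <- sparse_prior(obj, ref, 0.16)
  expect_equal(p2$penalty, 2 * p1$penalty)
  expect_equal(p2$gradient, 2 * p1$gradient)
  # elementwise oracle
  delta <- obj - ref$t_sparse
  expect_equal(p1$penalty, 0.08 * sum(Mod(delta)^2))
  expect_equal(p1$gradient, 0.08 * delta)
  # finite-difference consistency of the gradient convention
  h <- 1e-6; e <- matrix(0i, 8, 8); e[11] <- 1
  fd <- (sparse_prior(obj + h * e, ref, 0.08)$penalty -
           sparse_prior(obj - h * e, ref, 0.08)$penalty) / (2 * h)
  expect_equal(2 * Re(p1$gradient[11]), fd, tolerance = 1e-6)
})

test_that("spectral initialization agrees with a dense eigensolver", {
  plan <- scan_plan(c(4, 4), 2L, 1L)
  probe <- dense_probe(2, electrons = 4, seed = 8)
  op <- forward_operator(probe, plan)
  set.seed(9)
  y <- array(abs(rnorm(op$M * op$K))^2, c(2, 2, op$K))
  cfg <- recon_config(power_iters = 200L, seed = 3)
  t0 <- spectral_initialize(y, op, cfg)
  expect_true(all(abs(Mod(t0$values) - 1) < 1e-12)) # unit amplitude
  # percentile rule keeps exactly ceiling(0.2 KM) entries
  expect_equal(attr(t0, "n_retained"), as.integer(ceiling(0.2 * op$K * op$M)))
  v <- attr(t0, "eigenvector")
  # dense object-space operator via basis vectors
  km <- length(y)
  keep <- order(as.vector(y), decreasing = TRUE)[seq_len(ceiling(0.2 * km))]
  mask <- array(FALSE, dim(y)); mask[keep] <- TRUE
  wf <- pmax(op$illumination, 1e-6 * max(op$illumination))
  B <- matrix(0i, 16, 16)
  for (j in 1:16) {
    e <- matrix(0i, 4, 4); e[j] <- 1
    u <- op_forward(op, e); u[!mask] <- 0i
    B[, j] <- as.vector(op_adjoint(op, u) / wf)
  }
  ev <- eigen(B)$vectors[, 1]
  vn <- as.vector(v) / sqrt(sum(Mod(v)^2))
  expect_gte(Mod(sum(Conj(vn) * ev)), 0.999)
  expect_error(spectral_initialize(y * 0, op, cfg), "positive")
})

test_that("random initialization has unit amplitude and the stated phase law", {
  t1 <- random_initialize(c(256, 256), seed = 5)
  expect_true(all(abs(Mod(t1$values) - 1) < 1e-12))
  ph <- Arg(t1$values)
  n <- length(ph)
  # mean 0.1 within 3 SE; variance 0.1 within 3 SE of a normal sample
  expect_lt(abs(mean(ph) - 0.1), 3 * sqrt(0.1 / n))
  expect_lt(abs(var(as.vector(ph)) - 0.1), 3 * 0.1 * sqrt(2 / (n - 1)))
  expect_identical(random_initialize(c(16, 16), seed = 2)$values,
                   random_initialize(c(16, 16), seed = 2)$values)
})

test_that("plain maximum-likelihood CG descends and matches the likelihood", {
  geom <- test_geom(16L)
  ph <- generate_phantom(phantom_spec(grid = 32L, seed = 5))
  plan <- scan_plan(c(32, 32), 16L, 8L)
  probe <- make_random_probe(geom, 2, seed = 1, grid = 16L)
  sim <- simulate_counts(ph$object, probe, plan, geom, dose = 500, seed = 3)
  cfg <- recon_config(prior = "none", alpha_h = Inf, mu0 = 0, mu1 = 0,
                      max_iters = 40L, rel_tol = 1e-12, seed = 4)
  st <- reconstruct(sim$counts, sim$probe, plan, cfg)
  # objective trace is non-increasing (line-search contract)
  expect_true(all(diff(st$objective_trace) <= 1e-8 * pmax(abs(st$objective_trace[-1]), 1)))
  # with no prior the recorded objective is exactly the Poisson NLL
  expect_equal(utils::tail(st$objective_trace, 1),
               poisson_nll(st$object$values, sim$counts, sim$op), tolerance = 1e-10)
  # truncation bookkeeping: with alpha_h = Inf everything is retained
  expect_true(all(st$truncated_fraction_trace == 1))
})

test_that("the MAP objective with priors is also monotone under line search", {
  geom <- test_geom(16L)
  ph <- generate_phantom(phantom_spec(grid = 32L, seed = 6))
  plan <- scan_plan(c(32, 32), 16L, 8L)
  probe <- make_random_probe(geom, 2, seed = 2, grid = 16L)
  sim <- simulate_counts(ph$object, probe, plan, geom, dose = 100, seed = 5)
  st <- reconstruct(sim$counts, sim$probe, plan,
                    recon_config(prior = "tikhonov", max_iters = 30L, seed = 6))
  expect_true(all(diff(st$objective_trace) <= 1e-8 * pmax(abs(st$objective_trace[-1]), 1)))
  expect_true(all(st$truncated_fraction_trace >= 0 &
                    st$truncated_fraction_trace <= 1))
})
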