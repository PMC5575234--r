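# Shared fixtures: tiny operators, dense design matrices, small phantoms.

test_geom <- function(det = 16L, pixel_size = 1.7) {
  default_geometry(pixel_size = pixel_size, detector_pixels = as.integer(det))
}

# Dense, well-conditioned probe (no aperture zeros) for gradient/adjoint
# oracles: arbitrary complex matrix wrapped as a probe.
dense_probe <- function(m, electrons = 10, seed = 1) {
  set.seed(seed)
  v <- matrix(complex(real = stats::rnorm(m * m), imaginary = stats::rnorm(m * m)), m, m)
  eptycho:::new_probe_field(v, 1.7, electrons, NA_real_)
}

tiny_operator <- function(n = 8L, m = 4L, step = 2L, electrons = 10, seed = 1) {
  plan <- scan_plan(c(n, n), m, step)
  probe <- dense_probe(m, electrons, seed)
  list(op = forward_operator(probe, plan), plan = plan, probe = probe)
}

random_object <- function(n, seed = 1, amp = 0.1) {
  set.seed(seed)
  v <- matrix(complex(real = 1 + amp * stats::rnorm(n * n),
                      imaginary = amp * stats::rnorm(n * n)), n, n)
  v / max(Mod(v))
}

# Dense design matrix P (KM x N) built by applying the operator to basis vectors.
dense_design_matrix <- function(op) {
  n_tot <- op$N
  P <- matrix(0i, op$K * op$M, n_tot)
  for (j in seq_len(n_tot)) {
    e <- matrix(0i, op$object_dim[1], op$object_dim[2])
    e[j] <- 1
    P[, j] <- as.vector(op_forward(op, e))
  }
  P
}

# Central interior of a field (evaluation window away from the weakly
# illuminated scan border).
interior <- function(x, margin) crop_field(x, margin)

# Simulate counts for a phantom/probe/plan at a dose (identity detector).
simulate_counts <- function(object, probe, plan, geom, dose, seed) {
  target <- dose * (plan$step * geom$image_pixel_size)^2
  probe <- set_probe_electrons(probe, target)
  op <- forward_operator(probe, plan)
  sc <- scale_to_dose(forward_apply(object, op), dose, plan, geom, probe = probe)
  list(counts = apply_detector(sc, identity_response(), seed = seed),
       probe = probe, op = op, noise_free = sc)
}
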