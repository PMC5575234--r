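# Run configuration and the HDF5 dataset container tying
# simulate -> reconstruct -> evaluate -> average into reproducible runs.
# Layout (self-defined, CXI-inspired):
#   /entry/data        (m, m, K) measured counts
#   /entry/probe/re,im probe wave
#   /entry/positions   (K, 2) 0-based scan offsets
#   /entry/config_json full run configuration as a JSON string
#   /ground_truth/re,im  phantom transmission (when simulated internally)
# Complex arrays are stored as paired re/im datasets.

#' Default run configuration
#'
#' Nested list mirroring the full simulate/reconstruct pipeline; every random
#' choice derives from `master_seed`. Serializes losslessly through YAML.
#'
#' @param master_seed Master seed; per-stage substreams (phantom, probe,
#'   detector, initialization) are derived from it.
#' @return A list of class `run_config`.
#' @export
default_run_config <- function(master_seed = 1L) {
  structure(list(
    geometry = list(pixel_size = 1.7, energy_kev = 300, detector_pixels = 64L,
                    detector_pixel_size_um = 5, probe_half_angle_mrad = 4.5),
    probe = list(kind = "random", defocus_nm = 400, fzp_distance_nm = 600,
                 correlation_length_px = 4),
    scan = list(overlap = 0.75, step = NA_integer_, k_per_axis = NA_integer_),
    phantom = list(grid = 128L, n_pseudo_atoms = 40L, atom_sigma = 3.5,
                   peak_phase = 0.3, ice_phase_std = 0.02, thickness = 500,
                   mrc_path = NA_character_),
    dose = 20,
    detector = list(response = "identity"),
    recon = list(mu0 = 1e-2, mu1 = 8e-2, alpha_h = 5, max_iters = 200L,
                 rel_tol = 1e-7, init_mode = "random", power_iters = 70L,
                 spectral_percentile = 80, prior = "tikhonov",
                 denoiser_id = "wavelet", refresh_interval = 10L),
    master_seed = as.integer(master_seed)
  ), class = "run_config")
}

#' Read / write a run configuration as YAML
#'
#' @param path YAML file path.
#' @return `read_run_config()` returns a `run_config`; `write_run_config()`
#'   returns the path invisibly.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- default_run_config()
  for (nm in names(cfg)) {
    if (is.list(base[[nm]])) base[[nm]] <- utils::modifyList(base[[nm]], cfg[[nm]])
    else base[[nm]] <- cfg[[nm]]
  }
  base
}

#' @rdname read_run_config
#' @param config A `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Named substreams derived from the master seed.
derive_seeds <- function(master_seed) {
  set.seed(master_seed)
  s <- sample.int(.Machine$integer.max - 1L, 4L)
  list(phantom = s[1], probe = s[2], detector = s[3], init = s[4])
}

h5_write_complex <- function(z, file, group) {
  rhdf5::h5createGroup(file, group)
  rhdf5::h5write(Re(z), file, paste0(group, "/re"))
  rhdf5::h5write(Im(z), file, paste0(group, "/im"))
}

h5_read_complex <- function(file, group) {
  re <- rhdf5::h5read(file, paste0(group, "/re"))
  im <- rhdf5::h5read(file, paste0(group, "/im"))
  matrix(complex(real = re, imaginary = im), nrow(re), ncol(re))
}

h5_has <- function(file, path) {
  ls <- rhdf5::h5ls(file)
  full <- file.path(ls$group, ls$name)
  full <- sub("^//", "/", full)
  path %in% full
}

require_h5_path <- function(file, path) {
  if (!h5_has(file, path)) {
    stop(sprintf("dataset schema error: missing path %s in %s", path, file),
         call. = FALSE)
  }
}

build_probe <- function(config, geom, grid) {
  seeds <- derive_seeds(config$master_seed)
  switch(config$probe$kind,
    defocused = make_defocused_probe(geom, config$probe$defocus_nm, grid = grid),
    fzp = make_fzp_probe(geom, config$probe$fzp_distance_nm, grid = grid),
    random = make_random_probe(geom, config$probe$correlation_length_px,
                               seed = seeds$probe, grid = grid),
    stop(sprintf("unknown probe kind '%s'", config$probe$kind), call. = FALSE)
  )
}

#' Simulate a ptychography dataset and write the HDF5 container
#'
#' Runs the full simulation pipeline — phantom (or MRC import), probe, scan
#' plan from the overlap rule, noise-free diffraction, dose scaling, detector
#' model — and writes the dataset file. Logs the electrons per pattern and
#' per pixel.
#'
#' @param config A `run_config` (or a YAML path).
#' @param path Output HDF5 path.
#' @param quiet Suppress log messages.
#' @return Invisibly, a list with the `path`, the `scan_plan`, dose summaries
#'   and the ground-truth object.
#' @export
cmd_simulate <- function(config, path, quiet = FALSE) {
  if (is.character(config)) config <- read_run_config(config)
  if (!dir.exists(dirname(path))) {
    stop(sprintf("output directory does not exist: %s", dirname(path)), call. = FALSE)
  }
  seeds <- derive_seeds(config$master_seed)
  g <- config$geometry
  geom <- default_geometry(pixel_size = g$pixel_size, energy_kev = g$energy_kev,
                           detector_pixels = as.integer(g$detector_pixels),
                           detector_pixel_size_um = g$detector_pixel_size_um,
                           probe_half_angle_mrad = g$probe_half_angle_mrad)
  if (!is.na(config$phantom$mrc_path)) {
    pot <- load_mrc_potential(config$phantom$mrc_path)
    object <- potential_to_transmission(pot, geom)
  } else {
    ph <- config$phantom
    spec <- phantom_spec(grid = ph$grid, pixel_size = g$pixel_size,
                         n_pseudo_atoms = ph$n_pseudo_atoms,
                         atom_sigma = ph$atom_sigma, peak_phase = ph$peak_phase,
                         ice_phase_std = ph$ice_phase_std,
                         thickness = ph$thickness, seed = seeds$phantom)
    object <- generate_phantom(spec)$object
  }
  m <- geom$detector_pixels
  probe <- build_probe(config, geom, m)
  step <- if (!is.na(config$scan$step)) as.integer(config$scan$step)
          else step_from_overlap(probe, config$scan$overlap)
  kpa <- if (!is.na(config$scan$k_per_axis)) as.integer(config$scan$k_per_axis) else NULL
  plan <- scan_plan(dim(field_values(object)), m, step, k_per_axis = kpa)
  # electrons per exposure follow from the dose and the area advanced per step
  target_e <- config$dose * (step * geom$image_pixel_size)^2
  if (target_e > 0) probe <- set_probe_electrons(probe, target_e)
  op <- forward_operator(probe, plan)
  noise_free <- forward_apply(object, op)
  scaled <- scale_to_dose(noise_free, config$dose, plan, geom, probe = probe)
  response <- switch(config$detector$response,
                     identity = identity_response(),
                     k2like = detector_response(),
                     stop("unknown detector response", call. = FALSE))
  counts <- apply_detector(scaled, response, seed = seeds$detector)
  if (!quiet) {
    message(sprintf(
      "simulated K = %d patterns: %.1f e-/pattern, %.3f e-/detector pixel, %.1f e-/image pixel",
      plan$K, scaled$electrons_per_pattern, scaled$e_per_detector_pixel,
      scaled$e_per_image_pixel))
  }
  if (file.exists(path)) file.remove(path)
  rhdf5::h5createFile(path)
  rhdf5::h5createGroup(path, "/entry")
  rhdf5::h5write(counts$data, path, "/entry/data")
  h5_write_complex(probe_values(probe), path, "/entry/probe")
  rhdf5::h5write(plan$positions, path, "/entry/positions")
  meta <- list(config = unclass(config), step = step, K = plan$K,
               electrons_per_pattern = scaled$electrons_per_pattern,
               e_per_detector_pixel = scaled$e_per_detector_pixel,
               e_per_image_pixel = scaled$e_per_image_pixel,
               pixel_size = geom$image_pixel_size)
  rhdf5::h5write(as.character(jsonlite::toJSON(meta, auto_unbox = TRUE, digits = NA)),
                 path, "/entry/config_json")
  rhdf5::h5createGroup(path, "/ground_truth")
  rhdf5::h5write(Re(field_values(object)), path, "/ground_truth/re")
  rhdf5::h5write(Im(field_values(object)), path, "/ground_truth/im")
  rhdf5::h5closeAll()
  invisible(list(path = path, scan = plan, geom = geom,
                 electrons_per_pattern = scaled$electrons_per_pattern,
                 e_per_detector_pixel = scaled$e_per_detector_pixel,
                 e_per_image_pixel = scaled$e_per_image_pixel,
                 object = object))
}

#' Load a simulated dataset container
#'
#' @param path HDF5 dataset path.
#' @return List with `counts` (a `diffraction_stack`), `probe`
#'   (`probe_field`), `plan` (`scan_plan`), `meta`, and `ground_truth`
#'   (`complex_field` or NULL).
#' @export
load_dataset <- function(path) {
  if (!file.exists(path)) stop(sprintf("dataset not found: %s", path), call. = FALSE)
  for (p in c("/entry/data", "/entry/probe/re", "/entry/probe/im",
              "/entry/positions", "/entry/config_json")) {
    require_h5_path(path, p)
  }
  data <- rhdf5::h5read(path, "/entry/data")
  probe_v <- h5_read_complex(path, "/entry/probe")
  pos <- rhdf5::h5read(path, "/entry/positions")
  meta <- jsonlite::fromJSON(rhdf5::h5read(path, "/entry/config_json"))
  px <- meta$pixel_size
  gt <- if (h5_has(path, "/ground_truth/re")) {
    gre <- rhdf5::h5read(path, "/ground_truth/re")
    gim <- rhdf5::h5read(path, "/ground_truth/im")
    complex_field(matrix(complex(real = gre, imaginary = gim),
                         nrow(gre), ncol(gre)), px)
  } else NULL
  rhdf5::h5closeAll()
  object_dim <- if (!is.null(gt)) dim(gt$values) else {
    c(max(pos[, 1]) + nrow(probe_v), max(pos[, 2]) + nrow(probe_v))
  }
  plan <- structure(list(positions = matrix(as.integer(pos), nrow(pos), 2),
                         step = as.integer(meta$step), K = nrow(pos),
                         probe_dim = nrow(probe_v), object_dim = object_dim),
                    class = "scan_plan")
  probe <- new_probe_field(probe_v, px, sum(Mod(probe_v)^2), NA_real_)
  counts <- diffraction_stack(data, dose = meta$config$dose,
                              electrons_per_pattern = meta$electrons_per_pattern,
                              pixel_size = px)
  list(counts = counts, probe = probe, plan = plan, meta = meta, ground_truth = gt)
}

#' Reconstruct from a dataset container
#'
#' @param dataset_path Input HDF5 dataset.
#' @param out_path Output HDF5 path for the reconstruction (complex array +
#'   objective/truncation traces; a CSV of the traces is written alongside).
#' @param config Optional `run_config` overriding the one embedded in the
#'   dataset.
#' @param quiet Suppress log messages.
#' @return The `recon_state`, invisibly.
#' @export
cmd_reconstruct <- function(dataset_path, out_path, config = NULL, quiet = FALSE) {
  ds <- load_dataset(dataset_path)
  rc <- if (is.null(config)) ds$meta$config$recon else config$recon
  seeds <- derive_seeds(if (is.null(config)) ds$meta$config$master_seed
                        else config$master_seed)
  cfg <- recon_config(mu0 = rc$mu0, mu1 = rc$mu1, alpha_h = rc$alpha_h,
                      max_iters = rc$max_iters, rel_tol = rc$rel_tol,
                      init_mode = rc$init_mode, power_iters = rc$power_iters,
                      spectral_percentile = rc$spectral_percentile,
                      seed = seeds$init, prior = rc$prior,
                      denoiser_id = rc$denoiser_id,
                      refresh_interval = rc$refresh_interval)
  state <- reconstruct(ds$counts, ds$probe, ds$plan, cfg)
  if (!quiet) {
    message(sprintf("reconstruction: %d iterations, final objective %.6g",
                    state$iterations, utils::tail(state$objective_trace, 1)))
  }
  if (file.exists(out_path)) file.remove(out_path)
  rhdf5::h5createFile(out_path)
  h5_write_complex(state$object$values, out_path, "/recon")
  rhdf5::h5write(state$objective_trace, out_path, "/recon/objective_trace")
  rhdf5::h5write(state$truncated_fraction_trace, out_path,
                 "/recon/truncated_fraction_trace")
  rhdf5::h5write(state$object$pixel_size, out_path, "/recon/pixel_size")
  rhdf5::h5closeAll()
  utils::write.csv(
    data.frame(iteration = seq_along(state$objective_trace),
               objective = state$objective_trace,
               retained_fraction = state$truncated_fraction_trace),
    sub("\\.h5$", "_trace.csv", out_path), row.names = FALSE)
  invisible(state)
}

#' Load a reconstruction written by [cmd_reconstruct()]
#'
#' @param path Reconstruction HDF5 path.
#' @return A `complex_field`.
#' @export
load_reconstruction <- function(path) {
  require_h5_path(path, "/recon/re")
  z <- h5_read_complex(path, "/recon")
  px <- as.numeric(rhdf5::h5read(path, "/recon/pixel_size"))
  rhdf5::h5closeAll()
  complex_field(z, px)
}

#' Evaluate a reconstruction against ground truth
#'
#' Computes the FRC curve with both information thresholds, the SNR curve and
#' the gauge-aligned NRMSE; optionally writes a JSON report and CSV curves.
#'
#' @param recon Reconstruction (`complex_field`, matrix, or HDF5 path).
#' @param truth Ground truth (same options).
#' @param out_prefix Optional path prefix for `<prefix>_report.json`,
#'   `<prefix>_frc.csv` and `<prefix>_snr.csv`.
#' @return The report list.
#' @export
cmd_evaluate <- function(recon, truth, out_prefix = NULL) {
  if (is.character(recon)) recon <- load_reconstruction(recon)
  if (is.character(truth)) {
    ds <- load_dataset(truth)
    truth <- ds$ground_truth
  }
  curve <- frc(truth, recon)
  report <- list(
    nrmse = nrmse(truth, recon),
    resolution_one_bit = resolution_from_frc(curve, "one_bit"),
    resolution_half_bit = resolution_from_frc(curve, "half_bit")
  )
  snr <- snr_db(truth, recon)
  if (!is.null(out_prefix)) {
    jsonlite::write_json(report, paste0(out_prefix, "_report.json"),
                         auto_unbox = TRUE, digits = NA)
    utils::write.csv(as.data.frame(curve), paste0(out_prefix, "_frc.csv"),
                     row.names = FALSE)
    utils::write.csv(as.data.frame(snr), paste0(out_prefix, "_snr.csv"),
                     row.names = FALSE)
  }
  c(report, list(frc = curve, snr = snr))
}

#' Average reconstructions from files or fields
#'
#' @param recons List of `complex_field`s / matrices, or character vector of
#'   reconstruction HDF5 paths.
#' @param out_prefix Optional prefix for the split-half FRC CSV.
#' @return See [average_reconstructions()].
#' @export
cmd_average <- function(recons, out_prefix = NULL) {
  if (is.character(recons)) recons <- lapply(recons, load_reconstruction)
  res <- average_reconstructions(recons)
  if (!is.null(out_prefix)) {
    utils::write.csv(as.data.frame(res$frc), paste0(out_prefix, "_frc.csv"),
                     row.names = FALSE)
  }
  res
}
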