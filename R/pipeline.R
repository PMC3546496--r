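#' Pipeline configuration
#'
#' Builds the full configuration for the simulate -> reconstruct -> extract ->
#' quantify pipeline. Defaults reproduce the phantom study conditions: the
#' 18 x 15 cm tank whose agar fill (the electrically active domain) is 80 mm
#' high with the 8 x 8 array of 4 mm electrodes at 8 mm gaps resting on top,
#' 0.1 S/m background, 0.892 S/m saline inclusions whose tops sit 15 mm below
#' the electrode plane (the agar cover), 10 mA injection, 40 dB channel-SNR
#' measurement noise, and whitened combined-regularization reconstruction.
#'
#' @param tank named list overriding [tank_spec()] arguments.
#' @param electrodes named list overriding [electrode_layout()] arguments.
#' @param inclusions list of [inclusion_spec()] or of named argument lists.
#' @param noise list(snr_db =, seed =) for measurement noise (snr_db = Inf
#'   disables noise).
#' @param current_ma injection amplitude, mA.
#' @param inverse named list overriding [regularization_config()] arguments.
#' @param boundary named list overriding [edge_detection_config()] arguments.
#' @param quantify list(spacing_mm =, dims =, ha_fraction =, allow_open =).
#' @param whiten scale every measurement (rows of J and dv) by the reciprocal
#'   of the simulated reference voltage before inversion (normalized
#'   difference imaging; the correct whitening for channel-proportional
#'   noise). Default TRUE.
#' @param output_dir optional directory where stages persist artifacts.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(tank = list(), electrodes = list(),
                            inclusions = list(),
                            noise = list(snr_db = 40, seed = 1),
                            current_ma = 10,
                            inverse = list(), boundary = list(),
                            quantify = list(), whiten = TRUE,
                            output_dir = NULL) {
  tk <- do.call(tank_spec, utils::modifyList(list(height_mm = 80), as.list(tank)))
  ly <- do.call(electrode_layout, c(list(tank = tk), electrodes))
  incs <- lapply(inclusions, function(x) {
    if (inherits(x, "inclusion_spec")) x else do.call(inclusion_spec, x)
  })
  noise <- utils::modifyList(list(snr_db = 40, seed = 1), as.list(noise))
  inv <- do.call(regularization_config, inverse)
  bnd <- do.call(edge_detection_config, boundary)
  qnt <- utils::modifyList(
    list(spacing_mm = 1, dims = c(180, 150, 80), origin_mm = c(0, 0, 0),
         ha_fraction = 0.5, allow_open = TRUE),
    as.list(quantify))
  structure(list(tank = tk, electrodes = ly, inclusions = incs,
                 background_s_per_m = 0.1, noise = noise,
                 current_ma = current_ma, inverse = inv, boundary = bnd,
                 quantify = qnt, whiten = isTRUE(whiten),
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Phantom model presets
#'
#' The four phantom fillings of the feasibility study: no inclusion (0 mL)
#' and the 4x4x4 cm (64 mL), 5x5x5 cm (125 mL) and 8x8x5 cm (320 mL) saline
#' cuboids, centred laterally with their top faces 15 mm below the electrode
#' plane (under the agar cover layer).
#'
#' @param model one of "0mL", "64mL", "125mL", "320mL".
#' @param ... further arguments passed to [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
phantom_model <- function(model = c("64mL", "125mL", "320mL", "0mL"), ...) {
  model <- match.arg(model)
  dims <- switch(model,
                 "0mL" = NULL,
                 "64mL" = c(40, 40, 40),
                 "125mL" = c(50, 50, 50),
                 "320mL" = c(80, 80, 50))
  incs <- list()
  if (!is.null(dims)) {
    center <- c(90, 75, 80 - 15 - dims[3] / 2)
    incs <- list(inclusion_spec("cuboid", center, dims, 0.892))
  }
  pipeline_config(inclusions = incs, ...)
}

true_inclusion_stats <- function(config) {
  if (length(config$inclusions) == 0) {
    return(list(volume_ml = 0, center_mm = NULL))
  }
  vols <- vapply(config$inclusions, function(inc) {
    if (inc$shape == "cuboid") prod(inc$dims_mm) else 4 / 3 * pi * inc$dims_mm^3
  }, 1.0)
  ctr <- colSums(do.call(rbind, lapply(config$inclusions, `[[`, "center_mm")) *
                   vols) / sum(vols)
  list(volume_ml = sum(vols) / 1000, center_mm = as.numeric(ctr))
}

#' Read / write a pipeline configuration as YAML
#' @param config a [pipeline_config()].
#' @param path file path.
#' @export
write_pipeline_config <- function(config, path) {
  lst <- list(
    tank = config$tank[c("length_mm", "width_mm", "height_mm", "target_edge_mm")],
    electrodes = config$electrodes[c("n_rows", "n_cols", "radius_mm", "gap_mm",
                                     "back_radius_mm",
                                     "contact_impedance_ohm_m2")],
    inclusions = lapply(config$inclusions, function(i) {
      list(shape = i$shape, center_mm = i$center_mm, dims_mm = i$dims_mm,
           conductivity_s_per_m = i$conductivity_s_per_m)
    }),
    noise = config$noise, current_ma = config$current_ma,
    inverse = config$inverse[c("method", "lambda", "epsilon", "L_operator")],
    boundary = config$boundary[c("threshold_T", "auto_percentile",
                                 "min_component_size", "use_magnitude")],
    quantify = config$quantify, whiten = config$whiten,
    output_dir = config$output_dir)
  yaml::write_yaml(lst, path)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  lst <- yaml::read_yaml(path)
  if (!is.null(lst$noise$snr_db) && is.character(lst$noise$snr_db)) {
    lst$noise$snr_db <- as.numeric(lst$noise$snr_db)  # "Inf" round-trip
  }
  pipeline_config(tank = lst$tank %||% list(),
                  electrodes = lst$electrodes %||% list(),
                  inclusions = lst$inclusions %||% list(),
                  noise = lst$noise %||% list(),
                  current_ma = lst$current_ma %||% 10,
                  inverse = lst$inverse[!vapply(lst$inverse, is.null, TRUE)] %||% list(),
                  boundary = lst$boundary %||% list(),
                  quantify = lst$quantify %||% list(),
                  whiten = lst$whiten %||% TRUE,
                  output_dir = lst$output_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Simulate the measurement stage
#'
#' Builds the phantom, simulates the homogeneous reference frame and the
#' inclusion frame, applies seeded measurement noise to both, and (when an
#' output directory is configured) writes the frames as CSV, the mesh with
#' the true conductivity as VTK, and the ground-truth inclusion surfaces as
#' STL.
#'
#' @param config a [pipeline_config()].
#' @param verbose print stage timings.
#' @return list with mesh, layout, fields and the two frames.
#' @export
run_simulate <- function(config, verbose = FALSE) {
  t0 <- Sys.time()
  mesh <- build_tank_mesh(config$tank, config$electrodes)
  field_ref <- make_conductivity_field(mesh, config$background_s_per_m)
  field_true <- make_conductivity_field(mesh, config$background_s_per_m,
                                        config$inclusions)
  stage_log(verbose, "mesh", t0, sprintf("%d elements, %d nodes",
                                         mesh$n_elements, mesh$n_nodes))
  t0 <- Sys.time()
  frame_ref_clean <- simulate_frame(mesh, field_ref, config$electrodes,
                                    config$current_ma)
  frame_meas_clean <- simulate_frame(mesh, field_true, config$electrodes,
                                     config$current_ma)
  seed <- as.integer(config$noise$seed)
  frame_meas <- add_noise(frame_meas_clean, config$noise$snr_db, seed)
  frame_ref <- add_noise(frame_ref_clean, config$noise$snr_db, seed + 1L)
  stage_log(verbose, "forward", t0, sprintf("2 frames of %d values",
                                            length(frame_ref$values)))
  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_frame_csv(frame_ref, file.path(config$output_dir, "frame_reference.csv"))
    write_frame_csv(frame_meas, file.path(config$output_dir, "frame_measured.csv"))
    write_vtk(mesh, file.path(config$output_dir, "phantom.vtk"),
              list(sigma_true = field_true$values,
                   sigma_ref = field_ref$values))
    for (k in seq_along(config$inclusions)) {
      inc <- config$inclusions[[k]]
      if (inc$shape == "cuboid") {
        write_stl(make_cuboid_surface(inc$center_mm, inc$dims_mm),
                  file.path(config$output_dir,
                            sprintf("truth_inclusion_%d.stl", k)))
      } else {
        write_stl(make_sphere_surface(inc$center_mm, inc$dims_mm),
                  file.path(config$output_dir,
                            sprintf("truth_inclusion_%d.stl", k)))
      }
    }
  }
  list(mesh = mesh, layout = config$electrodes, field_ref = field_ref,
       field_true = field_true, frame_ref = frame_ref,
       frame_meas = frame_meas, frame_ref_clean = frame_ref_clean)
}

stage_log <- function(verbose, stage, t0, what) {
  if (verbose) {
    message(sprintf("[%s] %s (%.1f s)", stage, what,
                    as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  }
}

#' Run the full pipeline
#'
#' simulate (or reuse supplied frames) -> combined-regularization
#' reconstruction -> steplike-edge boundary extraction -> voxel
#' quantification. Returns the anomaly statistics together with the ground
#' truth comparison (volume error and per-axis position error) when the
#' configuration contains inclusions.
#'
#' @param config a [pipeline_config()].
#' @param sim optional result of [run_simulate()] to reuse.
#' @param verbose print stage timings.
#' @return an `anomaly_stats` object extended with `position_mm`,
#'   `position_error_pct`, `volume_error_pct`, `threshold`, `n_edge_elements`
#'   and `watertight`.
#' @export
run_full <- function(config, sim = NULL, verbose = FALSE) {
  if (is.null(sim)) sim <- run_simulate(config, verbose)
  t0 <- Sys.time()
  J <- compute_jacobian(sim$mesh, sim$field_ref, config$electrodes,
                        config$current_ma)
  stage_log(verbose, "jacobian", t0, sprintf("%d x %d", nrow(J$entries),
                                             ncol(J$entries)))
  t0 <- Sys.time()
  # Eq.-2 difference: simulated (clean) reference minus the measured frame
  dv <- sim$frame_ref_clean$values - sim$frame_meas$values
  if (isTRUE(config$whiten)) {
    w <- 1 / abs(sim$frame_ref_clean$values)
    J$entries <- J$entries * w
    dv <- dv * w
  }
  rec <- reconstruct(J, dv, config$inverse)
  rm(J)
  stage_log(verbose, "inverse", t0,
            sprintf("%s residual %.3g", rec$method, rec$residual_norm))
  t0 <- Sys.time()
  bd <- extract_boundary(sim$mesh, rec$delta_x, config$boundary)
  stage_log(verbose, "boundary", t0,
            sprintf("%d edge elements, %d triangles, watertight %s",
                    length(bd$edge_set$element_ids),
                    nrow(bd$surface$triangles), bd$surface$watertight))
  t0 <- Sys.time()
  grid <- voxel_grid(config$quantify$spacing_mm, config$quantify$dims,
                     config$quantify$origin_mm)
  grid <- classify_nodes(bd$surface, grid,
                         allow_open = isTRUE(config$quantify$allow_open))
  stats <- count_valid_cubes(grid)
  truth <- true_inclusion_stats(config)
  empty <- length(bd$edge_set$element_ids) == 0 || max(abs(rec$delta_x)) == 0
  stats$position_mm <- if (empty) c(NA_real_, NA_real_, NA_real_) else {
    center_of_mass(rec$delta_x, sim$mesh, config$quantify$ha_fraction)
  }
  stats$true_volume_ml <- truth$volume_ml
  stats$true_position_mm <- truth$center_mm
  stats$volume_error_pct <- if (truth$volume_ml > 0) {
    volume_error(stats$volume_ml, truth$volume_ml)
  } else NA_real_
  stats$position_error_pct <- if (!is.null(truth$center_mm) && !empty) {
    position_error(stats$position_mm, truth$center_mm, config$tank)
  } else c(NA_real_, NA_real_, NA_real_)
  stats$threshold <- bd$threshold
  stats$n_edge_elements <- length(bd$edge_set$element_ids)
  stats$n_elements <- sim$mesh$n_elements
  stats$watertight <- bd$surface$watertight
  stats$method <- rec$method
  stage_log(verbose, "quantify", t0,
            sprintf("%.1f mL (true %.1f)", stats$volume_ml, truth$volume_ml))

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_vtk(sim$mesh, file.path(config$output_dir, "reconstruction.vtk"),
              list(delta_x = rec$delta_x,
                   edge_element = as.numeric(
                     seq_len(sim$mesh$n_elements) %in%
                       bd$edge_set$element_ids)))
    if (nrow(bd$surface$triangles) > 0) {
      write_stl(bd$surface, file.path(config$output_dir, "boundary.stl"))
      write_ply(bd$surface, file.path(config$output_dir, "boundary.ply"))
    }
    sidecar <- list(method = rec$method, lambda = rec$lambda,
                    epsilon = rec$epsilon, residual_norm = rec$residual_norm,
                    threshold = bd$threshold,
                    seed = config$noise$seed, snr_db = config$noise$snr_db)
    jsonlite::write_json(sidecar,
                         file.path(config$output_dir, "reconstruction.json"),
                         auto_unbox = TRUE, digits = NA, null = "null")
    write_stats(stats, config$output_dir)
  }
  stats
}

write_stats <- function(stats, out_dir) {
  jsonlite::write_json(unclass(stats), file.path(out_dir, "stats.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  row <- data.frame(
    true_volume_ml = stats$true_volume_ml,
    est_volume_ml = stats$volume_ml,
    volume_error_pct = stats$volume_error_pct,
    pos_x_mm = stats$position_mm[1], pos_y_mm = stats$position_mm[2],
    pos_z_mm = stats$position_mm[3],
    pe_x_pct = stats$position_error_pct[1],
    pe_y_pct = stats$position_error_pct[2],
    pe_z_pct = stats$position_error_pct[3],
    valid_cubes = stats$valid_cube_count)
  path <- file.path(out_dir, "results.csv")
  utils::write.table(row, path, sep = ",", row.names = FALSE,
                     col.names = !file.exists(path), append = file.exists(path))
  invisible(path)
}

#' Run the three-model phantom study
#'
#' Convenience driver reproducing the simulated feasibility study: for each
#' cuboid inclusion model (64, 125 and 320 mL) it simulates the two frames at
#' the configured SNR, runs the full pipeline and collects volume and
#' position figures of merit.
#'
#' @param seed base RNG seed; model k uses seed + (k-1)*1000.
#' @param models subset of phantom models to run.
#' @param snr_db measurement noise level (default 40).
#' @param verbose print stage timings.
#' @return data.frame with one row per model: true/estimated volume (mL),
#'   signed volume error (%), per-axis position error (%), mesh size.
#' @export
run_phantom_study <- function(seed = 1, models = c("64mL", "125mL", "320mL"),
                              snr_db = 40, verbose = FALSE) {
  rows <- lapply(seq_along(models), function(k) {
    cfg <- phantom_model(models[k],
                         noise = list(snr_db = snr_db,
                                      seed = as.integer(seed) + (k - 1L) * 1000L))
    st <- run_full(cfg, verbose = verbose)
    data.frame(model = models[k],
               true_volume_ml = st$true_volume_ml,
               est_volume_ml = st$volume_ml,
               volume_error_pct = st$volume_error_pct,
               pe_x_pct = st$position_error_pct[1],
               pe_y_pct = st$position_error_pct[2],
               pe_z_pct = st$position_error_pct[3],
               n_elements = st$n_elements)
  })
  do.call(rbind, rows)
}

#' Staged pipeline commands operating on a run directory
#'
#' File-based counterparts of the in-memory pipeline, used by the command
#' line driver: `run_reconstruct` reads the persisted frames and writes the
#' reconstruction (VTK + per-element CSV), `run_extract` turns a persisted
#' reconstruction into the boundary surface (STL/PLY), and `run_quantify`
#' voxel-counts the persisted surface and writes the anomaly statistics. The
#' mesh is rebuilt deterministically from the configuration.
#'
#' @param config a [pipeline_config()] with a non-NULL `output_dir`.
#' @param verbose print stage timings.
#' @return invisibly, the main artifact of the stage.
#' @export
run_reconstruct <- function(config, verbose = FALSE) {
  dir <- config$output_dir
  stopifnot(!is.null(dir))
  mesh <- build_tank_mesh(config$tank, config$electrodes)
  field_ref <- make_conductivity_field(mesh, config$background_s_per_m)
  frame_meas <- read_frame_csv(file.path(dir, "frame_measured.csv"),
                               config$electrodes$n_electrodes,
                               config$current_ma)
  t0 <- Sys.time()
  frame_ref_clean <- simulate_frame(mesh, field_ref, config$electrodes,
                                    config$current_ma)
  J <- compute_jacobian(mesh, field_ref, config$electrodes, config$current_ma)
  dv <- frame_ref_clean$values - frame_meas$values
  if (isTRUE(config$whiten)) {
    w <- 1 / abs(frame_ref_clean$values)
    J$entries <- J$entries * w
    dv <- dv * w
  }
  rec <- reconstruct(J, dv, config$inverse)
  stage_log(verbose, "reconstruct", t0, sprintf("residual %.3g",
                                                rec$residual_norm))
  write_vtk(mesh, file.path(dir, "reconstruction.vtk"),
            list(delta_x = rec$delta_x))
  utils::write.csv(data.frame(element = seq_along(rec$delta_x),
                              delta_x = sprintf("%.17g", rec$delta_x)),
                   file.path(dir, "delta_x.csv"), row.names = FALSE,
                   quote = FALSE)
  jsonlite::write_json(list(method = rec$method, lambda = rec$lambda,
                            epsilon = rec$epsilon,
                            residual_norm = rec$residual_norm),
                       file.path(dir, "reconstruction.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(rec)
}

#' @rdname run_reconstruct
#' @export
run_extract <- function(config, verbose = FALSE) {
  dir <- config$output_dir
  stopifnot(!is.null(dir))
  mesh <- build_tank_mesh(config$tank, config$electrodes)
  dx <- as.numeric(utils::read.csv(file.path(dir, "delta_x.csv"),
                                   colClasses = c("integer", "character"))$delta_x)
  t0 <- Sys.time()
  bd <- extract_boundary(mesh, dx, config$boundary)
  stage_log(verbose, "extract", t0,
            sprintf("%d triangles", nrow(bd$surface$triangles)))
  write_stl(bd$surface, file.path(dir, "boundary.stl"))
  write_ply(bd$surface, file.path(dir, "boundary.ply"))
  write_vtk(mesh, file.path(dir, "edge_elements.vtk"),
            list(edge_element = as.numeric(seq_len(mesh$n_elements) %in%
                                             bd$edge_set$element_ids)))
  invisible(bd$surface)
}

#' @rdname run_reconstruct
#' @export
run_quantify <- function(config, verbose = FALSE) {
  dir <- config$output_dir
  stopifnot(!is.null(dir))
  mesh <- build_tank_mesh(config$tank, config$electrodes)
  dx <- as.numeric(utils::read.csv(file.path(dir, "delta_x.csv"),
                                   colClasses = c("integer", "character"))$delta_x)
  surf <- read_stl(file.path(dir, "boundary.stl"))
  t0 <- Sys.time()
  grid <- voxel_grid(config$quantify$spacing_mm, config$quantify$dims,
                     config$quantify$origin_mm)
  grid <- classify_nodes(surf, grid,
                         allow_open = isTRUE(config$quantify$allow_open))
  stats <- count_valid_cubes(grid)
  truth <- true_inclusion_stats(config)
  stats$position_mm <- if (max(abs(dx)) > 0) {
    center_of_mass(dx, mesh, config$quantify$ha_fraction)
  } else c(NA_real_, NA_real_, NA_real_)
  stats$true_volume_ml <- truth$volume_ml
  stats$true_position_mm <- truth$center_mm
  stats$volume_error_pct <- if (truth$volume_ml > 0) {
    volume_error(stats$volume_ml, truth$volume_ml)
  } else NA_real_
  stats$position_error_pct <- if (!is.null(truth$center_mm) &&
                                  all(is.finite(stats$position_mm))) {
    position_error(stats$position_mm, truth$center_mm, config$tank)
  } else c(NA_real_, NA_real_, NA_real_)
  stage_log(verbose, "quantify", t0, sprintf("%.1f mL", stats$volume_ml))
  write_stats(stats, dir)
  invisible(stats)
}
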