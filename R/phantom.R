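#' Inclusion specification
#'
#' A conductive (or resistive) inclusion inside the tank, either a cuboid
#' (axis-aligned, `dims_mm` = three edge lengths) or a sphere
#' (`dims_mm` = radius). The default conductivity is that of the saline
#' anomaly, 0.892 S/m.
#'
#' @param shape "cuboid" or "sphere".
#' @param center_mm centre of the inclusion (mm).
#' @param dims_mm edge lengths (cuboid) or radius (sphere), mm.
#' @param conductivity_s_per_m inclusion conductivity (S/m).
#' @return object of class `inclusion_spec`.
#' @export
inclusion_spec <- function(shape = c("cuboid", "sphere"), center_mm, dims_mm,
                           conductivity_s_per_m = 0.892) {
  shape <- match.arg(shape)
  center_mm <- as.numeric(center_mm)
  dims_mm <- as.numeric(dims_mm)
  stopifnot(length(center_mm) == 3, conductivity_s_per_m > 0, all(dims_mm > 0))
  if (shape == "cuboid") stopifnot(length(dims_mm) == 3)
  if (shape == "sphere") stopifnot(length(dims_mm) == 1)
  structure(list(shape = shape, center_mm = center_mm, dims_mm = dims_mm,
                 conductivity_s_per_m = conductivity_s_per_m),
            class = "inclusion_spec")
}

inclusion_inside_tank <- function(inc, tank) {
  lo <- if (inc$shape == "cuboid") inc$center_mm - inc$dims_mm / 2
        else inc$center_mm - inc$dims_mm
  hi <- if (inc$shape == "cuboid") inc$center_mm + inc$dims_mm / 2
        else inc$center_mm + inc$dims_mm
  ext <- c(tank$length_mm, tank$width_mm, tank$height_mm)
  all(lo >= 0) && all(hi <= ext)
}

point_in_inclusion <- function(pts, inc) {
  if (inc$shape == "cuboid") {
    h <- inc$dims_mm / 2
    abs(pts[, 1] - inc$center_mm[1]) <= h[1] &
      abs(pts[, 2] - inc$center_mm[2]) <= h[2] &
      abs(pts[, 3] - inc$center_mm[3]) <= h[3]
  } else {
    (pts[, 1] - inc$center_mm[1])^2 + (pts[, 2] - inc$center_mm[2])^2 +
      (pts[, 3] - inc$center_mm[3])^2 <= inc$dims_mm^2
  }
}

#' Piecewise-constant conductivity field
#'
#' Assigns each tetrahedron the inclusion conductivity when its centroid lies
#' inside an inclusion, otherwise the background conductivity (0.1 S/m agar
#' by default in the phantom configuration).
#'
#' @param mesh an `eit_mesh`.
#' @param background background conductivity, S/m.
#' @param inclusions list of [inclusion_spec()] (may be empty).
#' @return object of class `conductivity_field` with per-element `values`.
#' @export
make_conductivity_field <- function(mesh, background = 0.1, inclusions = list()) {
  stopifnot(inherits(mesh, "eit_mesh"), background > 0)
  if (inherits(inclusions, "inclusion_spec")) inclusions <- list(inclusions)
  vals <- rep(background, mesh$n_elements)
  cent <- element_centroids(mesh)
  for (inc in inclusions) {
    stopifnot(inherits(inc, "inclusion_spec"))
    if (!inclusion_inside_tank(inc, mesh$spec)) {
      stop("inclusion is not fully contained in the tank interior")
    }
    vals[point_in_inclusion(cent, inc)] <- inc$conductivity_s_per_m
  }
  structure(list(values = vals, background = background,
                 inclusions = inclusions, n_elements = mesh$n_elements),
            class = "conductivity_field")
}

# canonical measurement ordering: for each injection electrode i (1..n),
# all electrodes j != i in ascending order
frame_index_table <- function(n_electrodes = 64L) {
  inj <- rep(seq_len(n_electrodes), each = n_electrodes - 1L)
  meas <- unlist(lapply(seq_len(n_electrodes),
                        function(i) setdiff(seq_len(n_electrodes), i)))
  cbind(injection = inj, electrode = meas)
}

#' Measurement frame
#'
#' Ordered vector of boundary voltages for one acquisition: injections cycle
#' through the array electrodes (current returns through the grounded back
#' electrode) and for each injection the remaining electrodes are read out in
#' ascending index order, referenced to the back electrode. The default 8 x 8
#' array yields 64 x 63 = 4032 values.
#'
#' @param values voltage vector, volts.
#' @param n_electrodes number of array electrodes.
#' @param current_ma injection current amplitude (mA).
#' @param frame_kind "simulated" or "measured".
#' @return object of class `measurement_frame`.
#' @export
measurement_frame <- function(values, n_electrodes = 64L, current_ma = 10,
                              frame_kind = c("simulated", "measured")) {
  frame_kind <- match.arg(frame_kind)
  n <- as.integer(n_electrodes)
  if (length(values) != n * (n - 1L)) {
    stop("frame must hold n_electrodes * (n_electrodes - 1) values")
  }
  if (!all(is.finite(values))) stop("frame contains non-finite voltages")
  structure(list(values = as.numeric(values), n_electrodes = n,
                 current_ma = current_ma, frame_kind = frame_kind),
            class = "measurement_frame")
}

#' @export
print.measurement_frame <- function(x, ...) {
  cat(sprintf("measurement_frame: %d values (%d electrodes), %g mA, %s\n",
              length(x$values), x$n_electrodes, x$current_ma, x$frame_kind))
  invisible(x)
}

#' Add measurement noise at a prescribed channel SNR
#'
#' Adds zero-mean Gaussian noise per measurement channel with standard
#' deviation |V_i| * 10^(-snr_db/20) — the instrument-style channel SNR, so
#' every channel carries the same relative noise and the frame-level
#' rms(signal)/rms(noise) also equals the requested SNR in expectation.
#' `snr_db = Inf` returns the frame unchanged. Identical seeds give
#' bitwise-identical output.
#'
#' @param frame a [measurement_frame()].
#' @param snr_db target signal-to-noise ratio in dB (Inf for no noise).
#' @param seed integer RNG seed.
#' @return a new `measurement_frame` of kind "measured".
#' @export
add_noise <- function(frame, snr_db, seed) {
  stopifnot(inherits(frame, "measurement_frame"), !is.na(snr_db))
  if (is.infinite(snr_db)) return(frame)
  sd <- abs(frame$values) * 10^(-snr_db / 20)
  noise <- withr::with_seed(as.integer(seed),
                            stats::rnorm(length(frame$values), 0, sd))
  measurement_frame(frame$values + noise, frame$n_electrodes,
                    frame$current_ma, "measured")
}

#' Write / read a measurement frame as CSV
#'
#' Columns `injection_index`, `electrode_index` (0-based) and `voltage_v`
#' (full double precision, so a round-trip is bit-exact).
#'
#' @param frame a [measurement_frame()].
#' @param path file path.
#' @return `read_frame_csv` returns a `measurement_frame`.
#' @export
write_frame_csv <- function(frame, path) {
  tab <- frame_index_table(frame$n_electrodes)
  df <- data.frame(injection_index = tab[, 1] - 1L,
                   electrode_index = tab[, 2] - 1L,
                   voltage_v = sprintf("%.17g", frame$values))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_frame_csv
#' @param n_electrodes,current_ma,frame_kind frame metadata (not stored in CSV).
#' @export
read_frame_csv <- function(path, n_electrodes = 64L, current_ma = 10,
                           frame_kind = "measured") {
  df <- utils::read.csv(path, colClasses = c("integer", "integer", "character"))
  tab <- frame_index_table(n_electrodes)
  key_file <- df$injection_index * n_electrodes + df$electrode_index
  key_can <- (tab[, 1] - 1L) * n_electrodes + (tab[, 2] - 1L)
  vals <- as.numeric(df$voltage_v)[match(key_can, key_file)]
  if (anyNA(vals)) stop("CSV does not contain the full canonical frame")
  measurement_frame(vals, n_electrodes, current_ma, frame_kind)
}
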