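#' Electrode layout
#'
#' Planar electrode array on the top face plus a single back electrode (signal
#' ground) at the centre of the bottom face. The default is the 8 x 8 array of
#' 4 mm diameter electrodes with 8 mm gaps (12 mm pitch), centred on the top
#' face of the tank.
#'
#' @param tank a [tank_spec()].
#' @param n_rows,n_cols array dimensions (rows along y, columns along x).
#' @param radius_mm electrode radius (default 2, i.e. 4 mm diameter).
#' @param gap_mm gap between adjacent electrode rims (default 8).
#' @param back_radius_mm back-electrode radius (default 10).
#' @param contact_impedance_ohm_m2 contact impedance per electrode (default 0.01).
#' @return object of class `electrode_layout` with `centers` in row-major
#'   order (row 1 = smallest y, columns by increasing x), the back electrode,
#'   and the contact impedance.
#' @export
electrode_layout <- function(tank, n_rows = 8, n_cols = 8, radius_mm = 2,
                             gap_mm = 8, back_radius_mm = 10,
                             contact_impedance_ohm_m2 = 0.01) {
  stopifnot(inherits(tank, "tank_spec"), n_rows >= 1, n_cols >= 1,
            radius_mm > 0, gap_mm > 0, back_radius_mm > 0,
            contact_impedance_ohm_m2 > 0)
  pitch <- 2 * radius_mm + gap_mm
  cx <- tank$length_mm / 2 + (seq_len(n_cols) - (n_cols + 1) / 2) * pitch
  cy <- tank$width_mm / 2 + (seq_len(n_rows) - (n_rows + 1) / 2) * pitch
  if (min(cx) - radius_mm < 0 || max(cx) + radius_mm > tank$length_mm ||
      min(cy) - radius_mm < 0 || max(cy) + radius_mm > tank$width_mm) {
    stop("electrode array does not fit on the top face")
  }
  centers <- cbind(x = rep(cx, times = n_rows),
                   y = rep(cy, each = n_cols),
                   z = tank$height_mm)
  structure(list(centers = centers, radius_mm = radius_mm, gap_mm = gap_mm,
                 pitch_mm = pitch, n_rows = n_rows, n_cols = n_cols,
                 n_electrodes = n_rows * n_cols,
                 back_center = c(tank$length_mm / 2, tank$width_mm / 2, 0),
                 back_radius_mm = back_radius_mm,
                 contact_impedance_ohm_m2 = contact_impedance_ohm_m2),
            class = "electrode_layout")
}

# Assign boundary faces to electrodes: faces on the top face all of whose
# vertices lie within the effective contact radius of an electrode centre
# (the back electrode uses bottom faces likewise). The effective radius is
# max(1.5 * radius, 1.45 * smallest adjacent lattice edge) so that every
# electrode is resolved by at least three well-shaped faces on meshes coarser
# than the physical disc; the factor 1.45 just covers the far vertex of the
# incident triangle fan (sqrt(2) * h).
electrode_faces <- function(mesh, layout) {
  faces <- mesh$boundary_faces
  e1 <- mesh$nodes[faces[, 2], , drop = FALSE] - mesh$nodes[faces[, 1], , drop = FALSE]
  e2 <- mesh$nodes[faces[, 3], , drop = FALSE] - mesh$nodes[faces[, 1], , drop = FALSE]
  cr <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
              e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
              e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  area <- sqrt(rowSums(cr^2)) / 2         # mm^2
  local_h <- function(lat, at) {
    i <- findInterval(at, lat, all.inside = TRUE)
    h <- lat[i + 1L] - lat[i]
    if (i > 1L && abs(lat[i] - at) < 1e-9) h <- min(h, lat[i] - lat[i - 1L])
    h
  }
  vert_dist <- function(c_l) {
    d <- matrix(0, nrow(faces), 3L)
    for (a in 1:3) {
      d[, a] <- sqrt((mesh$nodes[faces[, a], 1] - c_l[1])^2 +
                     (mesh$nodes[faces[, a], 2] - c_l[2])^2)
    }
    apply(d, 1L, max)
  }
  n_arr <- layout$n_electrodes
  out <- vector("list", n_arr + 1L)
  top <- mesh$boundary_tag == "top"
  for (l in seq_len(n_arr)) {
    c_l <- layout$centers[l, ]
    h_loc <- min(local_h(mesh$lattice$x, c_l[1]), local_h(mesh$lattice$y, c_l[2]))
    r_eff <- max(1.5 * layout$radius_mm, 1.45 * h_loc)
    out[[l]] <- which(top & vert_dist(c_l) <= r_eff)
  }
  bot <- mesh$boundary_tag == "bottom"
  cb <- layout$back_center
  h_loc <- min(local_h(mesh$lattice$x, cb[1]), local_h(mesh$lattice$y, cb[2]))
  r_eff <- max(1.5 * layout$back_radius_mm, 1.45 * h_loc)
  out[[n_arr + 1L]] <- which(bot & vert_dist(cb) <= r_eff)

  n_f <- vapply(out, length, 1L)
  if (any(n_f < 3L)) {
    stop("electrode(s) ", paste(which(n_f < 3L), collapse = ", "),
         " resolved by fewer than 3 boundary faces; refine the mesh")
  }
  all_idx <- unlist(out)
  if (anyDuplicated(all_idx)) stop("electrode footprints overlap on the mesh")
  list(face_idx = out, area_mm2 = area, faces = faces)
}
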