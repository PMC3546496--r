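#' Quantification voxel grid
#'
#' Regular lattice of cubes used for volume counting. The default matches the
#' tank quantification grid: 1 mm spacing, 180 x 150 x 80 = 2,160,000 cubes
#' (the top 20 mm of the 100 mm tank, which holds the agar cover and the
#' electrode-artifact region, is excluded from quantification by default;
#' pass `dims = c(180, 150, 100)` to cover the full tank).
#'
#' @param spacing_mm cube edge length (default 1).
#' @param dims number of cubes per axis (default c(180, 150, 80)).
#' @param origin_mm lattice origin (default c(0, 0, 0)).
#' @return object of class `voxel_grid`; `inside_flags` is filled by
#'   [classify_nodes()].
#' @export
voxel_grid <- function(spacing_mm = 1, dims = c(180, 150, 80),
                       origin_mm = c(0, 0, 0)) {
  dims <- as.integer(dims)
  stopifnot(spacing_mm > 0, length(dims) == 3, all(dims > 0),
            length(origin_mm) == 3)
  structure(list(spacing_mm = spacing_mm, dims = dims,
                 origin_mm = as.numeric(origin_mm), inside_flags = NULL),
            class = "voxel_grid")
}

#' Number of cubes in the grid
#' @param grid a [voxel_grid()].
#' @return integer count (nx * ny * nz).
#' @export
n_cubes <- function(grid) prod(as.numeric(grid$dims))

#' Classify grid nodes as enclosed by a surface
#'
#' A node is flagged when it is enclosed by the triangle surface (ray-casting
#' parity along +z with a deterministic sub-spacing lateral offset to avoid
#' edge/vertex hits) or lies on the surface itself (within 1e-6 mm), so the
#' closed region includes its boundary — the convention that makes
#' voxel-counting an axis-aligned analytic cuboid reproduce its volume
#' exactly.
#'
#' @param surface a `triangle_surface` (should be watertight; an open surface
#'   is an error unless `allow_open = TRUE`, in which case parity counting is
#'   applied as-is and small holes may misclassify nearby columns).
#' @param grid a [voxel_grid()].
#' @param allow_open permit classification against a non-watertight surface.
#' @return the grid with `inside_flags` (logical array, node-indexed).
#' @export
classify_nodes <- function(surface, grid, allow_open = FALSE) {
  stopifnot(inherits(surface, "triangle_surface"), inherits(grid, "voxel_grid"))
  nx <- grid$dims[1] + 1L; ny <- grid$dims[2] + 1L; nz <- grid$dims[3] + 1L
  flags <- array(FALSE, c(nx, ny, nz))
  if (nrow(surface$triangles) == 0) {
    grid$inside_flags <- flags
    return(grid)
  }
  if (!isTRUE(surface$watertight) && !allow_open) {
    stop("surface is not watertight; re-run the boundary growth pass or ",
         "call with allow_open = TRUE")
  }
  s <- grid$spacing_mm; o <- grid$origin_mm
  V <- surface$vertices; Tm <- surface$triangles
  v1 <- V[Tm[, 1], , drop = FALSE]
  v2 <- V[Tm[, 2], , drop = FALSE]
  v3 <- V[Tm[, 3], , drop = FALSE]

  # --- parity of +z ray crossings, per (x, y) lattice column -------------
  # lattice points are laterally offset by an irrational sub-spacing shift so
  # no ray hits a triangle edge or vertex exactly
  ox <- s * 1e-4 * sqrt(2); oy <- s * 1e-4 * sqrt(3)
  gx <- function(i) o[1] + (i - 1) * s + ox
  gy <- function(j) o[2] + (j - 1) * s + oy
  ilo <- pmax(1L, ceiling((pmin(v1[, 1], v2[, 1], v3[, 1]) - o[1] - ox) / s) + 1L)
  ihi <- pmin(nx, floor((pmax(v1[, 1], v2[, 1], v3[, 1]) - o[1] - ox) / s) + 1L)
  jlo <- pmax(1L, ceiling((pmin(v1[, 2], v2[, 2], v3[, 2]) - o[2] - oy) / s) + 1L)
  jhi <- pmin(ny, floor((pmax(v1[, 2], v2[, 2], v3[, 2]) - o[2] - oy) / s) + 1L)
  cnt_i <- pmax(0L, ihi - ilo + 1L); cnt_j <- pmax(0L, jhi - jlo + 1L)
  ncand <- cnt_i * cnt_j
  keep <- which(ncand > 0L)
  if (length(keep) > 0) {
    tri_id <- rep(keep, ncand[keep])
    within <- sequence(ncand[keep]) - 1L
    ii <- ilo[tri_id] + within %% cnt_i[tri_id]
    jj <- jlo[tri_id] + within %/% cnt_i[tri_id]
    px <- gx(ii); py <- gy(jj)
    ax <- v1[tri_id, 1]; ay <- v1[tri_id, 2]
    bx <- v2[tri_id, 1]; by <- v2[tri_id, 2]
    cx <- v3[tri_id, 1]; cy <- v3[tri_id, 2]
    det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
    good <- abs(det) > 1e-12
    wa <- ((bx - px) * (cy - py) - (cx - px) * (by - py)) / det
    wb <- ((cx - px) * (ay - py) - (ax - px) * (cy - py)) / det
    wc <- 1 - wa - wb
    hit <- good & wa >= 0 & wb >= 0 & wc >= 0
    if (any(hit)) {
      zc <- wa[hit] * v1[tri_id[hit], 3] + wb[hit] * v2[tri_id[hit], 3] +
            wc[hit] * v3[tri_id[hit], 3]
      col <- ii[hit] + nx * (jj[hit] - 1L)
      # crossing contributes to all nodes strictly above it
      kz <- floor((zc - o[3]) / s + 1e-12) + 2L   # first node index above
      ok <- kz <= nz
      kz <- pmax(1L, kz[ok]); col <- col[ok]
      if (length(col) > 0) {
        key <- col + nx * ny * (kz - 1L)
        inc <- matrix(tabulate(key, nbins = nx * ny * nz), nx * ny, nz)
        below <- matrixStats_rowCumsums(inc)
        flags <- array(below %% 2L == 1L, c(nx, ny, nz))
      }
    }
  }

  # --- nodes lying on the surface count as enclosed ----------------------
  tol <- 1e-6
  blo <- function(k) pmax(1L, ceiling((pmin(v1[, k], v2[, k], v3[, k]) - o[k] - tol) / s) + 1L)
  bhi <- function(k, nmax) pmin(nmax, floor((pmax(v1[, k], v2[, k], v3[, k]) - o[k] + tol) / s) + 1L)
  xl <- blo(1); xh <- bhi(1, nx); yl <- blo(2); yh <- bhi(2, ny)
  zl <- blo(3); zh <- bhi(3, nz)
  ci <- pmax(0L, xh - xl + 1L); cj <- pmax(0L, yh - yl + 1L)
  ck <- pmax(0L, zh - zl + 1L)
  ncand <- ci * cj * ck
  keep <- which(ncand > 0L)
  if (length(keep) > 0) {
    tri_id <- rep(keep, ncand[keep])
    within <- sequence(ncand[keep]) - 1L
    ii <- xl[tri_id] + within %% ci[tri_id]
    jj <- yl[tri_id] + (within %/% ci[tri_id]) %% cj[tri_id]
    kk <- zl[tri_id] + within %/% (ci[tri_id] * cj[tri_id])
    p <- cbind(o[1] + (ii - 1) * s, o[2] + (jj - 1) * s, o[3] + (kk - 1) * s)
    a <- v1[tri_id, , drop = FALSE]
    ab <- v2[tri_id, , drop = FALSE] - a
    ac <- v3[tri_id, , drop = FALSE] - a
    nrm <- cross3m(ab, ac)
    nn <- sqrt(rowSums(nrm^2))
    good <- nn > 1e-12
    dist <- abs(rowSums((p - a) * nrm)) / pmax(nn, 1e-300)
    # barycentric coordinates of the in-plane projection
    d00 <- rowSums(ab * ab); d01 <- rowSums(ab * ac); d11 <- rowSums(ac * ac)
    d20 <- rowSums((p - a) * ab); d21 <- rowSums((p - a) * ac)
    den <- d00 * d11 - d01 * d01
    u <- (d11 * d20 - d01 * d21) / den
    v <- (d00 * d21 - d01 * d20) / den
    btol <- 1e-9
    on <- good & dist <= tol & u >= -btol & v >= -btol & u + v <= 1 + btol
    if (any(on)) {
      flags[cbind(ii[on], jj[on], kk[on])] <- TRUE
    }
  }
  grid$inside_flags <- flags
  grid
}

# row-wise cumulative sums of an (nrow x k) integer matrix without extra deps
matrixStats_rowCumsums <- function(m) {
  for (k in 2:ncol(m)) m[, k] <- m[, k] + m[, k - 1L]
  m
}

#' Count valid cubes and estimate volume
#'
#' A cube is valid when at least four of its eight vertices are enclosed by
#' the edge surface and those enclosed vertices are not all on a single cube
#' face (the non-coplanarity rule, which stops the counted region one layer
#' short of the outside). volume_ml = count * spacing^3 / 1000.
#'
#' @param grid a classified [voxel_grid()] (after [classify_nodes()]).
#' @return object of class `anomaly_stats` with `valid_cube_count` and
#'   `volume_ml`.
#' @export
count_valid_cubes <- function(grid) {
  stopifnot(inherits(grid, "voxel_grid"), !is.null(grid$inside_flags))
  F <- grid$inside_flags
  nx <- grid$dims[1]; ny <- grid$dims[2]; nz <- grid$dims[3]
  sub <- function(dx, dy, dz) {
    F[(1:nx) + dx, (1:ny) + dy, (1:nz) + dz, drop = FALSE]
  }
  v000 <- sub(0,0,0); v100 <- sub(1,0,0); v010 <- sub(0,1,0); v110 <- sub(1,1,0)
  v001 <- sub(0,0,1); v101 <- sub(1,0,1); v011 <- sub(0,1,1); v111 <- sub(1,1,1)
  n <- v000 + v100 + v010 + v110 + v001 + v101 + v011 + v111
  f1 <- v000 + v100 + v010 + v110   # z- face
  f2 <- v001 + v101 + v011 + v111   # z+ face
  f3 <- v000 + v100 + v001 + v101   # y- face
  f4 <- v010 + v110 + v011 + v111   # y+ face
  f5 <- v000 + v010 + v001 + v011   # x- face
  f6 <- v100 + v110 + v101 + v111   # x+ face
  coplanar4 <- (n == 4L) & (f1 == 4L | f2 == 4L | f3 == 4L | f4 == 4L |
                            f5 == 4L | f6 == 4L)
  count <- sum(n >= 4L) - sum(coplanar4)
  structure(list(valid_cube_count = count,
                 volume_ml = count * grid$spacing_mm^3 / 1000,
                 spacing_mm = grid$spacing_mm),
            class = "anomaly_stats")
}

#' @export
print.anomaly_stats <- function(x, ...) {
  cat(sprintf("anomaly_stats: %d valid cubes = %.3f mL", x$valid_cube_count,
              x$volume_ml))
  if (!is.null(x$position_mm)) {
    cat(sprintf("; position (%.1f, %.1f, %.1f) mm", x$position_mm[1],
                x$position_mm[2], x$position_mm[3]))
  }
  cat("\n")
  invisible(x)
}

#' Half-amplitude center of mass of a reconstruction
#'
#' Restricts to the half-amplitude (HA) set — elements whose |delta_x| is at
#' least `ha_fraction` of the peak — and returns the |delta_x|-weighted mean
#' of their centroids: position = sum(sigma_m p_m) / sum(sigma_m).
#'
#' @param delta_x per-element reconstructed perturbation.
#' @param mesh the owning `eit_mesh`.
#' @param ha_fraction amplitude fraction defining the HA set (default 0.5).
#' @param weight_by_volume additionally weight by element volume (default
#'   FALSE: plain per-element weights).
#' @return 3-vector, mm.
#' @export
center_of_mass <- function(delta_x, mesh, ha_fraction = 0.5,
                           weight_by_volume = FALSE) {
  stopifnot(ha_fraction > 0, ha_fraction <= 1,
            length(delta_x) == mesh$n_elements)
  a <- abs(delta_x)
  if (max(a) == 0) stop("all-zero perturbation has no center of mass")
  sel <- a >= ha_fraction * max(a)
  w <- a[sel]
  if (weight_by_volume) w <- w * mesh$volume_mm3[sel]
  p <- element_centroids(mesh)[sel, , drop = FALSE]
  as.numeric(colSums(p * w) / sum(w))
}

#' Per-axis position error
#'
#' Signed proportional difference between an estimated and a true position,
#' per axis, as a percentage of the tank extent on that axis.
#'
#' @param est,truth 3-vectors (mm).
#' @param tank a [tank_spec()].
#' @return 3-vector of signed percentages.
#' @export
position_error <- function(est, truth, tank) {
  ext <- c(tank$length_mm, tank$width_mm, tank$height_mm)
  as.numeric((est - truth) / ext * 100)
}

#' Signed volume error
#' @param est_ml,truth_ml volumes (mL); `truth_ml` must be positive.
#' @return signed percentage (est - truth) / truth * 100.
#' @export
volume_error <- function(est_ml, truth_ml) {
  stopifnot(truth_ml > 0)
  (est_ml - truth_ml) / truth_ml * 100
}
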