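#' Tank specification
#'
#' Describes the cuboid measurement tank. Coordinates are in millimetres with
#' the origin at one bottom corner and the z axis pointing towards the
#' electrode array on the top face.
#'
#' @param length_mm tank extent along x (default 180).
#' @param width_mm tank extent along y (default 150).
#' @param height_mm tank extent along z (default 100).
#' @param target_edge_mm target element edge length controlling mesh density.
#' @return object of class `tank_spec`.
#' @export
tank_spec <- function(length_mm = 180, width_mm = 150, height_mm = 100,
                      target_edge_mm = 12) {
  stopifnot(is.numeric(length_mm), length_mm > 0,
            is.numeric(width_mm), width_mm > 0,
            is.numeric(height_mm), height_mm > 0,
            is.numeric(target_edge_mm), target_edge_mm > 0)
  if (target_edge_mm >= min(length_mm, width_mm, height_mm) / 4) {
    stop("target_edge_mm must be smaller than a quarter of the smallest tank dimension")
  }
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm, target_edge_mm = target_edge_mm),
            class = "tank_spec")
}

# 1D lattice over [0, L] containing every anchor coordinate. Segments between
# consecutive anchors are split into at least `min_sub` equal parts of size
# <= h_anchor; the two outer segments use size <= h_edge.
axis_lattice <- function(L, anchors, h_edge, h_anchor = h_edge, min_sub = 1) {
  anchors <- sort(unique(anchors))
  stopifnot(all(anchors > 0), all(anchors < L))
  extras <- numeric(0)
  if (length(anchors) > 0L) {
    # one anchor-sized cell on the outer side of the first/last anchor so
    # edge anchors are surrounded by fine cells on both sides
    lo <- anchors[1] - h_anchor
    hi <- anchors[length(anchors)] + h_anchor
    extras <- c(if (lo > 1e-9) lo, if (hi < L - 1e-9) hi)
  }
  pts <- sort(unique(c(0, anchors, extras, L)))
  is_anchor <- pts %in% anchors
  out <- 0
  for (s in seq_len(length(pts) - 1L)) {
    a <- pts[s]; b <- pts[s + 1L]
    between_anchors <- is_anchor[s] && is_anchor[s + 1L]
    adj_anchor <- is_anchor[s] || is_anchor[s + 1L]
    h <- if (adj_anchor) h_anchor else h_edge
    k <- max(ceiling((b - a) / h - 1e-9), if (between_anchors) min_sub else 1L)
    out <- c(out, a + (b - a) * seq_len(k) / k)
  }
  sort(unique(out))
}

# Graded z lattice: thin layers at the top (electrode plane), growing with
# `ratio` towards the bottom, capped at h_max, rescaled to fill H exactly.
graded_z_lattice <- function(H, h_top, ratio = 1.45, h_max = 1.6 * h_top * 6) {
  t <- h_top
  while (sum(t) < H) t <- c(t, min(t[length(t)] * ratio, h_max))
  t <- t * (H / sum(t))
  rev(H - cumsum(c(0, t)))  # from 0 up to H, fine near H
}

#' Build the tetrahedral tank mesh
#'
#' Meshes the cuboid tank with a conforming tetrahedral grid: a tensor-product
#' node lattice (anchored at the electrode centres when a layout is supplied,
#' and graded towards the electrode plane) subdivided into six tetrahedra per
#' hexahedral cell along a consistent main diagonal. Every tetrahedron has
#' positive signed volume and boundary faces are tagged top/bottom/side.
#'
#' @param spec a [tank_spec()].
#' @param layout optional [electrode_layout()]; its electrode centres become
#'   lattice anchors so each electrode footprint is resolved by boundary faces.
#' @param graded_z logical; grade layer thickness towards the top face
#'   (default: only when a layout is given).
#' @return object of class `eit_mesh` with nodes (mm), tets, per-element
#'   volumes and P1 basis gradients, boundary faces and face-adjacency table.
#' @export
build_tank_mesh <- function(spec, layout = NULL, graded_z = !is.null(layout)) {
  stopifnot(inherits(spec, "tank_spec"))
  h <- spec$target_edge_mm
  if (!is.null(layout)) {
    xs <- axis_lattice(spec$length_mm, unique(layout$centers[, 1]), h, h / 2, min_sub = 2L)
    ys <- axis_lattice(spec$width_mm,  unique(layout$centers[, 2]), h, h / 2, min_sub = 2L)
  } else {
    xs <- axis_lattice(spec$length_mm, numeric(0), h)
    ys <- axis_lattice(spec$width_mm,  numeric(0), h)
  }
  zs <- if (graded_z) graded_z_lattice(spec$height_mm, h / 4, 1.45, 1.6 * h)
        else axis_lattice(spec$height_mm, numeric(0), h)

  nx <- length(xs); ny <- length(ys); nz <- length(zs)
  nodes <- cbind(x = rep(xs, times = ny * nz),
                 y = rep(rep(ys, each = nx), times = nz),
                 z = rep(zs, each = nx * ny))
  nid <- function(i, j, k) i + nx * (j - 1L) + nx * ny * (k - 1L)

  cells <- expand.grid(i = seq_len(nx - 1L), j = seq_len(ny - 1L),
                       k = seq_len(nz - 1L))
  corner <- function(di, dj, dk) nid(cells$i + di, cells$j + dj, cells$k + dk)
  # Kuhn subdivision: path from (0,0,0) to (1,1,1) for each axis permutation
  perms <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
  tet_list <- vector("list", 6L)
  for (p in seq_along(perms)) {
    d <- matrix(0L, 4L, 3L)
    for (s in 1:3) d[(s + 1L):4L, perms[[p]][s]] <- 1L
    tet_list[[p]] <- cbind(corner(d[1, 1], d[1, 2], d[1, 3]),
                           corner(d[2, 1], d[2, 2], d[2, 3]),
                           corner(d[3, 1], d[3, 2], d[3, 3]),
                           corner(d[4, 1], d[4, 2], d[4, 3]))
  }
  tets <- do.call(rbind, tet_list)

  geo <- tet_geometry(nodes, tets)
  neg <- geo$vol6 < 0
  if (any(neg)) {  # orient consistently
    tets[neg, c(1L, 2L)] <- tets[neg, c(2L, 1L)]
    geo <- tet_geometry(nodes, tets)
  }
  if (any(geo$vol6 <= 0)) {
    stop("degenerate (zero-volume) element at index ",
         which(geo$vol6 <= 0)[1])
  }

  bnd <- boundary_and_neighbors(tets, nrow(nodes))
  fz <- matrix(nodes[t(bnd$faces), 3], ncol = 3L, byrow = TRUE)
  tol <- 1e-9 * spec$height_mm
  tag <- ifelse(rowSums(abs(fz) < tol) == 3L, "bottom",
         ifelse(rowSums(abs(fz - spec$height_mm) < tol) == 3L, "top", "side"))

  structure(list(spec = spec, nodes = nodes, tets = tets,
                 n_nodes = nrow(nodes), n_elements = nrow(tets),
                 volume_mm3 = geo$vol6 / 6,
                 grad = geo$grad,     # list Bx,By,Bz: n_el x 4, units 1/mm
                 boundary_faces = bnd$faces, boundary_tag = tag,
                 boundary_tet = bnd$face_tet, neighbors = bnd$neighbors,
                 lattice = list(x = xs, y = ys, z = zs)),
            class = "eit_mesh")
}

# Signed 6*volume and P1 basis gradients for all tets (vectorized).
tet_geometry <- function(nodes, tets) {
  p <- lapply(1:4, function(a) nodes[tets[, a], , drop = FALSE])
  e1 <- p[[2]] - p[[1]]; e2 <- p[[3]] - p[[1]]; e3 <- p[[4]] - p[[1]]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  vol6 <- rowSums(e1 * cr(e2, e3))
  # grad(lambda_a) = n_a / (3V), n_a = inward-oriented area vector of the
  # face opposite vertex a
  opp <- list(c(2, 3, 4), c(1, 4, 3), c(1, 2, 4), c(1, 3, 2))
  Bx <- By <- Bz <- matrix(0, nrow(tets), 4L)
  for (a in 1:4) {
    b <- opp[[a]]
    n <- cr(p[[b[2]]] - p[[b[1]]], p[[b[3]]] - p[[b[1]]]) / 2
    s <- sign(rowSums(n * (p[[a]] - p[[b[1]]])))
    g <- n * s / (vol6 / 2)   # = n/(3V)
    Bx[, a] <- g[, 1]; By[, a] <- g[, 2]; Bz[, a] <- g[, 3]
  }
  list(vol6 = vol6, grad = list(Bx = Bx, By = By, Bz = Bz))
}

# Boundary faces (each used by exactly one tet) and the per-tet face-adjacency
# table (neighbor sharing the face opposite local vertex a, 0 if boundary).
boundary_and_neighbors <- function(tets, n_nodes) {
  n_el <- nrow(tets)
  opp <- list(c(2, 3, 4), c(1, 3, 4), c(1, 2, 4), c(1, 2, 3))
  fa <- fb <- fc <- integer(4L * n_el); ft <- integer(4L * n_el)
  for (a in 1:4) {
    idx <- ((a - 1L) * n_el + 1L):(a * n_el)
    tri <- cbind(tets[, opp[[a]][1]], tets[, opp[[a]][2]], tets[, opp[[a]][3]])
    tri <- t(apply(tri, 1L, sort.int, method = "quick"))
    fa[idx] <- tri[, 1]; fb[idx] <- tri[, 2]; fc[idx] <- tri[, 3]
    ft[idx] <- seq_len(n_el)
  }
  key <- (as.numeric(fa) * n_nodes + fb) * n_nodes + fc
  o <- order(key)
  ks <- key[o]
  first <- c(TRUE, ks[-1] != ks[-length(ks)])
  run <- cumsum(first)
  cnt <- tabulate(run)
  # boundary: runs of length 1
  b_idx <- o[first & cnt[run] == 1L]
  faces <- cbind(fa[b_idx], fb[b_idx], fc[b_idx])
  face_tet <- ft[b_idx]
  # interior: runs of length 2 -> neighbor pairs
  neighbors <- matrix(0L, n_el, 4L)
  i2 <- which(cnt[run] == 2L)
  oi <- o[i2]
  pos1 <- oi[seq(1L, length(oi), by = 2L)]
  pos2 <- oi[seq(2L, length(oi), by = 2L)]
  la <- (pos1 - 1L) %/% n_el + 1L; ta <- ft[pos1]
  lb <- (pos2 - 1L) %/% n_el + 1L; tb <- ft[pos2]
  neighbors[cbind(ta, la)] <- tb
  neighbors[cbind(tb, lb)] <- ta
  list(faces = faces, face_tet = face_tet, neighbors = neighbors)
}

#' Element centroids (mm)
#' @param mesh an `eit_mesh`.
#' @return n_elements x 3 matrix.
#' @export
element_centroids <- function(mesh) {
  (mesh$nodes[mesh$tets[, 1], ] + mesh$nodes[mesh$tets[, 2], ] +
   mesh$nodes[mesh$tets[, 3], ] + mesh$nodes[mesh$tets[, 4], ]) / 4
}

#' @export
print.eit_mesh <- function(x, ...) {
  cat(sprintf("eit_mesh: %d nodes, %d tetrahedra, tank %g x %g x %g mm\n",
              x$n_nodes, x$n_elements, x$spec$length_mm, x$spec$width_mm,
              x$spec$height_mm))
  invisible(x)
}
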