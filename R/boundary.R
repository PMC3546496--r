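#' Interpolate an element field to mesh nodes
#'
#' Node value = volume-weighted average of the values of the incident
#' elements, so a constant element field maps to the identical constant node
#' field. This supplies the continuous scalar field f whose gradient and
#' Laplacian drive the steplike-edge criteria.
#'
#' @param mesh an `eit_mesh`.
#' @param delta_x per-element values (e.g. a reconstructed perturbation).
#' @return object of class `node_scalar_field` with `f` (per node); gradient
#'   and Laplacian slots are filled by [differentiate()].
#' @export
element_to_node_field <- function(mesh, delta_x) {
  stopifnot(length(delta_x) == mesh$n_elements)
  idx <- as.vector(mesh$tets)
  w <- rep(mesh$volume_mm3, 4L)
  v <- rep(delta_x * mesh$volume_mm3, 4L)
  wsum <- rowsum(w, idx)
  vsum <- rowsum(v, idx)
  if (nrow(wsum) != mesh$n_nodes || any(wsum <= 0)) {
    stop("isolated node with no incident element")
  }
  f <- numeric(mesh$n_nodes)
  f[as.integer(rownames(wsum))] <- vsum / wsum
  structure(list(f = f, grad = NULL, lap = NULL, n_nodes = mesh$n_nodes),
            class = "node_scalar_field")
}

#' Gradient and Laplacian of a node field
#'
#' The nodal gradient is the volume-weighted average of the (constant) P1
#' element gradients of f; the nodal Laplacian is the Galerkin discretization
#' with lumped mass, lap = -M^{-1} K f where K is the unit-conductivity
#' stiffness matrix. For a globally linear f the interior gradient is exact
#' and the interior Laplacian vanishes. Units: f per mm and f per mm^2.
#'
#' @param field a `node_scalar_field` (with `f` populated).
#' @param mesh the owning `eit_mesh`.
#' @return the field with `grad` (n_nodes x 3) and `lap` (n_nodes) filled.
#' @export
differentiate <- function(field, mesh) {
  stopifnot(inherits(field, "node_scalar_field"), !is.null(field$f))
  f <- field$f
  tt <- mesh$tets; B <- mesh$grad
  gx <- B$Bx[, 1] * f[tt[, 1]] + B$Bx[, 2] * f[tt[, 2]] +
        B$Bx[, 3] * f[tt[, 3]] + B$Bx[, 4] * f[tt[, 4]]
  gy <- B$By[, 1] * f[tt[, 1]] + B$By[, 2] * f[tt[, 2]] +
        B$By[, 3] * f[tt[, 3]] + B$By[, 4] * f[tt[, 4]]
  gz <- B$Bz[, 1] * f[tt[, 1]] + B$Bz[, 2] * f[tt[, 2]] +
        B$Bz[, 3] * f[tt[, 3]] + B$Bz[, 4] * f[tt[, 4]]
  idx <- as.vector(tt)
  w <- rep(mesh$volume_mm3, 4L)
  acc <- function(g) {
    s <- rowsum(rep(g * mesh$volume_mm3, 4L), idx)
    out <- numeric(mesh$n_nodes)
    out[as.integer(rownames(s))] <- s
    out
  }
  wsum <- acc(rep(1, mesh$n_elements))
  grad <- cbind(acc(gx), acc(gy), acc(gz)) / wsum

  # lumped-mass Galerkin Laplacian: K[a,b] = sum_e V_e grad(phi_a).grad(phi_b)
  Kf_el <- matrix(0, mesh$n_elements, 4L)
  for (a in 1:4) {
    Kf_el[, a] <- mesh$volume_mm3 *
      (B$Bx[, a] * gx + B$By[, a] * gy + B$Bz[, a] * gz)
  }
  Kf <- numeric(mesh$n_nodes)
  s <- rowsum(as.vector(Kf_el), idx)
  Kf[as.integer(rownames(s))] <- s
  lap <- -Kf / (wsum / 4)   # lumped mass = sum V_e / 4
  field$grad <- grad
  field$lap <- lap
  field
}

#' Edge-detection configuration
#'
#' @param threshold_T explicit gradient threshold, or "auto" to take a
#'   percentile of the interior-node gradient magnitude.
#' @param auto_percentile percentile used by "auto" (default 90).
#' @param min_component_size pseudo-edge filter: connected components of edge
#'   elements smaller than this are discarded (default 10).
#' @param use_magnitude detect edges of |delta_x| (default) rather than of the
#'   signed perturbation.
#' @return object of class `edge_detection_config`.
#' @export
edge_detection_config <- function(threshold_T = "auto", auto_percentile = 90,
                                  min_component_size = 10,
                                  use_magnitude = TRUE) {
  if (!identical(threshold_T, "auto")) {
    stopifnot(is.numeric(threshold_T), threshold_T >= 0)
  }
  stopifnot(auto_percentile > 0, auto_percentile < 100, min_component_size >= 1)
  structure(list(threshold_T = threshold_T, auto_percentile = auto_percentile,
                 min_component_size = min_component_size,
                 use_magnitude = use_magnitude),
            class = "edge_detection_config")
}

interior_nodes <- function(mesh) {
  setdiff(seq_len(mesh$n_nodes), unique(as.vector(mesh$boundary_faces)))
}

#' Select the gradient threshold
#'
#' With `threshold_T = "auto"` the threshold is the configured percentile of
#' the gradient magnitude over interior nodes (boundary nodes carry one-sided
#' derivative estimates and are excluded). An explicit threshold passes
#' through unchanged.
#'
#' @param field differentiated `node_scalar_field`.
#' @param mesh the owning `eit_mesh`.
#' @param config an [edge_detection_config()].
#' @return numeric threshold T.
#' @export
select_threshold <- function(field, mesh, config = edge_detection_config()) {
  stopifnot(!is.null(field$grad))
  if (!identical(config$threshold_T, "auto")) return(config$threshold_T)
  gm <- sqrt(rowSums(field$grad^2))
  gm <- gm[interior_nodes(mesh)]
  if (length(gm) == 0) stop("mesh has no interior nodes")
  as.numeric(stats::quantile(gm, config$auto_percentile / 100, names = FALSE))
}

# Unique tet edges. Returns edge node pairs (E x 2) and the element -> edge
# incidence (n_el x 6).
mesh_edges <- function(mesh) {
  if (!is.null(mesh$edge_cache)) return(mesh$edge_cache)
  tt <- mesh$tets
  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  ea <- eb <- matrix(0L, mesh$n_elements, 6L)
  for (k in 1:6) {
    a <- tt[, pairs[[k]][1]]; b <- tt[, pairs[[k]][2]]
    ea[, k] <- pmin(a, b); eb[, k] <- pmax(a, b)
  }
  key <- as.numeric(ea) * mesh$n_nodes + as.numeric(eb)
  uk <- unique(key)
  id <- match(key, uk)
  edges <- cbind(as.numeric(ea)[match(uk, key)], as.numeric(eb)[match(uk, key)])
  list(edges = edges, elem_edges = matrix(id, mesh$n_elements, 6L))
}

#' Detect edge elements
#'
#' A tetrahedron edge (P1, P2) is intersected by the steplike edge surface
#' when both endpoints carry high gradient, |grad f(P1)| + |grad f(P2)| >= 2T,
#' and their Laplacians have opposite signs (a zero-crossing pair; an exactly
#' zero Laplacian counts as positive). A tetrahedron is an edge element when
#' at least three of its six edges are intersected.
#'
#' @param mesh an `eit_mesh`.
#' @param field differentiated `node_scalar_field`.
#' @param T gradient threshold (>= 0), e.g. from [select_threshold()].
#' @return object of class `edge_element_set`: `element_ids`, per-element
#'   intersected-edge count, component labels (filled by [filter_and_grow()]),
#'   and the underlying edge tables.
#' @export
detect_edge_elements <- function(mesh, field, T) {
  stopifnot(!is.null(field$grad), !is.null(field$lap))
  if (T < 0) stop("threshold must be nonnegative")
  me <- mesh_edges(mesh)
  gm <- sqrt(rowSums(field$grad^2))
  sgn <- ifelse(field$lap < 0, -1, 1)   # zero treated as positive
  a <- me$edges[, 1]; b <- me$edges[, 2]
  intersected <- (gm[a] + gm[b] >= 2 * T) & (sgn[a] * sgn[b] < 0)
  n_int <- matrix(intersected[me$elem_edges], mesh$n_elements, 6L)
  n_int <- rowSums(n_int)
  ids <- which(n_int >= 3L)
  structure(list(element_ids = ids, n_intersected = n_int,
                 edge_intersected = intersected, edges = me$edges,
                 elem_edges = me$elem_edges,
                 component_labels = rep(NA_integer_, length(ids))),
            class = "edge_element_set")
}

#' @export
print.edge_element_set <- function(x, ...) {
  cat(sprintf("edge_element_set: %d elements", length(x$element_ids)))
  if (!all(is.na(x$component_labels))) {
    cat(sprintf(" in %d component(s)", length(unique(x$component_labels))))
  }
  cat("\n")
  invisible(x)
}

# connected components of a set of elements under shared-face adjacency
element_components <- function(mesh, ids) {
  if (length(ids) == 0) return(integer(0))
  pos <- integer(mesh$n_elements)
  pos[ids] <- seq_along(ids)
  nb <- mesh$neighbors[ids, , drop = FALSE]
  from <- rep(seq_along(ids), 4L)
  to <- pos[pmax(nb, 1L)] * (nb > 0L)
  keep <- to > 0L
  g <- igraph::graph_from_edgelist(cbind(from[keep], to[keep]), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(ids) - igraph::vcount(g)))
  igraph::components(g)$membership[seq_along(ids)]
}

#' Pseudo-edge removal and 3D region growing
#'
#' Three passes reflecting the extraction procedure: (1) face-adjacency
#' connected components of the detected edge elements are computed and
#' components smaller than `min_component_size` are discarded as pseudo-edges
#' (small interlinked clusters caused by noise); (2) the mesh is cut into
#' horizontal slabs (two mean edge lengths thick) and the surviving elements
#' of each slab become region seeds; (3) any tetrahedron sharing a face with
#' an accepted edge element that itself has at least two intersected edges is
#' appended, iterating to a fixed point.
#'
#' @param edge_set an `edge_element_set` from [detect_edge_elements()].
#' @param mesh the owning `eit_mesh`.
#' @param config an [edge_detection_config()].
#' @return the filtered and grown `edge_element_set` with component labels.
#' @export
filter_and_grow <- function(edge_set, mesh, config = edge_detection_config()) {
  ids <- edge_set$element_ids
  if (length(ids) == 0) return(edge_set)
  comp <- element_components(mesh, ids)
  keep <- ids[comp %in% which(tabulate(comp) >= config$min_component_size)]

  # horizontal slab seeding: record seeds per slab (diagnostic), grow from all
  zc <- element_centroids(mesh)[, 3]
  el <- mesh$nodes[mesh$tets[, 1], ] - mesh$nodes[mesh$tets[, 2], ]
  slab_h <- 2 * mean(sqrt(rowSums(el^2)))
  slab <- pmax(1L, ceiling(zc / slab_h))
  seeds <- split(keep, slab[keep])

  accepted <- logical(mesh$n_elements)
  accepted[keep] <- TRUE
  frontier <- keep
  while (length(frontier) > 0) {
    nb <- unique(as.vector(mesh$neighbors[frontier, , drop = FALSE]))
    nb <- nb[nb > 0L]
    nb <- nb[!accepted[nb]]
    grow <- nb[edge_set$n_intersected[nb] >= 2L]
    accepted[grow] <- TRUE
    frontier <- grow
  }
  ids2 <- which(accepted)
  out <- edge_set
  out$element_ids <- ids2
  out$component_labels <- element_components(mesh, ids2)
  out$slab_seeds <- seeds
  out
}

#' Extract the zero-crossing surface (marching tetrahedra)
#'
#' Triangulates the Laplacian zero-crossing isosurface restricted to the
#' accepted edge elements. Crossing points are linear interpolations of the
#' Laplacian along sign-change edges, computed once per unique mesh edge so
#' that patches from adjacent elements share vertices bit-exactly and the
#' surface is crack-free. Three crossings yield one triangle, four yield two.
#' Triangles are oriented with normals pointing from the negative-Laplacian
#' side (the anomaly interior for a peaked perturbation) towards the positive
#' side. Elements without any sign change are skipped (counted in
#' `n_skipped`).
#'
#' @param edge_set an `edge_element_set`.
#' @param field differentiated `node_scalar_field` (Laplacian used).
#' @param mesh the owning `eit_mesh`.
#' @return object of class `triangle_surface` with `vertices` (mm),
#'   `triangles`, `watertight` flag and `n_skipped`.
#' @export
extract_surface <- function(edge_set, field, mesh) {
  stopifnot(!is.null(field$lap))
  ids <- edge_set$element_ids
  lap <- field$lap
  if (length(ids) == 0) {
    return(structure(list(vertices = matrix(0, 0, 3),
                          triangles = matrix(0L, 0, 3),
                          watertight = FALSE, n_skipped = 0L),
                     class = "triangle_surface"))
  }
  sgn_neg <- lap < 0            # zero counts as positive side
  edges <- edge_set$edges
  cross_edge <- xor(sgn_neg[edges[, 1]], sgn_neg[edges[, 2]])
  # crossing point per unique crossing edge (clamped off the endpoints)
  eidx <- which(cross_edge)
  la <- lap[edges[eidx, 1]]; lb <- lap[edges[eidx, 2]]
  t <- pmin(pmax(la / (la - lb), 1e-6), 1 - 1e-6)
  pa <- mesh$nodes[edges[eidx, 1], , drop = FALSE]
  pb <- mesh$nodes[edges[eidx, 2], , drop = FALSE]
  vtx <- pa + t * (pb - pa)
  vert_of_edge <- integer(nrow(edges))
  vert_of_edge[eidx] <- seq_along(eidx)

  pairs <- list(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  tt <- mesh$tets
  tris <- vector("list", length(ids))
  n_skipped <- 0L
  for (q in seq_along(ids)) {
    e <- ids[q]
    nn <- tt[e, ]
    neg <- which(sgn_neg[nn])
    k <- length(neg)
    if (k == 0L || k == 4L) { n_skipped <- n_skipped + 1L; next }
    ee <- edge_set$elem_edges[e, ]
    loc_cross <- which(cross_edge[ee])
    vids <- vert_of_edge[ee]
    if (k == 1L || k == 3L) {
      apex <- if (k == 1L) neg else setdiff(1:4, neg)
      le <- loc_cross[vapply(loc_cross,
                             function(s) apex %in% pairs[[s]], TRUE)]
      if (length(le) != 3L) { n_skipped <- n_skipped + 1L; next }
      tris[[q]] <- matrix(vids[le], 1L, 3L)
    } else {
      pos <- setdiff(1:4, neg)
      ord <- c(edge_id6(neg[1], pos[1]), edge_id6(neg[1], pos[2]),
               edge_id6(neg[2], pos[2]), edge_id6(neg[2], pos[1]))
      quad <- vids[ord]
      if (any(quad == 0L)) { n_skipped <- n_skipped + 1L; next }
      tris[[q]] <- rbind(quad[c(1, 2, 3)], quad[c(1, 3, 4)])
    }
    # orient: normal from negative side to positive side
    cn <- colMeans(mesh$nodes[nn[setdiff(1:4, neg)], , drop = FALSE]) -
          colMeans(mesh$nodes[nn[neg], , drop = FALSE])
    tm <- tris[[q]]
    for (r in seq_len(nrow(tm))) {
      v1 <- vtx[tm[r, 1], ]; v2 <- vtx[tm[r, 2], ]; v3 <- vtx[tm[r, 3], ]
      nrm <- cross3(v2 - v1, v3 - v1)
      if (sum(nrm * cn) < 0) tm[r, ] <- tm[r, c(1, 3, 2)]
    }
    tris[[q]] <- tm
  }
  tri <- do.call(rbind, tris)
  if (is.null(tri) || nrow(tri) == 0) {
    return(structure(list(vertices = matrix(0, 0, 3),
                          triangles = matrix(0L, 0, 3),
                          watertight = FALSE, n_skipped = n_skipped),
                     class = "triangle_surface"))
  }
  used <- sort(unique(as.vector(tri)))
  remap <- integer(max(used)); remap[used] <- seq_along(used)
  tri <- matrix(remap[tri], ncol = 3L)
  verts <- vtx[used, , drop = FALSE]
  # drop degenerate triangles
  a <- verts[tri[, 1], , drop = FALSE]
  b <- verts[tri[, 2], , drop = FALSE]
  cc <- verts[tri[, 3], , drop = FALSE]
  n2 <- cross3m(b - a, cc - a)
  ok <- sqrt(rowSums(n2^2)) / 2 > 1e-12
  tri <- tri[ok, , drop = FALSE]
  structure(list(vertices = verts, triangles = tri,
                 watertight = is_watertight(tri), n_skipped = n_skipped),
            class = "triangle_surface")
}

# local edge index (1..6) for a vertex pair of a tet
edge_id6 <- function(a, b) {
  key <- paste(min(a, b), max(a, b))
  match(key, c("1 2", "1 3", "1 4", "2 3", "2 4", "3 4"))
}

cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2], u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}
cross3m <- function(u, v) {
  cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
        u[, 3] * v[, 1] - u[, 1] * v[, 3],
        u[, 1] * v[, 2] - u[, 2] * v[, 1])
}

is_watertight <- function(tri) {
  if (nrow(tri) == 0) return(FALSE)
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  all(table(key) == 2L)
}

#' @export
print.triangle_surface <- function(x, ...) {
  cat(sprintf("triangle_surface: %d vertices, %d triangles, %s\n",
              nrow(x$vertices), nrow(x$triangles),
              if (isTRUE(x$watertight)) "watertight" else "open"))
  invisible(x)
}

#' Surface area (mm^2) and enclosed volume (mm^3) of a triangle surface
#'
#' The volume is the signed divergence-theorem sum and is only meaningful for
#' a closed, consistently oriented surface.
#' @param surface a `triangle_surface`.
#' @return numeric scalar.
#' @export
surface_area <- function(surface) {
  if (nrow(surface$triangles) == 0) return(0)
  a <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  b <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  cc <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  sum(sqrt(rowSums(cross3m(b - a, cc - a)^2))) / 2
}

#' @rdname surface_area
#' @export
surface_volume <- function(surface) {
  if (nrow(surface$triangles) == 0) return(0)
  a <- surface$vertices[surface$triangles[, 1], , drop = FALSE]
  b <- surface$vertices[surface$triangles[, 2], , drop = FALSE]
  cc <- surface$vertices[surface$triangles[, 3], , drop = FALSE]
  abs(sum(rowSums(a * cross3m(b, cc)))) / 6
}

#' Detect, filter and extract the anomaly boundary surface
#'
#' Convenience wrapper running the full boundary stage on a reconstruction:
#' node interpolation of |delta_x| (or signed delta_x), differentiation,
#' threshold selection, edge-element detection, pseudo-edge removal with
#' region growing, and zero-crossing surface extraction.
#'
#' @param mesh an `eit_mesh`.
#' @param delta_x per-element reconstructed perturbation.
#' @param config an [edge_detection_config()].
#' @return list with `surface`, `edge_set`, `field` and `threshold`.
#' @export
extract_boundary <- function(mesh, delta_x, config = edge_detection_config()) {
  vals <- if (config$use_magnitude) abs(delta_x) else delta_x
  field <- element_to_node_field(mesh, vals)
  field <- differentiate(field, mesh)
  T <- select_threshold(field, mesh, config)
  es <- detect_edge_elements(mesh, field, T)
  es <- filter_and_grow(es, mesh, config)
  surf <- extract_surface(es, field, mesh)
  list(surface = surf, edge_set = es, field = field, threshold = T)
}
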