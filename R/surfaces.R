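#' Analytic triangle surfaces
#'
#' Closed, consistently outward-oriented triangulations of simple solids:
#' used as phantom ground truth (the cuboid inclusions) and as oracles in
#' tests.
#'
#' @param center_mm 3-vector, mm.
#' @param dims_mm edge lengths (cuboid).
#' @return a `triangle_surface` (watertight).
#' @export
make_cuboid_surface <- function(center_mm, dims_mm) {
  h <- dims_mm / 2
  sgn <- as.matrix(expand.grid(c(-1, 1), c(-1, 1), c(-1, 1)))
  verts <- sweep(sgn * rep(h, each = 8), 2, center_mm, `+`)
  # corners indexed by (x,y,z) sign: 1:(---) 2:(+--) 3:(-+-) 4:(++-)
  #                                  5:(--+) 6:(+-+) 7:(-++) 8:(+++)
  quads <- rbind(c(1, 3, 4, 2),   # z- (outward -z)
                 c(5, 6, 8, 7),   # z+
                 c(1, 2, 6, 5),   # y-
                 c(3, 7, 8, 4),   # y+
                 c(1, 5, 7, 3),   # x-
                 c(2, 4, 8, 6))   # x+
  tri <- do.call(rbind, lapply(seq_len(nrow(quads)), function(q) {
    rbind(quads[q, c(1, 2, 3)], quads[q, c(1, 3, 4)])
  }))
  structure(list(vertices = verts, triangles = tri, watertight = TRUE,
                 n_skipped = 0L),
            class = "triangle_surface")
}

#' @rdname make_cuboid_surface
#' @param radius_mm sphere radius, mm.
#' @param n_theta,n_phi latitude/longitude resolution of the UV sphere.
#' @export
make_sphere_surface <- function(center_mm, radius_mm, n_theta = 48,
                                n_phi = 96) {
  th <- seq(0, pi, length.out = n_theta + 1L)[-c(1, n_theta + 1L)]
  ph <- seq(0, 2 * pi, length.out = n_phi + 1L)[-(n_phi + 1L)]
  ring <- function(t) cbind(sin(t) * cos(ph), sin(t) * sin(ph), cos(t))
  verts <- rbind(c(0, 0, 1), do.call(rbind, lapply(th, ring)), c(0, 0, -1))
  verts <- sweep(verts * radius_mm, 2, center_mm, `+`)
  top <- 1L; bot <- nrow(verts)
  rid <- function(i, j) 1L + (i - 1L) * n_phi + ((j - 1L) %% n_phi) + 1L
  tris <- list()
  tris[[1]] <- cbind(top, rid(1, 1:n_phi), rid(1, 2:(n_phi + 1L)))
  for (i in seq_len(length(th) - 1L)) {
    a <- rid(i, 1:n_phi); b <- rid(i, 2:(n_phi + 1L))
    c2 <- rid(i + 1L, 1:n_phi); d <- rid(i + 1L, 2:(n_phi + 1L))
    tris[[length(tris) + 1L]] <- rbind(cbind(a, c2, b), cbind(b, c2, d))
  }
  i <- length(th)
  tris[[length(tris) + 1L]] <- cbind(rid(i, 1:n_phi), bot, rid(i, 2:(n_phi + 1L)))
  structure(list(vertices = verts, triangles = do.call(rbind, tris),
                 watertight = TRUE, n_skipped = 0L),
            class = "triangle_surface")
}

#' Write a triangle surface to STL (ASCII) or PLY (ASCII)
#' @param surface a `triangle_surface`.
#' @param path output file.
#' @param name solid name recorded in the STL header.
#' @export
write_stl <- function(surface, path, name = "surface") {
  V <- surface$vertices; Tm <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", name), con)
  if (nrow(Tm) > 0) {
    a <- V[Tm[, 1], , drop = FALSE]
    b <- V[Tm[, 2], , drop = FALSE]
    cc <- V[Tm[, 3], , drop = FALSE]
    n <- cross3m(b - a, cc - a)
    n <- n / pmax(sqrt(rowSums(n^2)), 1e-300)
    txt <- sprintf(paste0("facet normal %g %g %g\n outer loop\n",
                          "  vertex %g %g %g\n  vertex %g %g %g\n",
                          "  vertex %g %g %g\n endloop\nendfacet"),
                   n[, 1], n[, 2], n[, 3], a[, 1], a[, 2], a[, 3],
                   b[, 1], b[, 2], b[, 3], cc[, 1], cc[, 2], cc[, 3])
    writeLines(txt, con)
  }
  writeLines(sprintf("endsolid %s", name), con)
  invisible(path)
}

#' @rdname write_stl
#' @export
write_ply <- function(surface, path) {
  V <- surface$vertices; Tm <- surface$triangles
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(V)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(Tm)),
               "property list uchar int vertex_indices", "end_header"), con)
  if (nrow(V) > 0) writeLines(sprintf("%g %g %g", V[, 1], V[, 2], V[, 3]), con)
  if (nrow(Tm) > 0) {
    writeLines(sprintf("3 %d %d %d", Tm[, 1] - 1L, Tm[, 2] - 1L, Tm[, 3] - 1L),
               con)
  }
  invisible(path)
}

#' Read an ASCII STL surface
#'
#' Parses an ASCII STL file back into a `triangle_surface`, merging vertices
#' that coincide exactly so shared edges are restored.
#'
#' @param path STL file path.
#' @return a `triangle_surface`.
#' @export
read_stl <- function(path) {
  ln <- readLines(path)
  vl <- grep("^\\s*vertex", ln, value = TRUE)
  if (length(vl) == 0) {
    return(structure(list(vertices = matrix(0, 0, 3),
                          triangles = matrix(0L, 0, 3),
                          watertight = FALSE, n_skipped = 0L),
                     class = "triangle_surface"))
  }
  num <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"), function(x) {
    as.numeric(x[2:4])
  }))
  key <- apply(num, 1L, paste, collapse = " ")
  uk <- !duplicated(key)
  verts <- num[uk, , drop = FALSE]
  idx <- match(key, key[uk])
  tri <- matrix(idx, ncol = 3L, byrow = TRUE)
  structure(list(vertices = verts, triangles = tri,
                 watertight = is_watertight(tri), n_skipped = 0L),
            class = "triangle_surface")
}
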