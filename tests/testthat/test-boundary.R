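test_that("element-to-node interpolation preserves constants and linear fields", {
  m <- box_mesh(40, 6)
  fld <- element_to_node_field(m, rep(3.5, m$n_elements))
  expect_equal(fld$f, rep(3.5, m$n_nodes), tolerance = 1e-14)
  # linear-in-z element field interpolates to a linear node field
  zc <- element_centroids(m)[, 3]
  fld2 <- element_to_node_field(m, 2 * zc)
  int <- planareit:::interior_nodes(m)
  expect_lt(max(abs(fld2$f[int] - 2 * m$nodes[int, 3])), 1e-6)
})

test_that("gradient and Laplacian are exact on linear fields, consistent on quadratics", {
  m <- box_mesh(80, 5)
  int <- planareit:::interior_nodes(m)
  lin <- differentiate(node_field(m, 3 * m$nodes[, 1] + 2 * m$nodes[, 2] -
                                    m$nodes[, 3]), m)
  expect_lt(max(abs(sweep(lin$grad[int, ], 2, c(3, 2, -1)))), 1e-9)
  expect_lt(max(abs(lin$lap[int])), 1e-9)

  quad <- differentiate(node_field(m, m$nodes[, 1]^2), m)
  expect_lt(max(abs(quad$lap[int] - 2)) / 2, 0.05)

  cst <- differentiate(node_field(m, rep(1, m$n_nodes)), m)
  expect_lt(max(abs(cst$grad)), 1e-12)
  expect_lt(max(abs(cst$lap)), 1e-12)
})

test_that("threshold selection is deterministic and handles flat fields", {
  m <- box_mesh(40, 6)
  cst <- differentiate(node_field(m, rep(2, m$n_nodes)), m)
  expect_identical(select_threshold(cst, m, edge_detection_config()), 0)
  cfg <- edge_detection_config(threshold_T = 0.125)
  expect_identical(select_threshold(cst, m, cfg), 0.125)
})

test_that("a planar step is localized to within two element layers", {
  m <- box_mesh(80, 5)
  z0 <- 40
  fld <- differentiate(node_field(m, tanh((m$nodes[, 3] - z0) / 6)), m)
  cfg <- edge_detection_config()
  T <- select_threshold(fld, m, cfg)
  es <- detect_edge_elements(m, fld, T)
  expect_gt(length(es$element_ids), 0)
  zc <- element_centroids(m)[es$element_ids, 3]
  expect_true(all(abs(zc - z0) <= 2 * 5))
  # auto threshold makes detection invariant to positive rescaling of f
  fld5 <- differentiate(node_field(m, 5 * tanh((m$nodes[, 3] - z0) / 6)), m)
  es5 <- detect_edge_elements(m, fld5, select_threshold(fld5, m, cfg))
  expect_identical(es5$element_ids, es$element_ids)
  # constant field has no edge elements
  cst <- differentiate(node_field(m, rep(1, m$n_nodes)), m)
  expect_identical(length(detect_edge_elements(m, cst, 0.1)$element_ids), 0L)
})

test_that("pseudo-edge filtering drops small components, growth is idempotent", {
  m <- box_mesh(80, 5)
  fld <- differentiate(node_field(m, tanh((m$nodes[, 3] - 40) / 6)), m)
  T <- select_threshold(fld, m, edge_detection_config())
  es <- detect_edge_elements(m, fld, T)
  # inject three isolated fake edge elements far from the step
  cent <- element_centroids(m)
  fake <- which(cent[, 3] < 10)[c(1, 200, 400)]
  es_f <- es
  es_f$element_ids <- sort(c(es$element_ids, fake))
  cfg <- edge_detection_config(min_component_size = 10)
  g1 <- filter_and_grow(es_f, m, cfg)
  expect_true(all(!fake %in% g1$element_ids))
  expect_true(all(es$element_ids %in% g1$element_ids))
  g2 <- filter_and_grow(g1, m, cfg)
  expect_identical(sort(g1$element_ids), sort(g2$element_ids))
})

test_that("marching tetrahedra reproduce a plane exactly", {
  m <- box_mesh(80, 5)
  z0 <- 40
  fld <- field_with_lap(m, tanh((m$nodes[, 3] - z0) / 6), m$nodes[, 3] - z0)
  es <- detect_edge_elements(m, fld, 0)
  surf <- extract_surface(es, fld, m)
  expect_gt(nrow(surf$triangles), 0)
  expect_lt(max(abs(surf$vertices[, 3] - z0)), 1e-4)
  expect_lt(abs(surface_area(surf) - 80 * 80) / (80 * 80), 1e-9)
})

test_that("marching tetrahedra recover a sphere within 5%", {
  m <- box_mesh(80, 4)
  r <- sqrt(rowSums(sweep(m$nodes, 2, c(40, 40, 40))^2))
  fld <- field_with_lap(m, 1 / (1 + exp((r - 25) / 5)), r - 25)
  es <- detect_edge_elements(m, fld, 0)
  surf <- extract_surface(es, fld, m)
  expect_true(surf$watertight)
  expect_identical(surface_components(surf), 1L)
  expect_lt(abs(surface_area(surf) - 4 * pi * 25^2) / (4 * pi * 25^2), 0.05)
  expect_lt(abs(surface_volume(surf) - 4 / 3 * pi * 25^3) /
              (4 / 3 * pi * 25^3), 0.05)
  # crack-free splicing: every interior edge is shared by exactly two
  # triangles referencing the identical interpolated vertex
  tri <- surf$triangles
  ed <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  key <- paste(pmin(ed[, 1], ed[, 2]), pmax(ed[, 1], ed[, 2]))
  expect_true(all(table(key) == 2L))
})

test_that("two disjoint anomalies yield two surface components", {
  m <- box_mesh(80, 5)
  r1 <- sqrt(rowSums(sweep(m$nodes, 2, c(22, 22, 40))^2))
  r2 <- sqrt(rowSums(sweep(m$nodes, 2, c(58, 58, 40))^2))
  fld <- field_with_lap(m, 1 / (1 + exp((pmin(r1, r2) - 12) / 4)),
                        pmin(r1 - 12, r2 - 12))
  es <- detect_edge_elements(m, fld, 0)
  surf <- extract_surface(es, fld, m)
  expect_identical(surface_components(surf), 2L)
})

test_that("the smoothed-sphere zero crossing sits at its analytic radius", {
  # For a radial logistic profile the Laplacian crossing is not at the
  # half-amplitude radius; solve lap(f)(r*) = 0 numerically and check the
  # discrete pipeline against that oracle.
  w <- 5; R <- 25
  lapf <- function(r) {
    s <- 1 / (1 + exp((r - R) / w))
    d1 <- -s * (1 - s) / w
    d2 <- s * (1 - s) * (1 - 2 * s) / w^2
    d2 + 2 * d1 / r
  }
  rstar <- uniroot(lapf, c(R, R + 3 * w))$root
  m <- box_mesh(120, 4)
  r <- sqrt(rowSums(sweep(m$nodes, 2, c(60, 60, 60))^2))
  fld <- differentiate(node_field(m, 1 / (1 + exp((r - R) / w))), m)
  cfg <- edge_detection_config()
  es <- filter_and_grow(
    detect_edge_elements(m, fld, select_threshold(fld, m, cfg)), m, cfg)
  surf <- extract_surface(es, fld, m)
  expect_true(surf$watertight)
  rv <- sqrt(rowSums(sweep(surf$vertices, 2, c(60, 60, 60))^2))
  expect_lt(abs(mean(rv) - rstar) / rstar, 0.05)
  expect_lt(abs(surface_area(surf) - 4 * pi * rstar^2) / (4 * pi * rstar^2),
            0.05)
})
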