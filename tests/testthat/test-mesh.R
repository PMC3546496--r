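test_that("tetrahedra tile the tank exactly with positive volumes", {
  for (m in list(small_mesh(), box_mesh(40, 6))) {
    tank_vol <- m$spec$length_mm * m$spec$width_mm * m$spec$height_mm
    expect_lt(abs(sum(m$volume_mm3) - tank_vol) / tank_vol, 1e-9)
    expect_true(all(m$volume_mm3 > 0))
  }
})

test_that("boundary surface of the box is closed (Euler characteristic 2)", {
  m <- small_mesh()
  faces <- m$boundary_faces
  verts <- unique(as.vector(faces))
  edges <- unique(c(paste(pmin(faces[, 1], faces[, 2]), pmax(faces[, 1], faces[, 2])),
                    paste(pmin(faces[, 2], faces[, 3]), pmax(faces[, 2], faces[, 3])),
                    paste(pmin(faces[, 1], faces[, 3]), pmax(faces[, 1], faces[, 3]))))
  expect_identical(length(verts) - length(edges) + nrow(faces), 2L)
})

test_that("desk-scale default mesh has order 1e4-1e5 elements", {
  cfg <- pipeline_config()
  m <- build_tank_mesh(cfg$tank, cfg$electrodes)
  expect_gte(m$n_elements, 1e4)
  expect_lte(m$n_elements, 1e5)
  # electrode centres are lattice vertices of the top face
  expect_true(all(unique(cfg$electrodes$centers[, 1]) %in% m$lattice$x))
  expect_true(all(unique(cfg$electrodes$centers[, 2]) %in% m$lattice$y))
  assign("desk_mesh", list(cfg = cfg, mesh = m), envir = .fixture_cache)
})

test_that("every electrode is resolved by at least three disjoint faces", {
  m <- small_mesh()
  ef <- planareit:::electrode_faces(m, small_layout())
  n_f <- vapply(ef$face_idx, length, 1L)
  expect_true(all(n_f >= 3L))
  expect_identical(anyDuplicated(unlist(ef$face_idx)), 0L)
})

test_that("invalid tank specs are rejected", {
  expect_error(tank_spec(60, 60, 40, target_edge_mm = 15), "target_edge_mm")
  expect_error(tank_spec(-10, 60, 40), "is not TRUE")
})
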