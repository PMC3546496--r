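test_that("voxel-counting an axis-aligned cuboid is exact", {
  g <- voxel_grid()
  expect_identical(n_cubes(g), 2160000)
  cub <- make_cuboid_surface(c(90, 75, 40), c(40, 40, 40))
  g1 <- classify_nodes(cub, g)
  # closed-region convention: boundary lattice nodes count as enclosed
  expect_identical(sum(g1$inside_flags), 68921L)  # 41^3
  st <- count_valid_cubes(g1)
  expect_identical(st$valid_cube_count, 64000L)
  expect_identical(st$volume_ml, 64)
})

test_that("sphere classification matches the analytic volume within 1%", {
  sp <- make_sphere_surface(c(90, 75, 40), 25)
  g1 <- classify_nodes(sp, voxel_grid())
  vol_flags <- sum(g1$inside_flags) / 1000
  v_true <- 4 / 3 * pi * 25^3 / 1000
  expect_lt(abs(vol_flags - v_true) / v_true, 0.01)
  # valid-cube rule trims a sub-voxel boundary layer on curved solids
  st <- count_valid_cubes(g1)
  expect_lt(abs(st$volume_ml - v_true) / v_true, 0.025)
})

test_that("empty and open surfaces are handled as specified", {
  empty <- structure(list(vertices = matrix(0, 0, 3),
                          triangles = matrix(0L, 0, 3),
                          watertight = FALSE, n_skipped = 0L),
                     class = "triangle_surface")
  g <- classify_nodes(empty, voxel_grid(1, c(20, 20, 20)))
  expect_identical(sum(g$inside_flags), 0L)
  open_surf <- make_cuboid_surface(c(10, 10, 10), c(8, 8, 8))
  open_surf$triangles <- open_surf$triangles[-1, ]
  open_surf$watertight <- FALSE
  expect_error(classify_nodes(open_surf, voxel_grid(1, c(20, 20, 20))),
               "watertight")
  expect_silent(classify_nodes(open_surf, voxel_grid(1, c(20, 20, 20)),
                               allow_open = TRUE))
})

test_that("valid-cube rule needs four non-coplanar enclosed vertices", {
  g <- voxel_grid(1, c(1, 1, 1))
  # all four flagged vertices on one cube face -> invalid
  g$inside_flags <- array(FALSE, c(2, 2, 2))
  g$inside_flags[, , 1] <- TRUE
  expect_identical(count_valid_cubes(g)$valid_cube_count, 0L)
  # three on a face plus one off it -> valid
  g$inside_flags[1, 1, 1] <- FALSE
  g$inside_flags[1, 1, 2] <- TRUE
  expect_identical(count_valid_cubes(g)$valid_cube_count, 1L)
  # full grid: every cube valid
  g2 <- voxel_grid(1, c(5, 4, 3))
  g2$inside_flags <- array(TRUE, c(6, 5, 4))
  expect_identical(count_valid_cubes(g2)$valid_cube_count, 60L)
})

test_that("volume estimation is monotone in the enclosed set", {
  set.seed(21)
  g <- voxel_grid(1, c(8, 8, 8))
  flags <- array(runif(9^3) < 0.4, c(9, 9, 9))
  g$inside_flags <- flags
  n1 <- count_valid_cubes(g)$valid_cube_count
  more <- flags
  more[sample(which(!flags), 50)] <- TRUE
  g$inside_flags <- more
  expect_gte(count_valid_cubes(g)$valid_cube_count, n1)
})

test_that("half-amplitude center of mass behaves geometrically", {
  m <- box_mesh(40, 6)
  cent <- element_centroids(m)
  dx <- numeric(m$n_elements)
  dx[10] <- -2
  expect_equal(center_of_mass(dx, m), as.numeric(cent[10, ]), tolerance = 1e-12)
  # symmetric pair of equal magnitude -> midpoint
  i <- which.min(rowSums(sweep(cent, 2, c(10, 20, 20))^2))
  j <- which.min(rowSums(sweep(cent, 2, c(30, 20, 20))^2))
  dx2 <- numeric(m$n_elements); dx2[c(i, j)] <- c(1, -1)
  expect_equal(center_of_mass(dx2, m),
               as.numeric((cent[i, ] + cent[j, ]) / 2), tolerance = 1e-12)
  # translation equivariance of a blob pattern on the structured mesh
  blob <- function(c0) exp(-rowSums(sweep(cent, 2, c0)^2) / 50)
  shift <- c(diff(m$lattice$x)[1], 0, 0)  # one lattice cell
  p1 <- center_of_mass(blob(c(14, 20, 20)), m)
  p2 <- center_of_mass(blob(c(14, 20, 20) + shift), m)
  expect_equal(p2 - p1, shift, tolerance = 1e-6)
  expect_error(center_of_mass(numeric(m$n_elements), m), "zero")
})

test_that("error figures of merit are plain signed percentages", {
  tk <- tank_spec(180, 150, 100)
  expect_equal(position_error(c(90, 75, 50), c(90, 75, 50), tk), c(0, 0, 0))
  expect_equal(position_error(c(99, 75, 50), c(90, 75, 50), tk), c(5, 0, 0))
  expect_equal(volume_error(62.8, 64), -1.875)
  expect_equal(volume_error(115.4, 125), -7.68)
  expect_equal(volume_error(64, 64), 0)
})
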