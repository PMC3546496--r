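test_that("complete electrode model conserves current at every electrode", {
  m <- small_mesh()
  ly <- small_layout()
  f0 <- make_conductivity_field(m, 0.1)
  sol <- solve_forward(m, f0, ly, injection_index = 0, current_ma = 10)
  I <- 10e-3
  cur <- sol$electrode_currents_a
  expect_lt(abs(cur[1] - I), 1e-8 * I)                 # driven
  expect_lt(max(abs(cur[2:4])), 1e-8 * I)              # idle electrodes
  expect_lt(abs(cur[5] + I), 1e-8 * I)                 # back electrode sink
  expect_lt(abs(sum(cur)), 1e-8 * I)                   # net zero
})

test_that("measurements obey reciprocity and the frame has canonical shape", {
  m <- small_mesh()
  ly <- small_layout()
  fr <- simulate_frame(m, make_conductivity_field(m, 0.1), ly)
  expect_identical(length(fr$values), 4L * 3L)
  tab <- planareit:::frame_index_table(4)
  for (p in list(c(1, 2), c(1, 4), c(2, 3), c(3, 4))) {
    vij <- fr$values[tab[, 1] == p[1] & tab[, 2] == p[2]]
    vji <- fr$values[tab[, 1] == p[2] & tab[, 2] == p[1]]
    expect_lt(abs(vij - vji) / abs(vij), 1e-6)
  }
})

test_that("plate-electrode bar matches the series-resistance closed form", {
  # full-coverage electrodes on top and bottom of a square bar: the CEM
  # solution is exactly 1D, so the P1 discretization reproduces
  # V = I * (L/(sigma A) + 2 z/A) to solver precision
  tk <- tank_spec(20, 20, 40, target_edge_mm = 4.5)
  ly <- electrode_layout(tk, n_rows = 1, n_cols = 1, radius_mm = 9.9,
                         gap_mm = 1, back_radius_mm = 9.9,
                         contact_impedance_ohm_m2 = 0.01)
  m <- build_tank_mesh(tk, ly)
  sigma <- 0.25
  sol <- solve_forward(m, make_conductivity_field(m, sigma), ly, 0,
                       current_ma = 10)
  A <- 20e-3 * 20e-3; L <- 40e-3; I <- 10e-3; z <- 0.01
  v_exact <- I * (L / (sigma * A) + 2 * z / A)
  expect_lt(abs(sol$electrode_voltages[1] - v_exact) / v_exact, 1e-8)
})

test_that("scaling conductivity and contact impedance together scales voltages", {
  m <- small_mesh()
  tk <- small_tank()
  ly1 <- small_layout()
  ly2 <- electrode_layout(tk, n_rows = 2, n_cols = 2, radius_mm = 2,
                          gap_mm = 8, back_radius_mm = 6,
                          contact_impedance_ohm_m2 = ly1$contact_impedance_ohm_m2 / 2)
  fr1 <- simulate_frame(m, make_conductivity_field(m, 0.1), ly1)
  fr2 <- simulate_frame(m, make_conductivity_field(m, 0.2), ly2)
  expect_lt(max(abs(2 * fr2$values - fr1$values) / abs(fr1$values)), 1e-9)
})

test_that("zero or negative conductivity is rejected", {
  m <- small_mesh()
  f0 <- make_conductivity_field(m, 0.1)
  f0$values[10] <- 0
  expect_error(simulate_frame(m, f0, small_layout()), "positive")
})
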