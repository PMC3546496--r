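test_that("conductivity fields are piecewise constant and positive", {
  m <- small_mesh()
  f0 <- make_conductivity_field(m, 0.1)
  expect_true(all(f0$values == 0.1))

  inc <- inclusion_spec("cuboid", c(30, 30, 20), c(20, 20, 20), 0.892)
  f1 <- make_conductivity_field(m, 0.1, list(inc))
  expect_setequal(unique(f1$values), c(0.1, 0.892))
  # volume-weighted inclusion fraction close to the analytic volume ratio
  frac <- sum(m$volume_mm3[f1$values == 0.892]) / sum(m$volume_mm3)
  expect_lt(abs(frac - 20^3 / (60 * 60 * 40)), 0.01)

  # two disjoint inclusions are additive
  inc2 <- inclusion_spec("sphere", c(12, 12, 12), 6, 0.5)
  f2 <- make_conductivity_field(m, 0.1, list(inc, inc2))
  expect_identical(sum(f2$values != 0.1),
                   sum(f1$values == 0.892) + sum(f2$values == 0.5))

  expect_error(
    make_conductivity_field(m, 0.1,
                            list(inclusion_spec("cuboid", c(55, 30, 20),
                                                c(20, 20, 20)))),
    "contained")
})

test_that("noise generator is seeded, unbiased and hits the requested SNR", {
  fr <- measurement_frame(sin(1:4032) + 2, 64, 10, "simulated")
  expect_identical(add_noise(fr, Inf, 1)$values, fr$values)
  n1 <- add_noise(fr, 40, 123)
  n2 <- add_noise(fr, 40, 123)
  expect_identical(n1$values, n2$values)
  expect_false(identical(add_noise(fr, 40, 124)$values, n1$values))

  # Monte-Carlo estimate of the realized SNR over many frames
  noise2 <- signal2 <- 0
  for (s in 1:200) {
    nf <- add_noise(fr, 40, s)
    noise2 <- noise2 + sum((nf$values - fr$values)^2)
    signal2 <- signal2 + sum(fr$values^2)
  }
  snr_emp <- 10 * log10(signal2 / noise2)
  expect_lt(abs(snr_emp - 40), 0.5)
})

test_that("measurement frames round-trip through CSV bit-exactly", {
  set.seed(5)
  fr <- measurement_frame(rnorm(4 * 3), n_electrodes = 4)
  path <- withr::local_tempfile(fileext = ".csv")
  write_frame_csv(fr, path)
  back <- read_frame_csv(path, n_electrodes = 4)
  expect_identical(back$values, fr$values)
})

test_that("frame ordering is the canonical injection-major order", {
  tab <- planareit:::frame_index_table(64)
  expect_identical(nrow(tab), 64L * 63L)
  expect_true(all(tab[, 1] != tab[, 2]))
  expect_identical(unname(tab[1:3, 2]), c(2L, 3L, 4L))
  expect_identical(unname(tab[64, 2]), 1L)  # second injection starts over
})
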