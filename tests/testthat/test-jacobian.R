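test_that("adjoint Jacobian matches the finite-difference oracle", {
  m <- small_mesh()
  ly <- small_layout()
  f0 <- make_conductivity_field(m, 0.1)
  J <- compute_jacobian(m, f0, ly)
  expect_identical(dim(J$entries), c(4L * 3L, m$n_elements))
  expect_true(all(is.finite(J$entries)))

  fr0 <- simulate_frame(m, f0, ly)
  dsig <- 1e-3 * 0.1
  set.seed(42)
  for (e in sample.int(m$n_elements, 5)) {
    fp <- f0
    fp$values[e] <- fp$values[e] + dsig
    fd <- (simulate_frame(m, fp, ly)$values - fr0$values) / dsig
    rel <- sqrt(sum((fd - J$entries[, e])^2)) / sqrt(sum(fd^2))
    expect_lt(rel, 0.01)
  }
})

test_that("Jacobian sign convention matches difference imaging (Eq. J dx = dV)", {
  m <- small_mesh()
  ly <- small_layout()
  f0 <- make_conductivity_field(m, 0.1)
  inc <- inclusion_spec("sphere", c(30, 30, 25), 8, 0.12)
  f1 <- make_conductivity_field(m, 0.1, list(inc))
  J <- compute_jacobian(m, f0, ly)
  dv <- simulate_frame(m, f0, ly)$values - simulate_frame(m, f1, ly)$values
  pred <- as.numeric(J$entries %*% (f0$values - f1$values))
  expect_gt(cor(pred, dv), 0.999)
  # zero perturbation predicts zero voltage change
  expect_identical(as.numeric(J$entries %*% numeric(m$n_elements)),
                   numeric(4L * 3L))
})

test_that("sensitivity is stronger under the array centre than at corners", {
  cj <- cond_jacobian()
  m <- cj$mesh
  cent <- element_centroids(m)
  norms <- sqrt(colSums(cj$J$entries^2))
  depth <- cent[, 3] > 12 & cent[, 3] < 20      # same depth band
  mid <- depth & sqrt((cent[, 1] - 18)^2 + (cent[, 2] - 18)^2) < 8
  corner <- depth & (pmin(cent[, 1], 36 - cent[, 1]) < 6) &
    (pmin(cent[, 2], 36 - cent[, 2]) < 6)
  expect_gt(mean(norms[mid]), mean(norms[corner]))
})
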