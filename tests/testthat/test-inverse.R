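test_that("closed-form identities hold", {
  # J = I, lambda = 1: (I + I)^{-1} dv = dv / 2
  r <- solve_tikhonov(diag(3), c(2, 4, 6), lambda = 1)
  expect_equal(r$delta_x, c(1, 2, 3), tolerance = 1e-12)
  # diagonal NOSER: dx_i = J_ii dv_i / (J_ii^2 (1 + eps))
  J <- diag(c(1, 2)); dv <- c(3, 5); eps <- 0.5
  r2 <- solve_noser(J, dv, eps)
  expect_equal(r2$delta_x, diag(J) * dv / (diag(J)^2 * 1.5), tolerance = 1e-12)
  # dv = 0 -> dx = 0
  expect_identical(solve_combined(matrix(rnorm(12), 3), numeric(3),
                                  1, 0.3)$delta_x, numeric(4))
})

test_that("all three solvers agree with the dense normal-equations oracle", {
  set.seed(11)
  for (dims in list(c(20, 10), c(30, 15), c(40, 25), c(25, 60), c(100, 100))) {
    J <- matrix(rnorm(prod(dims)), dims[1])
    dv <- rnorm(dims[1])
    lam <- 0.1; eps <- 0.3
    d0 <- colSums(J^2)
    oracle <- function(D) solve(crossprod(J) + D, crossprod(J, dv))
    o_t <- oracle(lam * diag(dims[2]))
    o_n <- oracle(diag(eps * d0))
    o_c <- oracle(lam * diag(dims[2]) + diag(eps * d0))
    expect_lt(max(abs(solve_tikhonov(J, dv, lam)$delta_x - o_t)) / max(abs(o_t)), 1e-8)
    expect_lt(max(abs(solve_noser(J, dv, eps)$delta_x - o_n)) / max(abs(o_n)), 1e-8)
    expect_lt(max(abs(solve_combined(J, dv, lam, eps)$delta_x - o_c)) / max(abs(o_c)), 1e-8)
  }
})

test_that("combined regularization has the right limiting behaviour", {
  set.seed(12)
  J <- matrix(rnorm(40 * 25), 40); dv <- rnorm(40)
  nos <- solve_noser(J, dv, 0.3)$delta_x
  tik <- solve_tikhonov(J, dv, 0.5)$delta_x
  expect_lt(max(abs(solve_combined(J, dv, 1e-12, 0.3)$delta_x - nos)) /
              max(abs(nos)), 1e-6)
  expect_lt(max(abs(solve_combined(J, dv, 0.5, 1e-12)$delta_x - tik)) /
              max(abs(tik)), 1e-6)
})

test_that("solutions are linear in the data", {
  set.seed(13)
  J <- matrix(rnorm(30 * 50), 30); dv <- rnorm(30)
  r1 <- solve_combined(J, dv, 0.2, 0.3)$delta_x
  r3 <- solve_combined(J, 3 * dv, 0.2, 0.3)$delta_x
  expect_equal(r3, 3 * r1, tolerance = 1e-12)
})

test_that("invalid parameters and degenerate systems are rejected", {
  J <- matrix(rnorm(20), 5)
  expect_error(solve_tikhonov(J, rnorm(5), lambda = 0), "lambda")
  expect_error(solve_noser(J, rnorm(5), epsilon = 1), "epsilon")
  expect_error(regularization_config("combined", lambda = -1), "lambda")
  J0 <- cbind(J, 0)  # element with no sensitivity
  expect_error(solve_noser(J0, rnorm(5), 0.3), "element")
})

test_that("regularization strictly reduces the condition number", {
  expect_identical(condition_number(diag(3), "jacobian"), 1)
  expect_identical(condition_number(diag(c(2, 1)), "jacobian"), 2)
  set.seed(14)
  J <- matrix(rnorm(30 * 40), 30)
  raw <- kappa(crossprod(J), exact = TRUE)
  for (meth in c("tikhonov", "noser", "combined")) {
    expect_lt(condition_number(J, meth, lambda = 0.5, epsilon = 0.3), raw)
  }
})

test_that("condition numbers reproduce the reference ordering of the methods", {
  # On the small phantom, in the comparison regime lambda < eps * min diag
  # (the regime the published typical values correspond to):
  # cond(J) > Tikhonov > NOSER > combined.
  cj <- cond_jacobian()
  eps <- 0.3
  lam <- 0.1 * eps * min(colSums(cj$J$entries^2))
  c_j <- condition_number(cj$J, "jacobian")
  c_t <- condition_number(cj$J, "tikhonov", lambda = lam)
  c_n <- condition_number(cj$J, "noser", epsilon = eps)
  c_c <- condition_number(cj$J, "combined", lambda = lam, epsilon = eps)
  expect_gt(c_j, c_t)
  expect_gt(c_t, c_n)
  expect_gt(c_n, c_c)
})
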