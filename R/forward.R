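#' @importFrom Matrix sparseMatrix forceSymmetric Cholesky solve crossprod
NULL

# Assemble the complete-electrode-model FEM system.
#
# Unknowns: N node potentials followed by the electrode voltages (array
# electrodes then the back electrode). The back electrode is the voltage
# reference; its DOF is eliminated (grounded). All assembly is done in SI
# units (mesh coordinates are mm and converted here).
cem_system <- function(mesh, field, layout) {
  stopifnot(inherits(mesh, "eit_mesh"), inherits(field, "conductivity_field"),
            inherits(layout, "electrode_layout"))
  if (field$n_elements != mesh$n_elements) {
    stop("conductivity field does not match the mesh")
  }
  if (any(field$values <= 0)) stop("conductivity must be positive everywhere")
  N <- mesh$n_nodes
  ef <- electrode_faces(mesh, layout)
  n_arr <- layout$n_electrodes
  n_e <- n_arr + 1L
  z <- rep(layout$contact_impedance_ohm_m2, n_e)

  # stiffness: K[a,b] += sigma * V_m3 * grad_a . grad_b (grads in 1/m)
  # mm-unit factors: vol(mm^3)*1e-9 * grad(1/mm)^2*1e6 = 1e-3
  B <- mesh$grad
  sig_v <- field$values * mesh$volume_mm3 * 1e-3
  ii <- jj <- vector("list", 16L); xx <- vector("list", 16L); k <- 0L
  for (a in 1:4) for (b in 1:4) {
    k <- k + 1L
    ii[[k]] <- mesh$tets[, a]; jj[[k]] <- mesh$tets[, b]
    xx[[k]] <- sig_v * (B$Bx[, a] * B$Bx[, b] + B$By[, a] * B$By[, b] +
                        B$Bz[, a] * B$Bz[, b])
  }
  Ki <- unlist(ii); Kj <- unlist(jj); Kx <- unlist(xx)

  # electrode boundary terms
  az_i <- az_j <- integer(0); az_x <- numeric(0)
  w_i <- w_j <- integer(0); w_x <- numeric(0)
  Dvec <- numeric(n_e)
  for (l in seq_len(n_e)) {
    fidx <- ef$face_idx[[l]]
    tri <- ef$faces[fidx, , drop = FALSE]
    A_m2 <- ef$area_mm2[fidx] * 1e-6
    Dvec[l] <- sum(A_m2) / z[l]
    # triangle mass matrix A/12 * (2 on diag, 1 off)
    for (a in 1:3) for (b in 1:3) {
      az_i <- c(az_i, tri[, a]); az_j <- c(az_j, tri[, b])
      az_x <- c(az_x, A_m2 / 12 * ifelse(a == b, 2, 1) / z[l])
    }
    for (a in 1:3) {
      w_i <- c(w_i, tri[, a]); w_j <- c(w_j, rep(l, nrow(tri)))
      w_x <- c(w_x, -A_m2 / 3 / z[l])
    }
  }
  Wmat <- sparseMatrix(i = w_i, j = w_j, x = w_x, dims = c(N, n_e))

  ndof <- N + n_e - 1L   # back electrode DOF dropped (ground)
  keep_w <- w_j < n_e
  A <- sparseMatrix(
    i = c(Ki, az_i, w_i[keep_w], N + w_j[keep_w], N + seq_len(n_e - 1L)),
    j = c(Kj, az_j, N + w_j[keep_w], w_i[keep_w], N + seq_len(n_e - 1L)),
    x = c(Kx, az_x, w_x[keep_w], w_x[keep_w], Dvec[-n_e]),
    dims = c(ndof, ndof))
  list(A = forceSymmetric(A), N = N, n_arr = n_arr, n_e = n_e,
       Wmat = Wmat, Dvec = Dvec, efaces = ef)
}

cem_factor <- function(sys) {
  tryCatch(Cholesky(sys$A, LDL = FALSE),
           error = function(e) stop("singular forward system: ",
                                    conditionMessage(e)))
}

# Solve for a set of injection patterns. Returns node potentials (N x k) and
# electrode voltages ((n_arr+1) x k, back electrode = 0 by construction).
cem_solve <- function(sys, fac, injections, current_a) {
  B <- matrix(0, nrow(sys$A), length(injections))
  B[cbind(sys$N + injections, seq_along(injections))] <- current_a
  X <- as.matrix(solve(fac, B))
  U <- rbind(X[sys$N + seq_len(sys$n_arr), , drop = FALSE],
             0)  # back electrode grounded
  list(u = X[seq_len(sys$N), , drop = FALSE], U = U)
}

# Net current through each electrode implied by a solution (amperes):
# I_l = |E_l|/z * U_l - 1/z * int_E u dS
electrode_net_currents <- function(sys, u, U) {
  as.numeric(sys$Dvec * U + crossprod(sys$Wmat, u))
}

#' Solve the forward problem for one injection
#'
#' Complete-electrode-model solve with current entering the indexed array
#' electrode and returning through the grounded back electrode.
#'
#' @param mesh an `eit_mesh`.
#' @param field a `conductivity_field`.
#' @param layout an [electrode_layout()].
#' @param injection_index 0-based index of the driven array electrode.
#' @param current_ma injection amplitude in mA (default 10).
#' @return list with `node_potentials` (volts, per node), `electrode_voltages`
#'   (array electrodes then back electrode, referenced to the back electrode)
#'   and `electrode_currents_a` (net current per electrode, amperes).
#' @export
solve_forward <- function(mesh, field, layout, injection_index,
                          current_ma = 10) {
  stopifnot(injection_index >= 0, injection_index < layout$n_electrodes)
  sys <- cem_system(mesh, field, layout)
  fac <- cem_factor(sys)
  sol <- cem_solve(sys, fac, injection_index + 1L, current_ma * 1e-3)
  list(node_potentials = sol$u[, 1],
       electrode_voltages = sol$U[, 1],
       electrode_currents_a = electrode_net_currents(sys, sol$u[, 1], sol$U[, 1]))
}

#' Simulate a full measurement frame
#'
#' Runs all injections (each array electrode in turn against the back
#' electrode) and collects, for each injection, the voltages of the remaining
#' array electrodes in ascending order — 64 x 63 = 4032 values for the
#' default array.
#'
#' @inheritParams solve_forward
#' @param current_ma injection amplitude in mA.
#' @return a [measurement_frame()] of kind "simulated".
#' @export
simulate_frame <- function(mesh, field, layout, current_ma = 10) {
  sys <- cem_system(mesh, field, layout)
  fac <- cem_factor(sys)
  n_arr <- layout$n_electrodes
  sol <- cem_solve(sys, fac, seq_len(n_arr), current_ma * 1e-3)
  tab <- frame_index_table(n_arr)
  vals <- sol$U[cbind(tab[, 2], tab[, 1])]
  measurement_frame(vals, n_arr, current_ma, "simulated")
}

#' Sensitivity (Jacobian) matrix by the adjoint method
#'
#' Derivative of every measurement with respect to each element's
#' conductivity at the reference field, J[m, e] = dV_m / dsigma_e, computed
#' from the adjoint identity dV_ij/dsigma_e = -(1/I) int_e grad(u_i).grad(u_j)
#' where u_i are the drive solutions. The sign convention matches difference
#' imaging: J (x_p - x) approximately equals V_p - V.
#'
#' @inheritParams solve_forward
#' @param current_ma injection amplitude in mA.
#' @return object of class `sensitivity_matrix`; `$entries` has one row per
#'   measurement (canonical frame order) and one column per element, units
#'   V per (S/m).
#' @export
compute_jacobian <- function(mesh, field, layout, current_ma = 10) {
  sys <- cem_system(mesh, field, layout)
  fac <- cem_factor(sys)
  n_arr <- layout$n_electrodes
  I_a <- current_ma * 1e-3
  sol <- cem_solve(sys, fac, seq_len(n_arr), I_a)
  tt <- mesh$tets; B <- mesh$grad
  # element-wise gradients of each drive field, V/m (grads are 1/mm -> *1e3)
  gfield <- function(Bc) {
    (Bc[, 1] * sol$u[tt[, 1], , drop = FALSE] +
     Bc[, 2] * sol$u[tt[, 2], , drop = FALSE] +
     Bc[, 3] * sol$u[tt[, 3], , drop = FALSE] +
     Bc[, 4] * sol$u[tt[, 4], , drop = FALSE]) * 1e3
  }
  Gx <- gfield(B$Bx); Gy <- gfield(B$By); Gz <- gfield(B$Bz)
  scale <- -(mesh$volume_mm3 * 1e-9) / I_a
  blocks <- vector("list", n_arr)
  for (i in seq_len(n_arr)) {
    meas <- setdiff(seq_len(n_arr), i)
    M <- (Gx[, meas, drop = FALSE] * Gx[, i] +
          Gy[, meas, drop = FALSE] * Gy[, i] +
          Gz[, meas, drop = FALSE] * Gz[, i]) * scale
    blocks[[i]] <- t(M)
  }
  J <- do.call(rbind, blocks)
  if (!all(is.finite(J))) stop("non-finite entries in the sensitivity matrix")
  structure(list(entries = J, n_electrodes = n_arr, current_ma = current_ma),
            class = "sensitivity_matrix")
}

#' @export
print.sensitivity_matrix <- function(x, ...) {
  cat(sprintf("sensitivity_matrix: %d measurements x %d elements\n",
              nrow(x$entries), ncol(x$entries)))
  invisible(x)
}

#' Write a sensitivity matrix in Matrix Market format
#' @param J a `sensitivity_matrix`.
#' @param path output file (.mtx).
#' @export
write_jacobian_mtx <- function(J, path) {
  Matrix::writeMM(Matrix::Matrix(J$entries, sparse = TRUE), path)
  invisible(path)
}
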