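#' Finite-difference duct shear (independent cross-check solver)
#'
#' Solves the Poisson problem of fully developed laminar duct flow,
#' `mu lap(u) = -G` with no-slip walls, on a second-order five-point grid
#' over the rectangular cross-section, then scales the pressure gradient so
#' the integrated velocity matches the prescribed flow rate and evaluates
#' the bottom-wall shear at the lateral centerline with a one-sided
#' second-order difference. The route shares nothing with the Fourier-series
#' solution in [rect_duct_shear()], so the two serve as mutual checks.
#'
#' @inheritParams inlet_velocity
#' @param n_y,n_z number of grid points across the width and height
#'   (defaults 241; odd, so the centerline is a grid node).
#' @return wall shear stress in Pa.
#' @export
fd_duct_shear <- function(condition, geometry, n_y = 241, n_z = 241) {
  stopifnot(inherits(condition, "flow_condition"),
            inherits(geometry, "channel_geometry"))
  if (n_y < 10 || n_z < 10) stop("grid too coarse", call. = FALSE)
  n_y <- as.integer(n_y); n_z <- as.integer(n_z)
  if (n_y %% 2L == 0L) n_y <- n_y + 1L  # keep the centerline on the grid
  w <- geometry$width; h <- geometry$height
  dy <- w / (n_y - 1); dz <- h / (n_z - 1)
  ny_i <- n_y - 2L; nz_i <- n_z - 2L  # interior nodes

  # -lap(u1) = 1 with u1 = 0 on the boundary; u = (G/mu) u1
  d2 <- function(n, dd) {
    Matrix::bandSparse(n, n, k = c(-1, 0, 1),
                       diagonals = list(rep(1 / dd^2, n - 1),
                                        rep(-2 / dd^2, n),
                                        rep(1 / dd^2, n - 1)))
  }
  A <- Matrix::kronecker(Matrix::Diagonal(nz_i), d2(ny_i, dy)) +
       Matrix::kronecker(d2(nz_i, dz), Matrix::Diagonal(ny_i))
  # -A is symmetric positive definite: use a sparse Cholesky factorization
  ch <- Matrix::Cholesky(Matrix::forceSymmetric(-A), LDL = FALSE)
  u1 <- Matrix::solve(ch, rep(1, ny_i * nz_i), system = "A")
  U <- matrix(0, n_y, n_z)
  U[2:(n_y - 1), 2:(n_z - 1)] <- as.numeric(u1)

  # trapezoidal integral of u1 over the cross-section (boundary rows are 0)
  q1 <- sum(U) * dy * dz
  mu <- condition$fluid$dynamic_viscosity
  G <- mu * condition$flow_rate / q1

  # du/dz at z = 0, y = 0 (mid column), one-sided second order, u(wall) = 0
  mid <- (n_y + 1L) %/% 2L
  dudz <- (4 * U[mid, 2] - U[mid, 3]) / (2 * dz)
  G * dudz
}
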