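# Displacement-field algebra: composition, fixed-point inversion, Jacobian.

# partial derivative of a 3D array along one axis (central differences,
# one-sided at the two border slabs), in physical units (per mm)
array_gradient <- function(a, axis, spacing) {
  s <- dim(a)
  n <- s[axis]
  idx_p <- c(2:n, n)       # forward neighbor (clamped)
  idx_m <- c(1, 1:(n - 1)) # backward neighbor (clamped)
  # denominator: 2h interior, h at the two borders
  den <- rep(2 * spacing, n)
  den[1] <- spacing
  den[n] <- spacing
  if (axis == 1L) {
    g <- (a[idx_p, , , drop = FALSE] - a[idx_m, , , drop = FALSE]) /
      array(den, dim = s)
  } else if (axis == 2L) {
    g <- (a[, idx_p, , drop = FALSE] - a[, idx_m, , drop = FALSE]) /
      array(rep(den, each = s[1]), dim = s)
  } else {
    g <- (a[, , idx_p, drop = FALSE] - a[, , idx_m, drop = FALSE]) /
      array(rep(den, each = s[1] * s[2]), dim = s)
  }
  g
}

#' Compose two displacement fields
#'
#' Returns the field `w` of the composed mapping
#' `x + w(x) = phi_outer(phi_inner(x))`, i.e.
#' `w(x) = u_inner(x) + u_outer(x + u_inner(x))` with the outer field
#' trilinearly interpolated at the displaced points (zero displacement is
#' assumed beyond the outer field's hull).
#'
#' @param outer,inner [vector_field()]s on the same grid; `inner` is applied
#'   first.
#' @return A [vector_field()] on the common grid.
#' @export
compose_fields <- function(outer, inner) {
  stopifnot(inherits(outer, "vector_field"), inherits(inner, "vector_field"))
  if (!same_grid(outer$grid, inner$grid))
    stop("compose_fields requires both fields on the same grid")
  ui <- field_matrix(inner)
  pts <- grid_points(inner$grid) + ui
  uo <- sample_field(outer, pts)
  matrix_field(inner$grid, ui + uo)
}

#' Invert a displacement field by fixed-point iteration
#'
#' Finds `v` with `phi^-1(y) = y + v(y)` for `phi(x) = x + u(x)` by iterating
#' `v_{k+1}(y) = -u(y + v_k(y))`, which converges for small-deformation
#' diffeomorphisms. Positivity of the Jacobian determinant is checked first.
#'
#' @param field A [vector_field()] with strictly positive Jacobian
#'   determinant.
#' @param tol Convergence tolerance in mm on the maximum voxel update
#'   (default 0.01 mm).
#' @param max_iter Maximum number of fixed-point iterations (default 50).
#' @return A [vector_field()] holding the inverse displacements, with
#'   attributes `iterations` and `residual_mm` (the final maximum update,
#'   which equals the maximum composition residual `|phi(phi^-1(y)) - y|` at
#'   the previous iterate).
#' @export
invert_field <- function(field, tol = 0.01, max_iter = 50L) {
  stopifnot(inherits(field, "vector_field"), tol > 0, max_iter >= 1)
  jd <- jacobian_determinant(field)
  if (min(jd$values) <= 0)
    stop(sprintf(
      "invert_field: field is not invertible (min Jacobian determinant %.4g)",
      min(jd$values)))
  pts <- grid_points(field$grid)
  v <- matrix(0, nrow(pts), 3)
  resid <- Inf
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    u_at <- sample_field(field, pts + v)
    v_new <- -u_at
    resid <- max(sqrt(rowSums((v_new - v)^2)))
    v <- v_new
    if (resid < tol) break
  }
  if (resid >= tol) {
    res_map <- scalar_volume(field$grid, sqrt(rowSums((sample_field(field, pts + v) + v)^2)))
    stop(structure(class = c("dirqa_inversion_error", "error", "condition"),
                   list(message = sprintf(
                     "invert_field did not converge in %d iterations (max update %.4g mm)",
                     max_iter, resid),
                     call = sys.call(-1), residual_map = res_map)))
  }
  out <- matrix_field(field$grid, v)
  attr(out, "iterations") <- it
  attr(out, "residual_mm") <- resid
  out
}

#' Jacobian determinant of a deformation
#'
#' Computes `det(I + grad u)` of the mapping `phi(x) = x + u(x)` at every
#' voxel, with derivatives taken by central differences in physical (mm)
#' coordinates (one-sided at the grid borders). Values of 1 indicate local
#' volume preservation, values below 1 local contraction; positivity
#' everywhere indicates an invertible (orientation-preserving) deformation.
#'
#' @param field A [vector_field()] on a grid with at least 3 voxels per axis.
#' @return A [scalar_volume()] of determinant values.
#' @export
jacobian_determinant <- function(field) {
  stopifnot(inherits(field, "vector_field"))
  if (any(field$grid$shape < 3L))
    stop("jacobian_determinant needs at least 3 voxels per axis")
  s <- field$grid$shape
  sp <- field$grid$spacing
  u <- field$displacements
  J <- vector("list", 9)
  for (i in 1:3) {
    ui <- array(u[, , , i], dim = s)
    for (j in 1:3) {
      g <- array_gradient(ui, j, sp[j])
      if (i == j) g <- g + 1
      J[[(i - 1) * 3 + j]] <- g
    }
  }
  # det of rows (J11 J12 J13; J21 J22 J23; J31 J32 J33), elementwise
  det_ <- J[[1]] * (J[[5]] * J[[9]] - J[[6]] * J[[8]]) -
          J[[2]] * (J[[4]] * J[[9]] - J[[6]] * J[[7]]) +
          J[[3]] * (J[[4]] * J[[8]] - J[[5]] * J[[7]])
  scalar_volume(field$grid, det_)
}
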