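#' Thin-plate-spline displacement field
#'
#' Fits a 3-D thin-plate-spline interpolant (radial kernel `phi(r) = r` plus
#' an affine term) to control-point displacements, independently per
#' component, by solving the standard augmented TPS linear system, and
#' evaluates the resulting field on a grid. The interpolant reproduces the
#' prescribed displacement exactly at every control point.
#'
#' @param control_points `n x 3` matrix of control-point world coordinates
#'   (mm); at least 4 non-coplanar points, no duplicates.
#' @param displacements `n x 3` matrix of displacements (mm) at the control
#'   points.
#' @param grid An [image_grid()] on which to evaluate the field.
#' @return A [vector_field()] on `grid`.
#' @examples
#' g <- image_grid(c(8, 8, 8), spacing = c(5, 5, 5))
#' cp <- rbind(c(5, 5, 5), c(30, 5, 10), c(5, 30, 15), c(20, 20, 30))
#' d  <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(-1, 0, 0))
#' f <- tps_field(cp, d, g)
#' @export
tps_field <- function(control_points, displacements, grid) {
  control_points <- as_point_matrix(control_points)
  displacements <- as_point_matrix(displacements)
  n <- nrow(control_points)
  stopifnot(nrow(displacements) == n)
  if (n < 4)
    stop("tps_field needs at least 4 control points")
  D <- as.matrix(stats::dist(control_points))
  if (any(D[upper.tri(D)] < 1e-9))
    stop("tps_field: duplicate control points")
  # coplanarity check: rank of centered points must be 3
  cen <- sweep(control_points, 2, colMeans(control_points))
  if (qr(cen)$rank < 3)
    stop("tps_field: control points are coplanar")
  P <- cbind(1, control_points)
  A <- rbind(cbind(D, P), cbind(t(P), matrix(0, 4, 4)))
  rhs <- rbind(displacements, matrix(0, 4, 3))
  coef <- tryCatch(solve(A, rhs),
                   error = function(e) stop("tps_field: singular TPS system"))
  w <- coef[1:n, , drop = FALSE]
  a <- coef[(n + 1):(n + 4), , drop = FALSE]
  pts <- grid_points(grid)
  u <- tps_eval(pts, control_points, w, a)
  matrix_field(grid, u)
}

# evaluate the fitted TPS at arbitrary points, blockwise to bound memory
tps_eval <- function(pts, cp, w, a, block = 65536L) {
  n <- nrow(pts)
  u <- matrix(0, n, 3)
  for (start in seq(1L, n, by = block)) {
    idx <- start:min(start + block - 1L, n)
    p <- pts[idx, , drop = FALSE]
    # |p_i - cp_j| without forming cubes: squared-distance expansion
    d2 <- outer(rowSums(p^2), rowSums(cp^2), "+") - 2 * p %*% t(cp)
    R <- sqrt(pmax(d2, 0))
    u[idx, ] <- R %*% w + cbind(1, p) %*% a
  }
  u
}
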