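# Internal numerics shared across modules: separable Gaussian smoothing,
# grid resampling, smooth blending windows.

# 1D Gaussian convolution matrix (n x n), kernel truncated at 3 sigma and
# row-renormalized so constants are preserved at the borders
gaussian_conv_matrix <- function(n, sigma_vox) {
  if (sigma_vox <= 0) return(diag(n))
  r <- max(1L, ceiling(3 * sigma_vox))
  offs <- (-r):r
  w <- exp(-offs^2 / (2 * sigma_vox^2))
  K <- matrix(0, n, n)
  for (d in seq_along(offs)) {
    o <- offs[d]
    i <- seq_len(n)
    j <- i + o
    ok <- j >= 1 & j <= n
    K[cbind(i[ok], j[ok])] <- K[cbind(i[ok], j[ok])] + w[d]
  }
  K / rowSums(K)
}

# separable Gaussian smoothing of a 3D array; sigma in voxels per axis
gaussian_smooth_array <- function(a, sigma_vox) {
  s <- dim(a)
  sigma_vox <- rep(sigma_vox, length.out = 3)
  if (sigma_vox[1] > 0) {
    K <- gaussian_conv_matrix(s[1], sigma_vox[1])
    dim(a) <- c(s[1], s[2] * s[3])
    a <- K %*% a
    dim(a) <- s
  }
  if (sigma_vox[2] > 0) {
    K <- gaussian_conv_matrix(s[2], sigma_vox[2])
    a <- aperm(array(a, s), c(2, 1, 3))
    dim(a) <- c(s[2], s[1] * s[3])
    a <- K %*% a
    dim(a) <- c(s[2], s[1], s[3])
    a <- aperm(a, c(2, 1, 3))
  }
  if (sigma_vox[3] > 0) {
    K <- gaussian_conv_matrix(s[3], sigma_vox[3])
    a <- aperm(array(a, s), c(3, 2, 1))
    dim(a) <- c(s[3], s[2] * s[1])
    a <- K %*% a
    dim(a) <- c(s[3], s[2], s[1])
    a <- aperm(a, c(3, 2, 1))
  }
  array(a, s)
}

#' Gaussian smoothing of a scalar volume
#'
#' Separable Gaussian filter with physical-length scale; the kernel is
#' truncated at 3 sigma and renormalized at the borders so constants are
#' preserved.
#'
#' @param volume A [scalar_volume()].
#' @param sigma_mm Smoothing scale in mm (scalar or per-axis triple).
#' @return A smoothed [scalar_volume()].
#' @export
smooth_volume <- function(volume, sigma_mm) {
  stopifnot(inherits(volume, "scalar_volume"))
  sig_vox <- rep(sigma_mm, length.out = 3) / volume$grid$spacing
  scalar_volume(volume$grid, gaussian_smooth_array(volume$values, sig_vox))
}

smooth_field <- function(field, sigma_mm) {
  sig_vox <- rep(sigma_mm, length.out = 3) / field$grid$spacing
  u <- field$displacements
  for (c_ in 1:3) {
    u[, , , c_] <- gaussian_smooth_array(array(u[, , , c_], dim = field$grid$shape),
                                         sig_vox)
  }
  vector_field(field$grid, u)
}

#' Resample a scalar volume onto another grid
#'
#' Trilinear resampling at the voxel centers of the target grid; values
#' outside the source hull take `fill`.
#'
#' @param volume A [scalar_volume()].
#' @param grid Target [image_grid()].
#' @param fill Out-of-hull fill value (default `min(volume$values)`).
#' @return A [scalar_volume()] on `grid`.
#' @export
resample_volume <- function(volume, grid, fill = min(volume$values)) {
  res <- trilinear_core(volume$values, volume$grid, grid_points(grid), fill)
  scalar_volume(grid, res$values)
}

#' Resample a vector field onto another grid
#'
#' Each displacement component is interpolated trilinearly; displacements
#' outside the source hull are set to zero (identity continuation). Used to
#' bring imported test DVFs sampled on a vendor grid onto the ground-truth
#' grid before comparison.
#'
#' @param field A [vector_field()].
#' @param grid Target [image_grid()].
#' @return A [vector_field()] on `grid`.
#' @export
resample_field <- function(field, grid) {
  u <- sample_field(field, grid_points(grid))
  matrix_field(grid, u)
}

# C1 smoothstep: 0 for t <= 0, 1 for t >= 1
smoothstep <- function(t) {
  t <- pmin(pmax(t, 0), 1)
  t * t * (3 - 2 * t)
}

# radial C1 window: 1 inside r0, falls to 0 at r1
radial_window <- function(r, r0, r1) {
  1 - smoothstep((r - r0) / (r1 - r0))
}

# normalized RMS error: RMSE over the mask divided by the intensity range of
# the reference volume
nrmse <- function(reference, test, mask = NULL) {
  a <- reference$values
  b <- test$values
  if (!is.null(mask)) {
    sel <- mask$membership
    a <- a[sel]
    b <- b[sel]
  }
  sqrt(mean((a - b)^2)) / diff(range(reference$values))
}
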