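# Vectorized trilinear interpolation on regular grids. The 8-neighbor gather
# uses linear indexing into the column-major array; points outside the voxel-
# center hull get the fill value and are flagged.

trilinear_core <- function(values, grid, points, fill, clamp = FALSE) {
  s <- grid$shape
  t_idx <- world_to_index(grid, points)
  outside <- t_idx[, 1] < 0 | t_idx[, 1] > s[1] - 1 |
             t_idx[, 2] < 0 | t_idx[, 2] > s[2] - 1 |
             t_idx[, 3] < 0 | t_idx[, 3] > s[3] - 1
  if (clamp) {
    # edge extension: interpolate at the nearest hull point instead of fill
    t_idx[, 1] <- pmin(pmax(t_idx[, 1], 0), s[1] - 1)
    t_idx[, 2] <- pmin(pmax(t_idx[, 2], 0), s[2] - 1)
    t_idx[, 3] <- pmin(pmax(t_idx[, 3], 0), s[3] - 1)
  }
  # lower corner, clamped so the 8-cell stays in bounds even at the far face
  i0 <- pmin.int(pmax.int(floor(t_idx[, 1]), 0), s[1] - 2)
  j0 <- pmin.int(pmax.int(floor(t_idx[, 2]), 0), s[2] - 2)
  k0 <- pmin.int(pmax.int(floor(t_idx[, 3]), 0), s[3] - 2)
  fx <- t_idx[, 1] - i0
  fy <- t_idx[, 2] - j0
  fz <- t_idx[, 3] - k0
  n1 <- s[1]; n12 <- s[1] * s[2]
  base <- 1 + i0 + n1 * j0 + n12 * k0
  v000 <- values[base]
  v100 <- values[base + 1]
  v010 <- values[base + n1]
  v110 <- values[base + n1 + 1]
  v001 <- values[base + n12]
  v101 <- values[base + n12 + 1]
  v011 <- values[base + n12 + n1]
  v111 <- values[base + n12 + n1 + 1]
  # symmetric form: exact at f = 0 and f = 1, so node sampling (including
  # the clamped far faces) returns stored values bit-identically
  gx <- 1 - fx; gy <- 1 - fy; gz <- 1 - fz
  c00 <- gx * v000 + fx * v100
  c10 <- gx * v010 + fx * v110
  c01 <- gx * v001 + fx * v101
  c11 <- gx * v011 + fx * v111
  c0 <- gy * c00 + fy * c10
  c1 <- gy * c01 + fy * c11
  out <- gz * c0 + fz * c1
  if (!clamp && any(outside)) out[outside] <- fill
  list(values = out, outside = outside)
}

as_point_matrix <- function(points) {
  if (is.null(dim(points))) {
    stopifnot(length(points) %% 3 == 0)
    points <- matrix(points, ncol = 3, byrow = TRUE)
  }
  points <- as.matrix(points)
  stopifnot(ncol(points) == 3)
  if (any(!is.finite(points)))
    stop("point coordinates must be finite")
  points
}

#' Trilinear sampling of a scalar volume at world points
#'
#' Interpolates the volume at arbitrary world positions (mm) using the 8
#' surrounding voxel-center values. Points outside the voxel-center hull
#' return `fill` and are flagged in the `outside` attribute of the result.
#' Sensible fills are 0 for dose grids and `min(volume$values)` (air) for
#' CT-like images.
#'
#' @param volume A [scalar_volume()].
#' @param points An `n x 3` matrix of world coordinates in mm (a length-3
#'   vector is accepted for a single point).
#' @param fill Value returned for points outside the grid hull.
#' @return Numeric vector of interpolated values, with a logical attribute
#'   `outside` marking out-of-hull points.
#' @examples
#' g <- image_grid(c(4, 4, 4))
#' v <- scalar_volume(g, seq_len(64))
#' trilinear_sample(v, c(1, 1, 1))   # a voxel center: the stored value
#' @export
trilinear_sample <- function(volume, points, fill = 0) {
  stopifnot(inherits(volume, "scalar_volume"))
  points <- as_point_matrix(points)
  res <- trilinear_core(volume$values, volume$grid, points, fill)
  structure(res$values, outside = res$outside)
}

# trilinear interpolation of each field component; returns n x 3 matrix.
# Displacements are edge-extended (clamped sampling) beyond the hull so
# field algebra (composition, inversion) stays well defined at the borders.
sample_field <- function(field, points) {
  points <- as_point_matrix(points)
  n <- n_voxels(field$grid)
  u <- field$displacements
  dim(u) <- c(n, 3L)
  out <- matrix(0, nrow(points), 3)
  outside <- NULL
  for (c_ in 1:3) {
    res <- trilinear_core(array(u[, c_], dim = field$grid$shape),
                          field$grid, points, 0, clamp = TRUE)
    out[, c_] <- res$values
    outside <- res$outside
  }
  attr(out, "outside") <- outside
  out
}

#' Warp a volume through a displacement field (pull-back)
#'
#' Computes `out(x) = moving(x + u(x))` at every voxel center `x` of the
#' field's grid, by trilinear interpolation of the moving volume. This is
#' pull-back warping: the output lives on the field (target/SOT) grid and the
#' field points into the moving (source/EOT) space.
#'
#' @param moving A [scalar_volume()] to be resampled.
#' @param field A [vector_field()] defined on the output grid.
#' @param fill Fill value for displaced points that leave the moving volume's
#'   hull; defaults to `min(moving$values)`.
#' @return A [scalar_volume()] on the field's grid. The fraction of
#'   out-of-hull target voxels is recorded in the `outside_fraction`
#'   attribute.
#' @export
warp_volume <- function(moving, field, fill = min(moving$values)) {
  stopifnot(inherits(moving, "scalar_volume"), inherits(field, "vector_field"))
  pts <- grid_points(field$grid) + field_matrix(field)
  res <- trilinear_core(moving$values, moving$grid, pts, fill)
  out <- scalar_volume(field$grid, res$values)
  attr(out, "outside_fraction") <- mean(res$outside)
  out
}

#' Warp a binary mask through a displacement field
#'
#' Pull-back warp of the mask indicator with trilinear interpolation followed
#' by thresholding at 0.5; used to carry ROI masks between the SOT and EOT
#' anatomies.
#'
#' @param mask An [roi_mask()].
#' @param field A [vector_field()] on the output grid.
#' @return An [roi_mask()] on the field's grid.
#' @export
warp_mask <- function(mask, field) {
  ind <- scalar_volume(mask$grid, as.numeric(mask$membership))
  w <- warp_volume(ind, field, fill = 0)
  roi_mask(field$grid, mask$name, w$values >= 0.5)
}
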