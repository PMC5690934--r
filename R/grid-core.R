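#' Regular image grid geometry
#'
#' An `image_grid` describes the geometry shared by all volumetric objects in
#' dirqa: a regular, axis-aligned voxel lattice. Voxel indices are 0-based and
#' the world position (mm) of the center of voxel `(i, j, k)` is
#' `origin + c(i, j, k) * spacing` (voxel-center convention). World axes are
#' aligned with grid axes; all lengths are millimetres.
#'
#' @param shape Integer triple, voxels per axis; every entry must be >= 2.
#' @param spacing Numeric triple, voxel spacing in mm; strictly positive.
#' @param origin Numeric triple, world position (mm) of the center of voxel
#'   `(0, 0, 0)`.
#' @return An object of class `image_grid`.
#' @examples
#' g <- image_grid(c(16, 16, 16), spacing = c(2.5, 2.5, 3))
#' g
#' @export
image_grid <- function(shape, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  stopifnot(length(shape) == 3L, length(spacing) == 3L, length(origin) == 3L)
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("grid spacing must be finite and strictly positive")
  if (any(shape < 2L))
    stop("grid must have at least 2 voxels per axis")
  if (any(!is.finite(origin)))
    stop("grid origin must be finite")
  structure(list(shape = shape, spacing = spacing, origin = origin),
            class = "image_grid")
}

#' @export
print.image_grid <- function(x, ...) {
  cat("image_grid:", paste(x$shape, collapse = " x "),
      "voxels, spacing", paste(format(x$spacing), collapse = " x "),
      "mm, origin (", paste(format(x$origin), collapse = ", "), ") mm\n")
  invisible(x)
}

#' @export
format.image_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(format(x$spacing), collapse = "x"), " mm")
}

n_voxels <- function(grid) prod(grid$shape)

same_grid <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    max(abs(a$spacing - b$spacing)) < tol &&
    max(abs(a$origin - b$origin)) < tol
}

#' World coordinates of the voxel centers along each axis
#'
#' @param grid An [image_grid()].
#' @return A list of three numeric vectors (mm), one per axis.
#' @keywords internal
grid_axes <- function(grid) {
  lapply(1:3, function(a) {
    grid$origin[a] + (seq_len(grid$shape[a]) - 1) * grid$spacing[a]
  })
}

#' World coordinates of every voxel center
#'
#' Returns an `n x 3` matrix in array (column-major) order, i.e. row `r`
#' corresponds to the voxel with linear index `r` of an array with the grid's
#' dimensions.
#'
#' @param grid An [image_grid()].
#' @return Numeric matrix, one world point (mm) per voxel.
#' @export
grid_points <- function(grid) {
  s <- grid$shape
  ax <- grid_axes(grid)
  cbind(rep(ax[[1]], times = s[2] * s[3]),
        rep(rep(ax[[2]], each = s[1]), times = s[3]),
        rep(ax[[3]], each = s[1] * s[2]))
}

world_to_index <- function(grid, points) {
  # continuous 0-based voxel indices of world points (n x 3)
  sweep(sweep(points, 2, grid$origin, "-"), 2, grid$spacing, "/")
}

#' Scalar volume on a regular grid
#'
#' A scalar value per voxel: Hounsfield units for CT-like images, Gy for dose
#' grids, mm for TRE maps.
#'
#' @param grid An [image_grid()].
#' @param values Numeric array with `dim == grid$shape` (or a vector of
#'   matching length); all values must be finite.
#' @return An object of class `scalar_volume`.
#' @export
scalar_volume <- function(grid, values) {
  stopifnot(inherits(grid, "image_grid"))
  values <- array(as.numeric(values), dim = grid$shape)
  if (any(!is.finite(values)))
    stop("scalar_volume values must be finite everywhere")
  structure(list(grid = grid, values = values), class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat("scalar_volume on", format(x$grid),
      sprintf("| range [%.4g, %.4g]\n", min(x$values), max(x$values)))
  invisible(x)
}

#' Displacement vector field on a regular grid
#'
#' One 3-vector (mm, world axes) per voxel. The field lives on the target
#' (SOT) grid and maps target world points into source (EOT) space via
#' `phi(x) = x + u(x)`; a zero field is the identity. This matches the
#' adaptive-radiotherapy arrangement in which dose computed on the EOT
#' anatomy is pulled back onto the SOT anatomy.
#'
#' @param grid An [image_grid()].
#' @param displacements Numeric array with `dim == c(grid$shape, 3)` (or a
#'   vector of matching length); finite everywhere.
#' @return An object of class `vector_field`.
#' @export
vector_field <- function(grid, displacements) {
  stopifnot(inherits(grid, "image_grid"))
  displacements <- array(as.numeric(displacements), dim = c(grid$shape, 3L))
  if (any(!is.finite(displacements)))
    stop("vector_field displacements must be finite everywhere")
  structure(list(grid = grid, displacements = displacements),
            class = "vector_field")
}

#' Zero (identity) displacement field
#'
#' @param grid An [image_grid()].
#' @return A [vector_field()] with all displacements zero.
#' @export
zero_field <- function(grid) {
  vector_field(grid, array(0, dim = c(grid$shape, 3L)))
}

#' @export
print.vector_field <- function(x, ...) {
  mag <- sqrt(rowSums(field_matrix(x)^2))
  cat("vector_field on", format(x$grid),
      sprintf("| |u| mean %.3g mm, max %.3g mm\n", mean(mag), max(mag)))
  invisible(x)
}

# displacements as an n x 3 matrix in array order
field_matrix <- function(field) {
  n <- n_voxels(field$grid)
  dim(field$displacements) <- c(n, 3L)
  m <- field$displacements
  m
}

matrix_field <- function(grid, m) {
  vector_field(grid, array(m, dim = c(grid$shape, 3L)))
}

#' Displacement magnitude map of a field
#'
#' @param field A [vector_field()].
#' @return A [scalar_volume()] of per-voxel displacement norms (mm).
#' @export
field_magnitude <- function(field) {
  scalar_volume(field$grid, sqrt(rowSums(field_matrix(field)^2)))
}

#' Binary region-of-interest mask
#'
#' @param grid An [image_grid()].
#' @param name ROI name; the phantom organ set is `brainstem`, `cord`,
#'   `mandible`, `parotid_l`, `parotid_r`, `external`, but any non-empty name
#'   is accepted.
#' @param membership Logical array with `dim == grid$shape`; at least one
#'   voxel must be TRUE.
#' @return An object of class `roi_mask`.
#' @export
roi_mask <- function(grid, name, membership) {
  stopifnot(inherits(grid, "image_grid"), is.character(name), nzchar(name))
  membership <- array(as.logical(membership), dim = grid$shape)
  if (any(is.na(membership)))
    stop("mask membership must not contain NA")
  if (!any(membership))
    stop("roi_mask must contain at least one voxel: ", name)
  structure(list(grid = grid, name = name, membership = membership),
            class = "roi_mask")
}

#' @export
print.roi_mask <- function(x, ...) {
  cat("roi_mask '", x$name, "' on ", format(x$grid), " | ",
      sum(x$membership), " voxels\n", sep = "")
  invisible(x)
}

#' Number of member voxels of a mask
#' @param mask An [roi_mask()].
#' @return Integer voxel count.
#' @export
mask_size <- function(mask) sum(mask$membership)

#' Physical volume of a mask in cubic centimetres
#' @param mask An [roi_mask()].
#' @return Volume in cm^3.
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$membership) * prod(mask$grid$spacing) / 1000
}

#' Centroid of a mask in world coordinates
#' @param mask An [roi_mask()].
#' @return Numeric triple (mm).
#' @export
mask_centroid <- function(mask) {
  pts <- grid_points(mask$grid)
  colMeans(pts[as.vector(mask$membership), , drop = FALSE])
}
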