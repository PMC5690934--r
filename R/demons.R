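# Built-in multi-resolution demons registration. Classic intensity-gradient
# demons: per-voxel update d = (m(phi) - f) grad f / (|grad f|^2 + (m(phi)-f)^2)
# with Gaussian regularization of the field after every iteration, run
# coarse-to-fine with trilinear field upsampling between levels. No initial
# rigid registration is applied. Output follows the package convention:
# the field lives on the fixed (SOT) grid and maps into moving (EOT) space,
# directly comparable to a phantom's ground-truth field.

#' Demons registration configuration
#'
#' @param levels Pyramid depth (>= 1); level `l` uses a grid downsampled by
#'   `2^(levels - l)`.
#' @param iterations Iterations per level, coarsest first (recycled to
#'   `levels`).
#' @param smoothing_sigma Gaussian field regularization (mm) applied after
#'   every iteration.
#' @param image_sigma Gaussian pre-smoothing (mm) of both images at full
#'   resolution, on top of the anti-alias smoothing used for downsampling.
#' @param step_normalization Cap each voxel update at
#'   `max_step_vox` voxels (the classic demons stabilization).
#' @param max_step_vox Update cap in voxel units.
#' @return An object of class `demons_config`.
#' @export
demons_config <- function(levels = 3L, iterations = c(60, 40, 20),
                          smoothing_sigma = 4, image_sigma = 2,
                          step_normalization = TRUE, max_step_vox = 0.8) {
  stopifnot(levels >= 1, smoothing_sigma > 0, all(iterations >= 0))
  structure(list(levels = as.integer(levels),
                 iterations = rep(as.integer(iterations),
                                  length.out = levels),
                 smoothing_sigma = smoothing_sigma,
                 image_sigma = image_sigma,
                 step_normalization = isTRUE(step_normalization),
                 max_step_vox = max_step_vox),
            class = "demons_config")
}

coarsen_grid <- function(grid, factor) {
  if (factor == 1) return(grid)
  shape <- pmax(floor((grid$shape - 1) / factor) + 1, 4)
  image_grid(shape, grid$spacing * factor, grid$origin)
}

#' Demons deformable registration
#'
#' Registers `moving` (the EOT image) onto `fixed` (the SOT image) and
#' returns the displacement field in the SOT-to-EOT convention. Voxels with
#' vanishing intensity gradient and residual receive no update (stabilized
#' denominator). The images must share a world extent; intensities are used
#' as-is (no histogram matching), and the result is invariant to a common
#' global intensity offset.
#'
#' @param fixed,moving [scalar_volume()]s.
#' @param config A [demons_config()].
#' @return A [vector_field()] on the fixed grid.
#' @export
demons_register <- function(fixed, moving, config = demons_config()) {
  stopifnot(inherits(fixed, "scalar_volume"), inherits(moving, "scalar_volume"),
            inherits(config, "demons_config"))
  u <- NULL
  for (lev in seq_len(config$levels)) {
    factor <- 2^(config$levels - lev)
    gl <- coarsen_grid(fixed$grid, factor)
    smooth_mm <- sqrt(config$image_sigma^2 +
                      (0.5 * factor * min(fixed$grid$spacing))^2)
    fl <- resample_volume(smooth_volume(fixed, smooth_mm), gl)
    ml <- resample_volume(smooth_volume(moving, smooth_mm), gl)
    u <- if (is.null(u)) zero_field(gl) else resample_field(u, gl)
    u <- demons_level(fl, ml, u, config$iterations[lev], config)
  }
  u
}

demons_level <- function(fl, ml, u, iters, config) {
  if (iters == 0) return(u)
  grid <- fl$grid
  g1 <- array_gradient(fl$values, 1L, grid$spacing[1])
  g2 <- array_gradient(fl$values, 2L, grid$spacing[2])
  g3 <- array_gradient(fl$values, 3L, grid$spacing[3])
  gf2 <- g1^2 + g2^2 + g3^2
  max_step <- config$max_step_vox * min(grid$spacing)
  n <- n_voxels(grid)
  um <- field_matrix(u)
  pts <- grid_points(grid)
  for (it in seq_len(iters)) {
    # edge-extended sampling: a fill value would fabricate intensity
    # differences at the volume faces and drive spurious boundary updates
    mw <- trilinear_core(ml$values, grid, pts + um, 0, clamp = TRUE)$values
    # classic passive-force demons: push the sample point so the warped
    # moving intensity approaches the fixed intensity
    diff <- as.vector(fl$values) - mw
    denom <- as.vector(gf2) + diff^2
    scale <- ifelse(denom > 1e-9, diff / denom, 0)
    step <- cbind(scale * as.vector(g1), scale * as.vector(g2),
                  scale * as.vector(g3))
    if (config$step_normalization) {
      sn <- sqrt(rowSums(step^2))
      over <- sn > max_step
      if (any(over)) step[over, ] <- step[over, ] * (max_step / sn[over])
    }
    um <- um + step
    uf <- smooth_field(matrix_field(grid, um), config$smoothing_sigma)
    um <- field_matrix(uf)
  }
  matrix_field(grid, um)
}
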