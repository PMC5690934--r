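# Parametric error injection: perturbs a ground-truth field with a known
# error so benchmark metrics have a planted truth. The three modes emulate
# the error patterns seen when comparing registration systems against
# ground-truth phantoms: a systematic offset (bias), spatially correlated
# random error (smooth_noise), and an isolated gross misregistration
# confined to one structure (local_blob — the long-tail histogram event).

#' Error model for test-DVF synthesis
#'
#' @param mode One of `"bias"`, `"smooth_noise"`, `"local_blob"`.
#' @param magnitude Error size in mm: the constant vector length (bias), the
#'   target mean error norm over the rescaling region (smooth_noise), or the
#'   peak displacement of the bump (local_blob). Must be >= 0.
#' @param direction Unit direction (bias and local_blob); normalized
#'   internally.
#' @param correlation_length Gaussian correlation length in mm
#'   (smooth_noise).
#' @param blob_center,blob_radius Center (mm) and support radius (mm) of the
#'   compact bump (local_blob); the bump profile is `(1 - (r/R)^2)^2` inside
#'   `r < R` and exactly zero outside.
#' @param seed Integer seed (smooth_noise).
#' @return An object of class `error_model`.
#' @export
error_model <- function(mode = c("bias", "smooth_noise", "local_blob"),
                        magnitude = 1,
                        direction = c(1, 0, 0),
                        correlation_length = 20,
                        blob_center = NULL, blob_radius = 20,
                        seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(magnitude >= 0, correlation_length > 0)
  if (mode == "local_blob") {
    if (is.null(blob_center)) stop("local_blob mode needs blob_center")
    stopifnot(blob_radius > 0)
  }
  structure(list(mode = mode, magnitude = magnitude,
                 direction = direction / sqrt(sum(direction^2)),
                 correlation_length = correlation_length,
                 blob_center = blob_center, blob_radius = blob_radius,
                 seed = as.integer(seed)),
            class = "error_model")
}

#' Inject a known error into a ground-truth field
#'
#' Returns `gt_field + e`. For `bias`, `e` is a constant vector of length
#' `magnitude`, so the TRE against the ground truth is `magnitude`
#' everywhere. For `smooth_noise`, `e` is an independent Gaussian random
#' field per component with the requested correlation length, rescaled so
#' the mean error norm over `mask` (the whole grid when `NULL`) equals
#' `magnitude`; deterministic given the model seed. For `local_blob`, `e` is
#' a compactly supported bump of peak length `magnitude`, zero outside
#' `blob_radius` — TRE is exactly zero in any ROI the support does not touch.
#'
#' @param gt_field The ground-truth [vector_field()].
#' @param model An [error_model()].
#' @param mask Optional [roi_mask()] over which the smooth-noise magnitude is
#'   normalized.
#' @return A [vector_field()] on the same grid.
#' @export
inject_error <- function(gt_field, model, mask = NULL) {
  stopifnot(inherits(gt_field, "vector_field"), inherits(model, "error_model"))
  grid <- gt_field$grid
  n <- n_voxels(grid)
  e <- switch(model$mode,
    bias = {
      matrix(model$direction * model$magnitude, n, 3, byrow = TRUE)
    },
    smooth_noise = {
      if (model$magnitude == 0) matrix(0, n, 3) else {
        e0 <- with_seed(model$seed, {
          sig_vox <- model$correlation_length / grid$spacing
          vapply(1:3, function(c_) {
            as.vector(gaussian_smooth_array(
              array(stats::rnorm(n), dim = grid$shape), sig_vox))
          }, numeric(n))
        })
        norms <- sqrt(rowSums(e0^2))
        sel <- if (is.null(mask)) rep(TRUE, n) else as.vector(mask$membership)
        e0 * (model$magnitude / mean(norms[sel]))
      }
    },
    local_blob = {
      pts <- grid_points(grid)
      r2 <- rowSums(sweep(pts, 2, model$blob_center)^2) / model$blob_radius^2
      w <- ifelse(r2 < 1, (1 - r2)^2, 0)
      outer(w, model$direction) * model$magnitude
    })
  matrix_field(grid, field_matrix(gt_field) + e)
}
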