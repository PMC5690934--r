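# Virtual phantom assembly: SOT/EOT image pair linked by a known ground-truth
# DVF, six ROI masks, and a single-fraction dose grid with controllable
# gradient placement relative to a chosen organ at risk.

#' Dose plan specification
#'
#' Parameterizes the synthetic single-fraction dose distribution: a uniform
#' prescription inside an ellipsoidal target with a Gaussian-tail penumbra,
#' rigidly placed so the 50% isodose surface sits a requested distance from a
#' named organ at risk. The gradient-margin knob controls how steep the dose
#' falloff is at that organ — the mechanism by which identical registration
#' errors produce very different dosimetric errors.
#'
#' @param target_center Target center (mm), or `NULL` to place the target
#'   automatically from `oar` and `gradient_margin`.
#' @param target_radii Ellipsoid semi-axes (mm triple).
#' @param prescription Prescription dose in Gy for the single fraction
#'   (default 2).
#' @param penumbra_sigma Gaussian penumbra scale (mm).
#' @param gradient_margin Distance (mm) of the 50% isodose from the named
#'   OAR; ignored when `target_center` is given.
#' @param oar Name of the OAR used for gradient placement.
#' @param dose_bath Relative weight of a broad low-dose component emulating
#'   the scatter/entrance dose bath of a rotational IMRT delivery (0
#'   disables).
#' @param bath_sigma Gaussian scale (mm) of the dose bath.
#' @return An object of class `dose_plan_spec`.
#' @export
dose_plan_spec <- function(target_center = NULL,
                           target_radii = c(20, 20, 20),
                           prescription = 2,
                           penumbra_sigma = 5,
                           gradient_margin = 2,
                           oar = "brainstem",
                           dose_bath = 0.15,
                           bath_sigma = 120) {
  stopifnot(prescription > 0, penumbra_sigma > 0, all(target_radii > 0),
            dose_bath >= 0, bath_sigma > 0)
  structure(list(target_center = target_center, target_radii = target_radii,
                 prescription = prescription, penumbra_sigma = penumbra_sigma,
                 gradient_margin = gradient_margin, oar = oar,
                 dose_bath = dose_bath, bath_sigma = bath_sigma),
            class = "dose_plan_spec")
}

# normalized falloff profile: 1 inside the target (d <= 0), a steep Gaussian
# penumbra plus an optional broad bath outside, monotone non-increasing in d
dose_profile <- function(spec, d) {
  dp <- pmax(d, 0)
  (exp(-dp^2 / (2 * spec$penumbra_sigma^2)) +
     spec$dose_bath * exp(-dp^2 / (2 * spec$bath_sigma^2))) /
    (1 + spec$dose_bath)
}

# signed mm distance beyond the ellipsoidal target surface (negative inside)
target_distance_mm <- function(points, center, radii) {
  rel <- sweep(points, 2, center)
  rho <- sqrt(rowSums(sweep(rel, 2, radii, "/")^2))
  (rho - 1) * mean(radii)
}

#' Synthesize a single-fraction dose distribution
#'
#' `dose(x) = prescription * s(d(x))` where `d` is the signed ellipsoidal
#' distance to the target surface and `s` is 1 inside the target and, beyond
#' it, a steep Gaussian penumbra tail plus an optional broad low-dose bath,
#' so dose is monotone non-increasing along any ray leaving the target. When the spec requests a
#' gradient margin, the target center is shifted along the line away from the
#' OAR centroid until the 50% isodose sits `gradient_margin` mm from the
#' nearest OAR voxel. Deterministic.
#'
#' @param spec A [dose_plan_spec()].
#' @param grid The dose [image_grid()] (the EOT grid).
#' @param masks Named list of [roi_mask()]s in the dose frame; required when
#'   the target is placed automatically.
#' @return A [scalar_volume()] in Gy, with the placed center in the
#'   `target_center` attribute.
#' @export
synthesize_dose <- function(spec, grid, masks = NULL) {
  stopifnot(inherits(spec, "dose_plan_spec"))
  pts <- grid_points(grid)
  # distance at which the profile crosses 50% of prescription
  d50 <- stats::uniroot(function(d) dose_profile(spec, d) - 0.5,
                        c(0, 20 * spec$bath_sigma))$root
  center <- spec$target_center
  if (is.null(center)) {
    if (is.null(masks) || is.null(masks[[spec$oar]]))
      stop("automatic target placement needs the '", spec$oar, "' mask")
    oar <- masks[[spec$oar]]
    oar_pts <- grid_points(oar$grid)[as.vector(oar$membership), , drop = FALSE]
    cen_oar <- colMeans(oar_pts)
    dir <- c(0, -1, 0)  # default: anterior of the OAR
    center <- cen_oar + dir * (min(spec$target_radii) + d50 +
                               spec$gradient_margin + 10)
    for (it in 1:6) {
      m <- min(target_distance_mm(oar_pts, center, spec$target_radii)) - d50
      if (abs(m - spec$gradient_margin) < 0.05) break
      step_dir <- center - cen_oar
      step_dir <- step_dir / sqrt(sum(step_dir^2))
      center <- center + step_dir * (spec$gradient_margin - m)
    }
  }
  lo <- grid$origin
  hi <- grid$origin + (grid$shape - 1) * grid$spacing
  if (any(center < lo) || any(center > hi))
    stop("requested dose gradient margin is unachievable inside the grid")
  d <- target_distance_mm(pts, center, spec$target_radii)
  out <- scalar_volume(grid, spec$prescription * dose_profile(spec, d))
  attr(out, "target_center") <- center
  out
}

#' Synthesize the end-of-treatment image
#'
#' Forward-deforms the SOT image through the ground-truth mapping:
#' `EOT(y) = SOT(y + v(y))` with `v` the numerical inverse of the SOT-to-EOT
#' field, then adds independent Gaussian image noise.
#'
#' @param sot The (noise-free) SOT [scalar_volume()].
#' @param gt_field The ground-truth [vector_field()] (SOT to EOT).
#' @param noise_sd Gaussian noise standard deviation (HU).
#' @param seed Integer seed for the noise.
#' @return A [scalar_volume()] on the field's grid, with the inverse field in
#'   the `inverse_field` attribute.
#' @export
synthesize_eot <- function(sot, gt_field, noise_sd = 5, seed = 1L) {
  inv <- invert_field(gt_field)
  eot <- warp_volume(sot, inv)
  if (noise_sd > 0) {
    eot <- with_seed(seed, scalar_volume(
      eot$grid, eot$values + stats::rnorm(n_voxels(eot$grid), sd = noise_sd)))
  }
  attr(eot, "inverse_field") <- inv
  eot
}

#' Phantom configuration
#'
#' Bundles the grid, anatomy, deformation model, dose plan and build options
#' for [generate_phantom()]. The defaults define the study conditions: a 64^3
#' grid of 3 mm voxels, end-of-course deformation magnitudes (about 2 degrees
#' of head rotation, mild neck flexion, 3 degrees of mandible rotation, 25%
#' parotid shrinkage, 4 mm peak surface regression, a 2 mm TPS residual), a
#' 2 Gy fraction with a 5 mm penumbra placed 2 mm from the brainstem, and a
#' per-phantom +/-30% jitter of component magnitudes emulating the
#' patient-to-patient spread of anatomical change.
#'
#' @param grid An [image_grid()].
#' @param anatomy An [anatomy_config()].
#' @param model A [deformation_model()]; `tps_residual = NULL` here defaults
#'   to the `node_shrinkage` preset at 2 mm.
#' @param dose A [dose_plan_spec()].
#' @param model_jitter Relative half-width of the per-phantom uniform jitter
#'   applied to each component magnitude (0 disables).
#' @param anatomy_jitter Randomize the anatomy geometry per phantom (each
#'   phantom emulates a different patient); `FALSE` reuses the configured
#'   geometry exactly.
#' @param eot_noise_sd EOT image noise (HU).
#' @param build_tol Maximum allowed normalized RMS round-trip intensity error
#'   inside the external mask.
#' @return A list of class `phantom_config`.
#' @export
phantom_config <- function(grid = image_grid(c(64, 64, 64), c(3, 3, 3)),
                           anatomy = anatomy_config(),
                           model = deformation_model(
                             tps_residual = tps_preset("node_shrinkage", 2)),
                           dose = dose_plan_spec(),
                           model_jitter = 0.3,
                           anatomy_jitter = TRUE,
                           eot_noise_sd = 5,
                           build_tol = 0.02) {
  structure(list(grid = grid, anatomy = anatomy, model = model, dose = dose,
                 model_jitter = model_jitter, anatomy_jitter = anatomy_jitter,
                 eot_noise_sd = eot_noise_sd, build_tol = build_tol),
            class = "phantom_config")
}

# per-phantom anatomical variability: each phantom is a different "patient",
# with slightly different head size, organ positions and parotid volumes.
# Ranges are kept small enough that every organ stays inside the external
# surface (build_anatomy re-validates).
jitter_anatomy <- function(cfg, seed) {
  with_seed(seed, {
    cfg$head_radii <- cfg$head_radii * stats::runif(3, 0.97, 1.05)
    cfg$neck_radius <- cfg$neck_radius * stats::runif(1, 0.92, 1.08)
    cfg$parotid_offset_x <- cfg$parotid_offset_x + stats::runif(1, -3, 2)
    cfg$parotid_y <- cfg$parotid_y + stats::runif(1, -4, 4)
    cfg$parotid_radii <- cfg$parotid_radii * stats::runif(3, 0.92, 1.08)
    cfg$cord_xy[2] <- cfg$cord_xy[2] + stats::runif(1, -5, 5)
    cfg$brainstem_xy[2] <- cfg$brainstem_xy[2] + stats::runif(1, -3, 3)
    cfg$mandible_arc_radius <- cfg$mandible_arc_radius + stats::runif(1, -2, 2)
    cfg
  })
}

# per-phantom magnitude jitter: each component scaled by an independent
# U(1-j, 1+j) factor; parotid loss scaled through its contraction factor
jitter_model <- function(model, jitter, seed) {
  if (jitter <= 0) return(model)
  f <- with_seed(seed, stats::runif(7, 1 - jitter, 1 + jitter))
  m <- model
  m$head_rotation$angle_deg <- m$head_rotation$angle_deg * f[1]
  m$head_translation <- m$head_translation * f[2]
  m$spine_flexion$rate_deg_per_cm <- m$spine_flexion$rate_deg_per_cm * f[3]
  m$mandible_rotation$angle_deg <- m$mandible_rotation$angle_deg * f[4]
  a <- 1 - (1 - m$parotid_shrinkage$loss)^(1 / 3)
  m$parotid_shrinkage$loss <- 1 - (1 - pmin(f[5] * a, 0.9))^3
  m$weight_loss$peak_mm <- m$weight_loss$peak_mm * f[6]
  if (!is.null(m$tps_residual))
    m$tps_residual$displacements <- m$tps_residual$displacements * f[7]
  m
}

#' Generate a virtual phantom
#'
#' Runs the full synthesis chain: anatomy, jittered deformation model,
#' ground-truth field (with invertibility check), numerical inverse, EOT
#' image, and EOT dose placed relative to the deformed OAR. The phantom is a
#' pure function of `(config, seed)`. Build fidelity — the normalized RMS
#' error of `warp_volume(eot, gt_field)` against the SOT image inside the
#' external mask — is checked against `config$build_tol` and stored.
#'
#' @param config A [phantom_config()].
#' @param seed Integer seed.
#' @return An object of class `dir_phantom` with elements `sot`, `eot`,
#'   `gt_field`, `inverse_field`, `masks`, `eot_dose`, `model`, `config`,
#'   `seed`, `fidelity_nrmse`.
#' @export
generate_phantom <- function(config = phantom_config(), seed = 1L) {
  stopifnot(inherits(config, "phantom_config"))
  grid <- config$grid
  acfg <- if (isTRUE(config$anatomy_jitter))
    jitter_anatomy(config$anatomy, seed + 4L) else config$anatomy
  an <- build_anatomy(grid, acfg, seed)
  model <- jitter_model(config$model, config$model_jitter, seed + 2L)
  gt <- build_ground_truth_mapping(model, an$masks, grid)
  eot <- synthesize_eot(an$clean, gt, config$eot_noise_sd, seed + 3L)
  inv <- attr(eot, "inverse_field")
  attr(eot, "inverse_field") <- NULL
  # dose is planned on the EOT anatomy: place it against the deformed OAR
  oar_name <- config$dose$oar
  masks_eot <- if (!is.null(oar_name) && is.null(config$dose$target_center)) {
    stats::setNames(list(warp_mask(an$masks[[oar_name]], inv)), oar_name)
  } else NULL
  eot_dose <- synthesize_dose(config$dose, grid, masks_eot)
  fidelity <- nrmse(an$image, warp_volume(eot, gt), an$masks$external)
  if (fidelity > config$build_tol)
    stop(sprintf("phantom round-trip fidelity %.3f exceeds build tolerance %.3f",
                 fidelity, config$build_tol))
  structure(list(sot = an$image, eot = eot, gt_field = gt,
                 inverse_field = inv, masks = an$masks, eot_dose = eot_dose,
                 model = model, config = config, seed = as.integer(seed),
                 fidelity_nrmse = fidelity),
            class = "dir_phantom")
}

#' @export
print.dir_phantom <- function(x, ...) {
  mag <- field_magnitude(x$gt_field)$values[x$masks$external$membership]
  cat("dir_phantom (seed ", x$seed, ") on ", format(x$sot$grid), "\n",
      "  ground-truth |u| inside body: mean ", sprintf("%.2f", mean(mag)),
      " mm, max ", sprintf("%.2f", max(mag)), " mm\n",
      "  round-trip NRMSE: ", sprintf("%.4f", x$fidelity_nrmse), "\n",
      sep = "")
  invisible(x)
}

#' Generate a suite of phantoms
#'
#' Reproduces the study design shape: `n` phantoms (the reference library has
#' 10), each with the six standard ROIs, differing in their per-phantom
#' deformation magnitudes through the model jitter.
#'
#' @param n Number of phantoms.
#' @param config A [phantom_config()] shared by all phantoms.
#' @param seed Base seed; phantom `i` uses `seed + 1000 * i`.
#' @return A list of `dir_phantom` objects named `phantom_1 ... phantom_n`.
#' @export
generate_suite <- function(n = 10, config = phantom_config(), seed = 1L) {
  stopifnot(n >= 1)
  out <- lapply(seq_len(n), function(i)
    generate_phantom(config, seed = as.integer(seed + 1000L * i)))
  names(out) <- paste0("phantom_", seq_len(n))
  out
}
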