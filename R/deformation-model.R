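# Ground-truth deformation synthesis. The mapping from start-of-treatment to
# end-of-treatment anatomy is a composition of analytic components — rigid
# head motion, spine flexion, mandible rotation, parotid shrinkage, weight
# loss — plus a thin-plate-spline residual for localized soft-tissue shifts
# (tumor/node shrinkage, hyoid movement, shoulder drift). Every rigid-like
# component is blended to the identity outside its anatomical support with a
# C1 window so the composed field remains a small-deformation diffeomorphism;
# positivity of the Jacobian determinant is verified per component and for
# the composite.

#' Deformation model for phantom synthesis
#'
#' Parameterizes the anatomical-change components of a phantom's ground-truth
#' mapping. All magnitudes zero yields the identity. Defaults emulate a
#' typical end-of-course head-and-neck change: a couple of degrees of head
#' rotation with a small translation, mild neck flexion, a few degrees of
#' mandible rotation, 25% parotid volume loss and several millimetres of
#' inward surface regression from weight loss.
#'
#' @param head_rotation List with `angle_deg`, unit `axis`, rotation
#'   `center` (mm).
#' @param head_translation Translation (mm triple) applied with the head
#'   rotation.
#' @param head_blend_z Two z values (mm): the head component's weight rises
#'   smoothly from 0 below the first to 1 above the second.
#' @param spine_flexion List with `rate_deg_per_cm` (bending angle per cm of
#'   inferior distance from the pivot), `pivot` (mm), `saturation_mm`
#'   (distance at which the angle stops growing).
#' @param mandible_rotation List with `angle_deg`, `axis`, `center` (condyle
#'   axis, mm) and `support_sigma` (mm Gaussian support around the mandible
#'   centroid).
#' @param parotid_shrinkage List with `loss` (named fractional volume loss
#'   per parotid) and `support_radius` (mm Gaussian envelope).
#' @param weight_loss List with `peak_mm` (inward surface displacement) and
#'   `falloff_mm` (depth decay scale).
#' @param tps_residual `NULL`, or a list with `control_points` and
#'   `displacements` matrices (mm) for a [tps_field()] residual.
#' @param boundary_taper_mm Width of the window forcing the composed field to
#'   zero at the grid boundary (keeps the mapping a bijection of the grid
#'   hull and the numerical inverse well defined everywhere).
#' @return An object of class `deformation_model`.
#' @export
deformation_model <- function(
    head_rotation = list(angle_deg = 2, axis = c(1, 0, 0),
                         center = c(94.5, 99, 125)),
    head_translation = c(2, 1, 0),
    head_blend_z = c(100, 130),
    spine_flexion = list(rate_deg_per_cm = 0.2, pivot = c(94.5, 109, 120),
                         saturation_mm = 80),
    mandible_rotation = list(angle_deg = 3, axis = c(1, 0, 0),
                             center = c(94.5, 95, 118), support_sigma = 30),
    parotid_shrinkage = list(loss = c(parotid_l = 0.25, parotid_r = 0.25),
                             support_radius = 25),
    weight_loss = list(peak_mm = 4, falloff_mm = 25),
    tps_residual = NULL,
    boundary_taper_mm = 9) {
  structure(list(head_rotation = head_rotation,
                 head_translation = head_translation,
                 head_blend_z = head_blend_z,
                 spine_flexion = spine_flexion,
                 mandible_rotation = mandible_rotation,
                 parotid_shrinkage = parotid_shrinkage,
                 weight_loss = weight_loss,
                 tps_residual = tps_residual,
                 boundary_taper_mm = boundary_taper_mm),
            class = "deformation_model")
}

#' All-zero deformation model (identity mapping)
#' @return A `deformation_model` whose components all vanish.
#' @export
zero_deformation_model <- function() {
  deformation_model(
    head_rotation = list(angle_deg = 0, axis = c(1, 0, 0),
                         center = c(94.5, 99, 125)),
    head_translation = c(0, 0, 0),
    spine_flexion = list(rate_deg_per_cm = 0, pivot = c(94.5, 109, 120),
                         saturation_mm = 80),
    mandible_rotation = list(angle_deg = 0, axis = c(1, 0, 0),
                             center = c(94.5, 95, 118), support_sigma = 30),
    parotid_shrinkage = list(loss = c(parotid_l = 0, parotid_r = 0),
                             support_radius = 25),
    weight_loss = list(peak_mm = 0, falloff_mm = 25),
    tps_residual = NULL)
}

#' Scale all deformation magnitudes of a model
#'
#' Multiplies every component magnitude (angles, translations, contraction
#' strength, surface displacement, TPS displacements) by `k`. Parotid volume
#' loss is rescaled through its linear contraction factor so displacement
#' magnitude scales linearly with `k`.
#'
#' @param model A [deformation_model()].
#' @param k Non-negative scale factor.
#' @return A scaled `deformation_model`.
#' @export
scale_model <- function(model, k) {
  stopifnot(inherits(model, "deformation_model"), k >= 0)
  m <- model
  m$head_rotation$angle_deg <- m$head_rotation$angle_deg * k
  m$head_translation <- m$head_translation * k
  m$spine_flexion$rate_deg_per_cm <- m$spine_flexion$rate_deg_per_cm * k
  m$mandible_rotation$angle_deg <- m$mandible_rotation$angle_deg * k
  a <- 1 - (1 - m$parotid_shrinkage$loss)^(1 / 3)  # linear contraction factor
  m$parotid_shrinkage$loss <- 1 - (1 - pmin(k * a, 0.9))^3
  m$weight_loss$peak_mm <- m$weight_loss$peak_mm * k
  if (!is.null(m$tps_residual))
    m$tps_residual$displacements <- m$tps_residual$displacements * k
  m
}

# rigid rotation + translation displacement at points (n x 3)
rigid_displacement <- function(pts, angle_deg, axis, center, translation) {
  th <- angle_deg * pi / 180
  ax <- axis / sqrt(sum(axis^2))
  K <- matrix(c(0, ax[3], -ax[2], -ax[3], 0, ax[1], ax[2], -ax[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  rel <- sweep(pts, 2, center)
  sweep(rel %*% t(R) - rel, 2, translation, "+")
}

# C1 body-support window: 1 inside the body, decaying to 0 within about
# sigma_mm outside the skin. Rigid-like components are multiplied by it so
# the DVF vanishes in air away from the patient (where a deformation has no
# meaning) and stays small near the grid boundary.
body_support <- function(masks, grid, sigma_mm = 8) {
  b <- gaussian_smooth_array(
    array(as.numeric(masks$external$membership), dim = grid$shape),
    sigma_mm / grid$spacing)
  smoothstep(2 * as.vector(b))
}

component_head <- function(model, pts, grid, support) {
  hr <- model$head_rotation
  tr <- model$head_translation
  if (abs(hr$angle_deg) < 1e-12 && max(abs(tr)) < 1e-12) return(NULL)
  u <- rigid_displacement(pts, hr$angle_deg, hr$axis, hr$center, tr)
  bz <- model$head_blend_z
  w <- smoothstep((pts[, 3] - bz[1]) / (bz[2] - bz[1])) * support
  matrix_field(grid, u * w)
}

component_spine <- function(model, pts, grid, support) {
  sf <- model$spine_flexion
  if (abs(sf$rate_deg_per_cm) < 1e-12) return(NULL)
  below <- pmax(sf$pivot[3] - pts[, 3], 0)
  th <- -sf$rate_deg_per_cm * pmin(below, sf$saturation_mm) / 10 * pi / 180
  # rotate (y, z) about the left-right axis through the pivot by theta(z)
  dy <- pts[, 2] - sf$pivot[2]
  dz <- pts[, 3] - sf$pivot[3]
  u <- cbind(0,
             cos(th) * dy - sin(th) * dz - dy,
             sin(th) * dy + cos(th) * dz - dz)
  w <- (1 - smoothstep((pts[, 3] - sf$pivot[3]) / 20)) * support  # fades above pivot
  matrix_field(grid, u * w)
}

component_mandible <- function(model, pts, grid, masks, support) {
  mr <- model$mandible_rotation
  if (abs(mr$angle_deg) < 1e-12) return(NULL)
  u <- rigid_displacement(pts, mr$angle_deg, mr$axis, mr$center, c(0, 0, 0))
  cen <- mask_centroid(masks$mandible)
  d2 <- rowSums(sweep(pts, 2, cen)^2)
  w <- exp(-d2 / (2 * mr$support_sigma^2)) * support
  matrix_field(grid, u * w)
}

# contraction strength is calibrated so the mean Jacobian determinant over
# the parotid mask equals 1 - loss, i.e. the forward-warped parotid loses
# the requested volume fraction
component_parotid <- function(model, pts, grid, masks) {
  ps <- model$parotid_shrinkage
  if (all(ps$loss < 1e-12)) return(NULL)
  total <- matrix(0, nrow(pts), 3)
  for (side in names(ps$loss)) {
    loss <- ps$loss[[side]]
    if (loss < 1e-12) next
    mask <- masks[[side]]
    cen <- mask_centroid(mask)
    rel <- sweep(pts, 2, cen)
    env <- exp(-rowSums(rel^2) / (2 * ps$support_radius^2))
    base <- -rel * env  # unit-strength inward radial field
    f_of <- function(a) {
      jd <- jacobian_determinant(matrix_field(grid, a * base))
      mean(jd$values[mask$membership]) - (1 - loss)
    }
    a <- stats::uniroot(f_of, c(0, 0.6), tol = 1e-5)$root
    total <- total + a * base
  }
  matrix_field(grid, total)
}

component_weight_loss <- function(model, pts, grid, masks) {
  wl <- model$weight_loss
  if (abs(wl$peak_mm) < 1e-12) return(NULL)
  b <- gaussian_smooth_array(
    array(as.numeric(masks$external$membership), dim = grid$shape),
    wl$falloff_mm / grid$spacing)
  g <- cbind(as.vector(array_gradient(b, 1L, grid$spacing[1])),
             as.vector(array_gradient(b, 2L, grid$spacing[2])),
             as.vector(array_gradient(b, 3L, grid$spacing[3])))
  # inward direction = grad b (b grows inward); scaling by |grad b| relative
  # to its maximum (instead of normalizing) keeps the field smooth where the
  # gradient vanishes, so the mapping stays comfortably diffeomorphic
  g_max <- max(sqrt(rowSums(g^2)))
  w <- 4 * as.vector(b) * (1 - as.vector(b))  # peaks at the surface, 0 deep
  matrix_field(grid, wl$peak_mm * w * g / g_max)
}

component_tps <- function(model, grid) {
  tr <- model$tps_residual
  if (is.null(tr) || max(abs(tr$displacements)) < 1e-12) return(NULL)
  tps_field(tr$control_points, tr$displacements, grid)
}

boundary_taper <- function(grid, taper_mm) {
  pts <- grid_points(grid)
  w <- rep(1, nrow(pts))
  for (a in 1:3) {
    lo <- grid$origin[a]
    hi <- grid$origin[a] + (grid$shape[a] - 1) * grid$spacing[a]
    w <- w * smoothstep((pts[, a] - lo) / taper_mm) *
      smoothstep((hi - pts[, a]) / taper_mm)
  }
  w
}

#' Build the ground-truth SOT-to-EOT mapping
#'
#' Composes the model's analytic components in a fixed order — rigid head
#' motion, spine flexion, mandible rotation, parotid shrinkage, weight loss,
#' TPS residual (head applied innermost) — tapers the composite to zero at
#' the grid boundary, and verifies that the Jacobian determinant is strictly
#' positive everywhere. The returned field maps SOT world points into EOT
#' space (`phi(x) = x + u(x)`).
#'
#' @param model A [deformation_model()].
#' @param masks Named list of [roi_mask()]s from [build_anatomy()] (uses
#'   `mandible`, `parotid_l`, `parotid_r`, `external`).
#' @param grid The SOT [image_grid()].
#' @return A [vector_field()].
#' @export
build_ground_truth_mapping <- function(model, masks, grid) {
  stopifnot(inherits(model, "deformation_model"))
  pts <- grid_points(grid)
  support <- body_support(masks, grid)
  components <- list(
    head = component_head(model, pts, grid, support),
    spine_flexion = component_spine(model, pts, grid, support),
    mandible = component_mandible(model, pts, grid, masks, support),
    parotid_shrinkage = component_parotid(model, pts, grid, masks),
    weight_loss = component_weight_loss(model, pts, grid, masks),
    tps_residual = component_tps(model, grid))
  components <- Filter(Negate(is.null), components)
  if (length(components) == 0) return(zero_field(grid))
  for (nm in names(components)) {
    jd <- jacobian_determinant(components[[nm]])
    if (min(jd$values) <= 0)
      stop(sprintf("deformation component '%s' is not invertible (min |J| = %.4g)",
                   nm, min(jd$values)))
  }
  total <- components[[1]]
  if (length(components) > 1) {
    for (i in 2:length(components))
      total <- compose_fields(outer = components[[i]], inner = total)
  }
  w <- boundary_taper(grid, model$boundary_taper_mm)
  total <- matrix_field(grid, field_matrix(total) * w)
  jd <- jacobian_determinant(total)
  if (min(jd$values) <= 0)
    stop(sprintf("composed ground-truth field is not invertible (min |J| = %.4g)",
                 min(jd$values)))
  total
}

#' Thin-plate-spline residual presets
#'
#' Control-point presets expressing the localized soft-tissue changes of the
#' deformation catalog that are not dedicated analytic components: tumor or
#' nodal shrinkage (points converging on a neck node), hyoid movement, and
#' shoulder drift. Displacements are a millimetre to a few millimetres;
#' corner anchor points pin the far field.
#'
#' @param preset One of `"node_shrinkage"`, `"hyoid_shift"`,
#'   `"shoulder_drift"`.
#' @param magnitude_mm Peak control-point displacement (mm).
#' @return A list with `control_points` and `displacements` suitable for the
#'   `tps_residual` slot of [deformation_model()].
#' @export
tps_preset <- function(preset = c("node_shrinkage", "hyoid_shift",
                                  "shoulder_drift"),
                       magnitude_mm = 2) {
  preset <- match.arg(preset)
  anchors <- rbind(c(10, 10, 10), c(180, 10, 10), c(10, 180, 10),
                   c(180, 180, 10), c(10, 10, 180), c(180, 10, 180),
                   c(10, 180, 180), c(180, 180, 180), c(95, 95, 95))
  core <- switch(preset,
    node_shrinkage = list(
      cp = rbind(c(120, 85, 90), c(130, 85, 90), c(125, 92, 96),
                 c(125, 80, 84)),
      d = rbind(c(1, 0, 0), c(-1, 0, 0), c(0, -0.7, -0.5), c(0, 0.7, 0.5))),
    hyoid_shift = list(
      cp = rbind(c(94.5, 70, 100), c(94.5, 78, 104)),
      d = rbind(c(0, 0.8, -0.6), c(0, 0.8, -0.6))),
    shoulder_drift = list(
      cp = rbind(c(50, 100, 15), c(140, 100, 15)),
      d = rbind(c(-0.5, 0, -1), c(0.5, 0, -1))))
  list(control_points = rbind(core$cp, anchors),
       displacements = rbind(core$d * magnitude_mm,
                             matrix(0, nrow(anchors), 3)))
}
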