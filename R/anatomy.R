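# Parametric head-and-neck anatomy: piecewise-constant HU shapes (cranium,
# brainstem, vertebral column + cord, mandible arc, parotids, body surface)
# softened by a partial-volume blur, plus low-frequency soft-tissue texture
# and Gaussian image noise. Geometry is analytic so masks are exact and the
# whole build is a pure function of (config, seed).

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default anatomy configuration
#'
#' Geometry (mm, world coordinates) of the synthetic head-and-neck anatomy,
#' sized for the default 64^3 grid of 3 mm voxels (192 mm extent). All
#' centers and radii can be overridden; [build_anatomy()] rejects
#' configurations whose organs do not fit inside the external surface or the
#' grid.
#'
#' @param ... Named overrides of the default entries.
#' @return A named list of anatomy parameters.
#' @export
anatomy_config <- function(...) {
  cfg <- list(
    head_center = c(94.5, 94.5, 136), head_radii = c(75, 82, 52),
    neck_center_xy = c(94.5, 103), neck_radius = 45,
    shell_rho = c(0.80, 0.97), shell_zmin = 124,
    brainstem_xy = c(94.5, 99), brainstem_radius = 7,
    brainstem_z = c(120, 152),
    cord_xy = c(94.5, 109), cord_radius = 5, cord_z = c(0, 117),
    vertebra_radius = 13,
    mandible_center_xy = c(94.5, 78), mandible_arc_radius = 36,
    mandible_tube_radius = 6, mandible_z = 108, mandible_half_angle = 70,
    parotid_offset_x = 52, parotid_y = 99, parotid_z = 116,
    parotid_radii = c(11, 14, 17),
    hu = list(air = -1000, soft = 40, shell = 700, vertebra = 500,
              mandible = 800, brainstem = 20, cord = 55, parotid = 90),
    texture_sd = 25, texture_sigma = 12,   # HU, mm
    blur_sigma_vox = 0.8,                  # partial-volume blur, voxels
    noise_sd = 5                           # HU
  )
  dots <- list(...)
  stopifnot(all(names(dots) %in% names(cfg)))
  utils::modifyList(cfg, dots)
}

#' Build the synthetic head-and-neck anatomy
#'
#' Returns a CT-like start-of-treatment image and the six standard ROI masks
#' (brainstem, cord, mandible, left/right parotid, external). Organ masks are
#' pairwise disjoint and subsets of the external mask by construction. The
#' noise-free image is returned alongside so the end-of-treatment image can
#' be synthesized from it with independent noise.
#'
#' @param grid An [image_grid()].
#' @param config An [anatomy_config()].
#' @param seed Integer seed fixing the texture and noise.
#' @return A list with `image` (noisy [scalar_volume()]), `clean` (noise-free
#'   [scalar_volume()]) and `masks` (named list of [roi_mask()]).
#' @export
build_anatomy <- function(grid, config = anatomy_config(), seed = 1L) {
  stopifnot(inherits(grid, "image_grid"))
  pts <- grid_points(grid)
  x <- pts[, 1]; y <- pts[, 2]; z <- pts[, 3]
  cfg <- config

  hc <- cfg$head_center; hr <- cfg$head_radii
  rho_head <- sqrt(((x - hc[1]) / hr[1])^2 + ((y - hc[2]) / hr[2])^2 +
                   ((z - hc[3]) / hr[3])^2)
  head <- rho_head <= 1
  neck <- sqrt((x - cfg$neck_center_xy[1])^2 +
               (y - cfg$neck_center_xy[2])^2) <= cfg$neck_radius & z <= hc[3]
  external <- head | neck

  shell <- rho_head >= cfg$shell_rho[1] & rho_head <= cfg$shell_rho[2] &
    z >= cfg$shell_zmin
  brainstem <- sqrt((x - cfg$brainstem_xy[1])^2 +
                    (y - cfg$brainstem_xy[2])^2) <= cfg$brainstem_radius &
    z >= cfg$brainstem_z[1] & z <= cfg$brainstem_z[2]
  rp_cord <- sqrt((x - cfg$cord_xy[1])^2 + (y - cfg$cord_xy[2])^2)
  in_cord_z <- z >= cfg$cord_z[1] & z <= cfg$cord_z[2]
  cord <- rp_cord <= cfg$cord_radius & in_cord_z
  vertebra <- rp_cord > cfg$cord_radius + 1 & rp_cord <= cfg$vertebra_radius &
    in_cord_z

  mc <- cfg$mandible_center_xy
  rp_m <- sqrt((x - mc[1])^2 + (y - mc[2])^2)
  ang <- atan2(x - mc[1], -(y - mc[2]))  # 0 at the anterior midline
  mandible <- sqrt((rp_m - cfg$mandible_arc_radius)^2 +
                   (z - cfg$mandible_z)^2) <= cfg$mandible_tube_radius &
    abs(ang) <= cfg$mandible_half_angle * pi / 180

  pr <- cfg$parotid_radii
  parotid_at <- function(cx) {
    sqrt(((x - cx) / pr[1])^2 + ((y - cfg$parotid_y) / pr[2])^2 +
         ((z - cfg$parotid_z) / pr[3])^2) <= 1
  }
  parotid_l <- parotid_at(hc[1] + cfg$parotid_offset_x)
  parotid_r <- parotid_at(hc[1] - cfg$parotid_offset_x)

  organs <- list(brainstem = brainstem, cord = cord, mandible = mandible,
                 parotid_l = parotid_l, parotid_r = parotid_r)
  for (nm in names(organs)) {
    if (!any(organs[[nm]]))
      stop("grid too small to contain organ: ", nm)
    # organ contours are clipped to the body outline, as drawn contours are;
    # losing a substantial fraction means the geometry does not fit
    clipped <- organs[[nm]] & external
    if (sum(clipped) < 0.9 * sum(organs[[nm]]))
      stop("organ extends outside the external surface: ", nm)
    organs[[nm]] <- clipped
  }
  brainstem <- organs$brainstem; cord <- organs$cord
  mandible <- organs$mandible
  parotid_l <- organs$parotid_l; parotid_r <- organs$parotid_r
  for (i in seq_along(organs)) for (j in seq_len(i - 1)) {
    if (any(organs[[i]] & organs[[j]]))
      stop("overlapping organ masks: ", names(organs)[i], " / ", names(organs)[j])
  }

  hu <- cfg$hu
  vals <- rep(hu$air, length(x))
  vals[external] <- hu$soft
  vals[shell & external] <- hu$shell
  vals[vertebra & external] <- hu$vertebra
  vals[mandible] <- hu$mandible
  vals[brainstem] <- hu$brainstem
  vals[cord] <- hu$cord
  vals[parotid_l | parotid_r] <- hu$parotid

  img <- array(vals, dim = grid$shape)
  texture <- with_seed(seed, {
    tx <- array(stats::rnorm(n_voxels(grid)), dim = grid$shape)
    tx <- gaussian_smooth_array(tx, cfg$texture_sigma / grid$spacing)
    tx <- tx / stats::sd(tx) * cfg$texture_sd
    tx
  })
  img[array(external, dim = grid$shape)] <-
    img[array(external, dim = grid$shape)] +
    texture[array(external, dim = grid$shape)]
  img <- gaussian_smooth_array(img, cfg$blur_sigma_vox)
  clean <- scalar_volume(grid, img)
  noisy <- with_seed(seed + 1L, {
    scalar_volume(grid, img + stats::rnorm(n_voxels(grid), sd = cfg$noise_sd))
  })

  masks <- list(
    brainstem = roi_mask(grid, "brainstem", brainstem),
    cord      = roi_mask(grid, "cord", cord),
    mandible  = roi_mask(grid, "mandible", mandible),
    parotid_l = roi_mask(grid, "parotid_l", parotid_l),
    parotid_r = roi_mask(grid, "parotid_r", parotid_r),
    external  = roi_mask(grid, "external", external)
  )
  list(image = noisy, clean = clean, masks = masks)
}
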