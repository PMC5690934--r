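# Dose propagation scoring: pull the EOT dose back onto the SOT anatomy
# through ground-truth and test DVFs, build cumulative DVHs, and quantify
# the dosimetric consequence of registration error (delta mean dose, delta
# max dose, mean DVH difference).

#' Transfer dose from the EOT to the SOT anatomy
#'
#' Pull-back dose mapping: `dose_sot(x) = dose_eot(x + u(x))` for a field in
#' the SOT-to-EOT convention. No energy/mass rescaling is applied. Dose
#' outside the EOT hull is taken as 0; if more than `warn_fraction` of the
#' voxels inside the external mask map out of hull, a warning is attached.
#'
#' @param eot_dose Dose [scalar_volume()] (Gy) on the EOT grid.
#' @param field A [vector_field()] on the SOT grid.
#' @param external Optional external [roi_mask()] used for the out-of-hull
#'   check.
#' @param warn_fraction Out-of-hull warning threshold (default 0.01).
#' @return A [scalar_volume()] on the field's grid.
#' @export
transfer_dose <- function(eot_dose, field, external = NULL,
                          warn_fraction = 0.01) {
  stopifnot(inherits(eot_dose, "scalar_volume"), inherits(field, "vector_field"))
  pts <- grid_points(field$grid) + field_matrix(field)
  res <- trilinear_core(eot_dose$values, eot_dose$grid, pts, 0)
  out <- scalar_volume(field$grid, res$values)
  if (!is.null(external)) {
    frac <- mean(res$outside[as.vector(external$membership)])
    if (frac > warn_fraction)
      warning(sprintf(
        "transfer_dose: %.1f%% of voxels inside the external contour map outside the dose grid",
        100 * frac))
    attr(out, "outside_fraction") <- frac
  }
  out
}

#' Cumulative dose-volume histogram
#'
#' Fraction of ROI voxels receiving at least each dose level, evaluated on a
#' regular dose axis from 0 to just above the ROI maximum. The curve starts
#' at 1.0 at zero dose and is monotone non-increasing.
#'
#' @param dose Dose [scalar_volume()] (Gy).
#' @param mask An [roi_mask()] on the same grid.
#' @param bin_width Dose axis step (Gy, default 0.02).
#' @return An object of class `dvh_curve`: list with `roi`, `dose_grid` (Gy)
#'   and `volume_fraction`.
#' @export
compute_dvh <- function(dose, mask, bin_width = 0.02) {
  stopifnot(inherits(dose, "scalar_volume"), inherits(mask, "roi_mask"),
            bin_width > 0)
  if (!same_grid(dose$grid, mask$grid))
    stop("compute_dvh: dose and mask grids differ")
  v <- dose$values[mask$membership]
  if (length(v) == 0) stop("empty ROI mask")
  edges <- seq(0, max(v, 0) + bin_width, by = bin_width)
  sv <- sort(v)
  # fraction of voxels with dose >= d, via position in the sorted sample
  frac <- 1 - (findInterval(edges, sv, left.open = TRUE) / length(sv))
  structure(list(roi = mask$name, dose_grid = edges, volume_fraction = frac),
            class = "dvh_curve")
}

#' @export
print.dvh_curve <- function(x, ...) {
  cat("dvh_curve '", x$roi, "': ", length(x$dose_grid),
      " dose points up to ", sprintf("%.2f", max(x$dose_grid)), " Gy\n",
      sep = "")
  invisible(x)
}

# dose at volume D(v): largest dose with V(d) >= v, linearly interpolated
# across the bracketing curve points
dose_at_volume <- function(curve, v) {
  d <- curve$dose_grid
  vf <- curve$volume_fraction
  vapply(v, function(vi) {
    i <- max(which(vf >= vi))
    if (i == length(vf)) return(d[i])
    if (vf[i] == vf[i + 1]) return(d[i])
    d[i] + (d[i + 1] - d[i]) * (vf[i] - vi) / (vf[i] - vf[i + 1])
  }, numeric(1))
}

#' Mean DVH difference between two cumulative DVHs
#'
#' Both curves are inverted to dose-at-volume `D(v)` by linear interpolation
#' and compared point by point along the volume axis:
#' `mean over v in {1%, ..., 99%} of |D_test(v) - D_gt(v)|`, in Gy. The
#' signed mean (test minus ground truth) is returned in the `signed`
#' attribute.
#'
#' @param gt,test `dvh_curve`s for the same ROI.
#' @return Mean absolute dose-at-volume difference (Gy).
#' @export
dvh_mean_difference <- function(gt, test) {
  stopifnot(inherits(gt, "dvh_curve"), inherits(test, "dvh_curve"))
  if (!identical(gt$roi, test$roi))
    stop("dvh_mean_difference: curves belong to different ROIs")
  for (cv in list(gt, test)) {
    if (any(diff(cv$volume_fraction) > 1e-12))
      stop("dvh_mean_difference: non-monotone DVH curve")
  }
  v <- seq(0.01, 0.99, by = 0.01)
  dd <- dose_at_volume(test, v) - dose_at_volume(gt, v)
  structure(mean(abs(dd)), signed = mean(dd))
}

#' Dosimetric error statistics for one ROI
#'
#' Compares the test-transferred dose with the ground-truth-transferred dose
#' inside an ROI: absolute difference in mean dose (Gy and % of the
#' ground-truth mean), in maximum dose (Gy), and the mean DVH difference
#' (Gy). Signed versions (test minus ground truth) are kept alongside for
#' direction-of-error analysis.
#'
#' @param dose_gt,dose_test [scalar_volume()]s (Gy) on the same grid.
#' @param mask An [roi_mask()].
#' @param bin_width DVH dose axis step (Gy).
#' @return An object of class `dose_error_stats`: `roi`, `d_mean_pct`,
#'   `d_mean_gy`, `d_max_gy`, `dvh_mean_gy`, plus `signed_d_mean_gy`,
#'   `signed_d_max_gy`, `signed_dvh_mean_gy` and the ROI mean doses. The
#'   percentage is `NA` when the ground-truth mean dose is zero.
#' @export
dose_error_stats <- function(dose_gt, dose_test, mask, bin_width = 0.02) {
  stopifnot(inherits(dose_gt, "scalar_volume"),
            inherits(dose_test, "scalar_volume"),
            inherits(mask, "roi_mask"))
  if (!same_grid(dose_gt$grid, dose_test$grid))
    stop("dose_error_stats: dose grids differ")
  vg <- dose_gt$values[mask$membership]
  vt <- dose_test$values[mask$membership]
  mean_gt <- mean(vg)
  mean_test <- mean(vt)
  s_mean <- mean_test - mean_gt
  s_max <- max(vt) - max(vg)
  dvh <- dvh_mean_difference(compute_dvh(dose_gt, mask, bin_width),
                             compute_dvh(dose_test, mask, bin_width))
  structure(list(roi = mask$name,
                 d_mean_pct = if (mean_gt > 0) 100 * abs(s_mean) / mean_gt
                              else NA_real_,
                 d_mean_gy = abs(s_mean),
                 d_max_gy = abs(s_max),
                 dvh_mean_gy = as.numeric(dvh),
                 signed_d_mean_gy = s_mean,
                 signed_d_max_gy = s_max,
                 signed_dvh_mean_gy = attr(dvh, "signed"),
                 mean_dose_gt = mean_gt,
                 mean_dose_test = mean_test),
            class = "dose_error_stats")
}

#' @export
print.dose_error_stats <- function(x, ...) {
  cat(sprintf(
    "%s: dDmean %.3f Gy (%s%%), dDmax %.3f Gy, dDVHmean %.3f Gy\n",
    x$roi, x$d_mean_gy,
    if (is.na(x$d_mean_pct)) "NA" else sprintf("%.1f", x$d_mean_pct),
    x$d_max_gy, x$dvh_mean_gy))
  invisible(x)
}
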