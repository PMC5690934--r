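# Target registration error analysis: voxel-wise TRE maps, per-ROI
# statistics, the TG-132 goal check, DICE similarity, per-ROI histograms and
# the two-standard-deviation failure rule.

#' Voxel-wise target registration error map
#'
#' `TRE(x) = |u_test(x) - u_gt(x)|`: the Euclidean distance between the
#' positions to which the two fields map each voxel. Both fields must live on
#' the same grid in the same (SOT-to-EOT) convention; resample an imported
#' field with [resample_field()] first if needed.
#'
#' @param gt_field Ground-truth [vector_field()].
#' @param test_field Test [vector_field()].
#' @return A [scalar_volume()] of TRE values in mm.
#' @export
tre_map <- function(gt_field, test_field) {
  stopifnot(inherits(gt_field, "vector_field"),
            inherits(test_field, "vector_field"))
  if (!same_grid(gt_field$grid, test_field$grid))
    stop("tre_map requires both fields on the same grid; resample first")
  d <- field_matrix(test_field) - field_matrix(gt_field)
  scalar_volume(gt_field$grid, sqrt(rowSums(d^2)))
}

#' Per-ROI TRE statistics
#'
#' Mean, population standard deviation, maximum and the fraction of voxels
#' within 2 mm, over the member voxels of the mask. These are the per-organ
#' summary rows of a phantom benchmark table.
#'
#' @param tre A TRE [scalar_volume()] in mm.
#' @param mask An [roi_mask()] on the same grid.
#' @return An object of class `tre_stats`: list with `roi`, `tre_mean`,
#'   `tre_sd`, `tre_max`, `frac_within_2mm`, `n_voxels`.
#' @export
roi_tre_stats <- function(tre, mask) {
  stopifnot(inherits(tre, "scalar_volume"), inherits(mask, "roi_mask"))
  if (!same_grid(tre$grid, mask$grid))
    stop("roi_tre_stats: map and mask grids differ")
  v <- tre$values[mask$membership]
  if (length(v) == 0) stop("empty ROI mask")
  m <- mean(v)
  structure(list(roi = mask$name,
                 tre_mean = m,
                 tre_sd = sqrt(mean((v - m)^2)),
                 tre_max = max(v),
                 frac_within_2mm = mean(v <= 2),
                 n_voxels = length(v)),
            class = "tre_stats")
}

#' @export
print.tre_stats <- function(x, ...) {
  cat(sprintf("%s: TRE %.2f +/- %.2f mm (max %.2f), %.1f%% <= 2 mm, n = %d\n",
              x$roi, x$tre_mean, x$tre_sd, x$tre_max,
              100 * x$frac_within_2mm, x$n_voxels))
  invisible(x)
}

#' TG-132 goal check
#'
#' The AAPM TG-132 goal for DIR validation: at least 95% of ROI voxels with
#' TRE within 2 mm.
#'
#' @param stats A `tre_stats` from [roi_tre_stats()].
#' @return `TRUE` (pass) or `FALSE` (fail).
#' @export
tg132_check <- function(stats) {
  stopifnot(inherits(stats, "tre_stats"))
  stats$frac_within_2mm >= 0.95
}

#' Flag registration failures by the two-SD rule
#'
#' Pools all mean-TRE entries for one ROI across registration sources and
#' phantoms, computes the system-independent average and its (population)
#' standard deviation, and flags every entry whose TREmu reaches or exceeds
#' the average plus two standard deviations. With zero pooled SD nothing is
#' flagged.
#'
#' @param tre_means Numeric vector of TREmu values (one per
#'   source-by-phantom entry), or a data frame with a `tre_mean` column;
#'   at least 3 entries.
#' @return Logical vector of flags (same order as the input), with the pooled
#'   average and threshold in attributes `tre_avg` and `threshold`.
#' @export
flag_failures <- function(tre_means) {
  if (is.data.frame(tre_means)) tre_means <- tre_means$tre_mean
  tre_means <- as.numeric(tre_means)
  if (length(tre_means) < 3) stop("flag_failures needs at least 3 entries")
  avg <- mean(tre_means)
  sd_ <- sqrt(mean((tre_means - avg)^2))
  thr <- avg + 2 * sd_
  flags <- if (sd_ == 0) rep(FALSE, length(tre_means)) else tre_means >= thr
  structure(flags, tre_avg = avg, threshold = thr)
}

#' DICE similarity of two masks
#'
#' `2 |A intersect B| / (|A| + |B|)`.
#'
#' @param maskA,maskB [roi_mask()]s on the same grid.
#' @return DICE coefficient in `[0, 1]`.
#' @export
dice <- function(maskA, maskB) {
  stopifnot(inherits(maskA, "roi_mask"), inherits(maskB, "roi_mask"))
  if (!same_grid(maskA$grid, maskB$grid))
    stop("dice: masks on different grids")
  a <- maskA$membership
  b <- maskB$membership
  2 * sum(a & b) / (sum(a) + sum(b))
}

#' Per-ROI TRE histogram
#'
#' Counts ROI voxels per half-open TRE bin `[k w, (k+1) w)`; the last bin is
#' extended to include the maximum. The counts always sum to the ROI size.
#'
#' @param tre A TRE [scalar_volume()] (mm).
#' @param mask An [roi_mask()] on the same grid.
#' @param bin_width Bin width in mm (default 0.5).
#' @return An object of class `tre_histogram`: list with `roi`, `bin_edges`
#'   (length `nbins + 1`) and `counts`.
#' @export
tre_histogram <- function(tre, mask, bin_width = 0.5) {
  stopifnot(inherits(tre, "scalar_volume"), inherits(mask, "roi_mask"),
            bin_width > 0)
  if (!same_grid(tre$grid, mask$grid))
    stop("tre_histogram: map and mask grids differ")
  v <- tre$values[mask$membership]
  nbins <- max(1L, floor(max(v) / bin_width) + 1L)
  idx <- pmin(floor(v / bin_width), nbins - 1L) + 1L
  counts <- tabulate(idx, nbins)
  structure(list(roi = mask$name,
                 bin_edges = (0:nbins) * bin_width,
                 counts = counts),
            class = "tre_histogram")
}

#' @export
print.tre_histogram <- function(x, ...) {
  cat("tre_histogram '", x$roi, "': ", length(x$counts), " bins of ",
      x$bin_edges[2] - x$bin_edges[1], " mm, ", sum(x$counts), " voxels\n",
      sep = "")
  invisible(x)
}

#' Plot a TRE histogram
#'
#' @param x A `tre_histogram`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly, the bar midpoints.
#' @export
plot.tre_histogram <- function(x, ...) {
  mids <- graphics::barplot(x$counts,
                            names.arg = sprintf("%.1f", utils::head(x$bin_edges, -1)),
                            xlab = "TRE (mm)", ylab = "voxels",
                            main = x$roi, ...)
  invisible(mids)
}
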