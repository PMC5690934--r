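make_mask <- function(grid, sel, name = "roi") {
  m <- array(FALSE, grid$shape)
  m[sel] <- TRUE
  roi_mask(grid, name, m)
}

test_that("dose transfer copies under the zero field and undoes a translation", {
  g <- image_grid(c(10, 10, 10), c(2, 2, 2))
  set.seed(51)
  dose <- scalar_volume(g, runif(1000, 0, 2))
  expect_identical(transfer_dose(dose, zero_field(g))$values, dose$values)
  # translated dose pulled back through the translation field
  t_mm <- c(2, 0, 0)
  shifted_vals <- array(0, c(10, 10, 10))
  shifted_vals[2:10, , ] <- dose$values[1:9, , ]  # dose moved +1 voxel in x
  shifted <- scalar_volume(g, shifted_vals)
  f <- vector_field(g, array(rep(t_mm, each = 1000), c(10, 10, 10, 3)))
  back <- transfer_dose(shifted, f)
  expect_equal(back$values[1:9, , ], dose$values[1:9, , ], tolerance = 1e-12)
})

test_that("ground-truth dose transfer on a phantom matches the per-voxel oracle", {
  ph <- small_phantom()
  got <- transfer_dose(ph$eot_dose, ph$gt_field)
  pts <- grid_points(ph$sot$grid) + dirqa:::field_matrix(ph$gt_field)
  ext <- which(as.vector(ph$masks$external$membership))
  want <- vapply(ext[seq(1, length(ext), by = 7)], function(i) {
    o <- oracle_trilinear(ph$eot_dose, pts[i, ])
    if (is.na(o)) 0 else o
  }, numeric(1))
  expect_equal(as.numeric(got$values)[ext[seq(1, length(ext), by = 7)]], want,
               tolerance = 1e-12)
})

test_that("cumulative DVHs handle uniform and split doses and match the sort oracle", {
  g <- image_grid(c(6, 6, 6))
  mask <- make_mask(g, 1:216)
  uni <- compute_dvh(scalar_volume(g, rep(2, 216)), mask, 0.25)
  expect_equal(uni$volume_fraction[uni$dose_grid <= 2],
               rep(1, sum(uni$dose_grid <= 2)))
  expect_equal(uni$volume_fraction[uni$dose_grid > 2],
               rep(0, sum(uni$dose_grid > 2)))
  split <- compute_dvh(scalar_volume(g, rep(c(1, 2), each = 108)), mask, 0.25)
  expect_equal(split$volume_fraction[which(split$dose_grid == 1.5)], 0.5)
  # random dose vs sorted-fraction oracle
  set.seed(52)
  dose <- scalar_volume(g, runif(216, 0, 2.5))
  curve <- compute_dvh(dose, mask, 0.1)
  v <- dose$values[mask$membership]
  want <- vapply(curve$dose_grid, function(d) mean(v >= d), numeric(1))
  expect_equal(curve$volume_fraction, want, tolerance = 1e-12)
  # monotone non-increasing, starts at 1
  expect_true(all(diff(curve$volume_fraction) <= 0))
  expect_equal(curve$volume_fraction[1], 1)
  # voxel-order invariance
  perm <- sample(216)
  dose_p <- scalar_volume(g, dose$values[perm])
  expect_equal(compute_dvh(dose_p, mask, 0.1)$volume_fraction,
               curve$volume_fraction)
})

test_that("the mean DVH difference matches constant shifts and a piecewise oracle", {
  g <- image_grid(c(6, 6, 6))
  mask <- make_mask(g, 1:216)
  c20 <- compute_dvh(scalar_volume(g, rep(2.0, 216)), mask, 0.05)
  c15 <- compute_dvh(scalar_volume(g, rep(1.5, 216)), mask, 0.05)
  expect_equal(as.numeric(dvh_mean_difference(c20, c20)), 0)
  expect_equal(as.numeric(dvh_mean_difference(c20, c15)), 0.5,
               tolerance = 1e-9)
  expect_equal(attr(dvh_mean_difference(c20, c15), "signed"), -0.5,
               tolerance = 1e-9)
  # two-step DVHs with hand-computed dose-at-volume difference:
  # A: half the ROI at 1 Gy, half at 2 Gy; B: half at 1.2 Gy, half at 1.6 Gy.
  # D_A(v) = 2 for v <= 0.5, 1 for v > 0.5 (up to bin interpolation);
  # D_B(v) = 1.6 / 1.2 likewise, so |D_A - D_B| = 0.4 on v < 0.5 and 0.2
  # beyond: mean over 1..99% = (49*0.4 + 0.3 + 49*0.2) / 99
  a <- compute_dvh(scalar_volume(g, rep(c(1, 2), each = 108)), mask, 0.01)
  b <- compute_dvh(scalar_volume(g, rep(c(1.2, 1.6), each = 108)), mask, 0.01)
  want <- (49 * 0.4 + 0.3 + 49 * 0.2) / 99
  expect_equal(as.numeric(dvh_mean_difference(a, b)), want, tolerance = 0.02)
  expect_error(dvh_mean_difference(a, compute_dvh(
    scalar_volume(g, rep(1, 216)), make_mask(g, 1:216, "other"), 0.01)),
    "different ROIs")
})

test_that("mean ROI dose from the DVH matches the voxel-wise mean within 1%", {
  ph <- small_phantom()
  dose <- transfer_dose(ph$eot_dose, ph$gt_field)
  for (nm in c("brainstem", "parotid_l")) {
    curve <- compute_dvh(dose, ph$masks[[nm]], 0.005)
    v <- seq(0.005, 0.995, by = 0.01)
    dvh_mean <- mean(dirqa:::dose_at_volume(curve, v))
    vox_mean <- mean(dose$values[ph$masks[[nm]]$membership])
    expect_lt(abs(dvh_mean - vox_mean) / vox_mean, 0.01)
  }
})

test_that("dose error statistics are zero for identity and exact for shifts", {
  g <- image_grid(c(6, 6, 6))
  mask <- make_mask(g, 1:216)
  set.seed(53)
  dose <- scalar_volume(g, runif(216, 0.5, 2))
  s0 <- dose_error_stats(dose, dose, mask)
  expect_equal(s0$d_mean_gy, 0)
  expect_equal(s0$d_max_gy, 0)
  expect_equal(s0$dvh_mean_gy, 0)
  expect_equal(s0$d_mean_pct, 0)
  up <- scalar_volume(g, dose$values + 0.2)
  s1 <- dose_error_stats(dose, up, mask, bin_width = 0.01)
  expect_equal(s1$d_mean_gy, 0.2, tolerance = 1e-9)
  expect_equal(s1$d_max_gy, 0.2, tolerance = 1e-9)
  expect_equal(s1$dvh_mean_gy, 0.2, tolerance = 1e-6)
  expect_equal(s1$signed_d_mean_gy, 0.2, tolerance = 1e-9)
  expect_equal(s1$d_mean_pct, 100 * 0.2 / mean(dose$values), tolerance = 1e-9)
  # zero ground-truth mean: percentage reported missing
  zero_dose <- scalar_volume(g, rep(0, 216))
  expect_true(is.na(dose_error_stats(zero_dose, zero_dose, mask)$d_mean_pct))
})

test_that("bias along a linear dose gradient produces the predicted mean-dose error", {
  # linear-dose slab: 0.1 Gy/mm along y, flat elsewhere
  g <- image_grid(c(24, 24, 24), c(2, 2, 2))
  pts <- grid_points(g)
  dose <- scalar_volume(g, 0.1 * pts[, 2])
  mask <- make_mask(g, which(apply(dirqa:::world_to_index(g, pts), 1,
                                   function(t) all(t >= 6 & t <= 17))))
  zero <- zero_field(g)
  bias_field <- function(dir, mag) {
    vector_field(g, array(rep(dir * mag, each = 24^3), c(24, 24, 24, 3)))
  }
  par <- dose_error_stats(transfer_dose(dose, zero),
                          transfer_dose(dose, bias_field(c(0, 1, 0), 3)), mask)
  expect_equal(par$d_mean_gy, 0.3, tolerance = 0.2 * 0.3)
  perp <- dose_error_stats(transfer_dose(dose, zero),
                           transfer_dose(dose, bias_field(c(1, 0, 0), 3)), mask)
  expect_lt(perp$d_mean_gy, 0.05)
  # opposite-direction biases give opposite-signed mean-dose errors
  up <- dose_error_stats(transfer_dose(dose, zero),
                         transfer_dose(dose, bias_field(c(0, 1, 0), 2)), mask)
  down <- dose_error_stats(transfer_dose(dose, zero),
                           transfer_dose(dose, bias_field(c(0, -1, 0), 2)), mask)
  expect_gt(up$signed_d_mean_gy, 0)
  expect_lt(down$signed_d_mean_gy, 0)
  expect_equal(up$signed_d_mean_gy, -down$signed_d_mean_gy, tolerance = 1e-6)
})
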