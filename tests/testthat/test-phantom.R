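# Module tests use a 32^3 / 6 mm version of the default anatomy so each
# phantom builds in a couple of seconds; geometry is identical in mm.

test_that("anatomy construction is deterministic and masks satisfy invariants", {
  g <- image_grid(c(32, 32, 32), c(6, 6, 6))
  a1 <- build_anatomy(g, anatomy_config(), seed = 3)
  a2 <- build_anatomy(g, anatomy_config(), seed = 3)
  expect_identical(a1$image$values, a2$image$values)
  expect_identical(lapply(a1$masks, function(m) m$membership),
                   lapply(a2$masks, function(m) m$membership))
  organs <- setdiff(names(a1$masks), "external")
  ext <- a1$masks$external$membership
  for (nm in organs) {
    expect_gt(mask_size(a1$masks[[nm]]), 0)
    expect_true(all(ext[a1$masks[[nm]]$membership]))
  }
  # pairwise disjoint organs
  for (i in seq_along(organs)) for (j in seq_len(i - 1)) {
    expect_equal(sum(a1$masks[[organs[i]]]$membership &
                     a1$masks[[organs[j]]]$membership), 0)
  }
})

test_that("the all-zero deformation model yields the identity mapping", {
  g <- image_grid(c(16, 16, 16), c(12, 12, 12))
  an <- build_anatomy(g, anatomy_config(), seed = 1)
  f <- build_ground_truth_mapping(zero_deformation_model(), an$masks, g)
  expect_true(all(f$displacements == 0))
})

test_that("a pure head rotation fixes its rotation center", {
  g <- image_grid(c(32, 32, 32), c(6, 6, 6))
  an <- build_anatomy(g, anatomy_config(), seed = 1)
  m <- zero_deformation_model()
  m$head_rotation$angle_deg <- 3
  m$head_rotation$center <- c(96, 96, 138)  # a voxel center, inside the head
  f <- build_ground_truth_mapping(m, an$masks, g)
  u_at_center <- dirqa:::sample_field(f, matrix(m$head_rotation$center, 1))
  expect_lt(sqrt(sum(u_at_center^2)), 1e-9)
  # and the field is nonzero elsewhere in the head
  expect_gt(max(abs(f$displacements)), 0.5)
})

test_that("parotid shrinkage contracts the parotid by the requested fraction", {
  # full 3 mm resolution: the voxel-counting oracle needs the mask boundary
  # displacement (~1.6 mm) resolved
  g <- image_grid(c(64, 64, 64), c(3, 3, 3))
  an <- build_anatomy(g, anatomy_config(), seed = 1)
  m <- zero_deformation_model()
  m$parotid_shrinkage$loss <- c(parotid_l = 0.3, parotid_r = 0)
  f <- build_ground_truth_mapping(m, an$masks, g)
  jd <- jacobian_determinant(f)
  mask <- an$masks$parotid_l$membership
  expect_lt(mean(jd$values[mask]), 1)
  # voxel-counting oracle: warp the mask forward (through the inverse field)
  # and compare volumes
  inv <- invert_field(f)
  warped <- warp_mask(an$masks$parotid_l, inv)
  ratio <- mask_size(warped) / mask_size(an$masks$parotid_l)
  expect_lt(abs(ratio - 0.7), 0.07)
})

test_that("every generated ground-truth field is invertible and displacement scales with the model", {
  g <- image_grid(c(32, 32, 32), c(6, 6, 6))
  an <- build_anatomy(g, anatomy_config(), seed = 2)
  base <- deformation_model(tps_residual = tps_preset("node_shrinkage", 2))
  mags <- vapply(c(0.5, 1, 2), function(k) {
    f <- build_ground_truth_mapping(scale_model(base, k), an$masks, g)
    expect_gt(min(jacobian_determinant(f)$values), 0)
    mean(sqrt(rowSums(dirqa:::field_matrix(f)^2))[an$masks$external$membership])
  }, numeric(1))
  expect_equal(mags[1] / mags[2], 0.5, tolerance = 0.15)
  expect_equal(mags[3] / mags[2], 2, tolerance = 0.15)
  # scaling by zero is the identity
  f0 <- build_ground_truth_mapping(scale_model(base, 0), an$masks, g)
  expect_true(all(f0$displacements == 0))
})

test_that("EOT synthesis is exact for identity and translation mappings", {
  g <- image_grid(c(16, 16, 16), c(6, 6, 6))
  set.seed(4)
  v <- scalar_volume(g, rnorm(16^3))
  eot <- synthesize_eot(v, zero_field(g), noise_sd = 0)
  expect_equal(eot$values, v$values)
  # pure translation: EOT(y) = SOT(y - t) at interior voxels
  t_mm <- c(6, 0, 0)
  f <- vector_field(g, array(rep(t_mm, each = 16^3), c(16, 16, 16, 3)))
  eot2 <- synthesize_eot(v, f, noise_sd = 0)
  expect_equal(eot2$values[2:16, , ], v$values[1:15, , ], tolerance = 1e-9)
})

test_that("phantom generation is deterministic and meets its build fidelity bound", {
  ph <- small_phantom()
  ph2 <- generate_phantom(small_phantom_config(), seed = 7L)
  expect_identical(ph$sot$values, ph2$sot$values)
  expect_identical(ph$gt_field$displacements, ph2$gt_field$displacements)
  expect_identical(ph$eot_dose$values, ph2$eot_dose$values)
  expect_lt(ph$fidelity_nrmse, 0.05)
  expect_gt(min(jacobian_determinant(ph$gt_field)$values), 0)
  # different seed gives a different phantom
  ph3 <- generate_phantom(small_phantom_config(), seed = 8L)
  expect_false(identical(ph$sot$values, ph3$sot$values))
})

test_that("the synthetic dose meets prescription, monotonicity and margin behavior", {
  ph <- small_phantom()
  g <- ph$eot_dose$grid
  ctr <- attr(ph$eot_dose, "target_center")
  expect_equal(as.numeric(trilinear_sample(ph$eot_dose, matrix(ctr, 1))), 2)
  # dose along rays leaving the target is monotone non-increasing
  set.seed(5)
  for (k in 1:10) {
    dir <- rnorm(3); dir <- dir / sqrt(sum(dir^2))
    ts <- seq(0, 80, by = 2)
    p <- t(ctr + outer(dir, ts))
    dose <- as.numeric(trilinear_sample(ph$eot_dose, p, fill = 0))
    inside <- !attr(trilinear_sample(ph$eot_dose, p, fill = 0), "outside")
    expect_true(all(diff(dose[inside]) <= 1e-9))
  }
  # a larger protection margin lowers the OAR's mean dose
  spec_near <- dose_plan_spec(gradient_margin = 2, oar = "cord")
  spec_far <- dose_plan_spec(gradient_margin = 20, oar = "cord")
  d_near <- synthesize_dose(spec_near, g, ph$masks)
  d_far <- synthesize_dose(spec_far, g, ph$masks)
  cord <- ph$masks$cord$membership
  expect_lt(mean(d_far$values[cord]), mean(d_near$values[cord]))
})

test_that("a generated suite has the study design shape", {
  suite <- generate_suite(2, small_phantom_config(), seed = 1)
  expect_length(suite, 2)
  expect_named(suite, c("phantom_1", "phantom_2"))
  for (ph in suite) {
    expect_s3_class(ph, "dir_phantom")
    expect_named(ph$masks, c("brainstem", "cord", "mandible",
                             "parotid_l", "parotid_r", "external"))
  }
  expect_false(identical(suite[[1]]$gt_field$displacements,
                         suite[[2]]$gt_field$displacements))
})
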