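make_mask <- function(grid, sel, name = "roi") {
  m <- array(FALSE, grid$shape)
  m[sel] <- TRUE
  roi_mask(grid, name, m)
}

test_that("TRE maps handle identity, constant offset and match the scalar-loop oracle", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 2))
  f <- smooth_random_field(g, 2, seed = 41)
  expect_true(all(tre_map(f, f)$values == 0))
  off <- vector_field(g, array(rep(c(3, 0, 0), each = 512), c(8, 8, 8, 3)))
  expect_equal(as.numeric(tre_map(zero_field(g), off)$values), rep(3, 512))
  # brute-force oracle on a random pair
  f2 <- smooth_random_field(g, 2, seed = 42)
  got <- tre_map(f, f2)
  want <- vapply(seq_len(512), function(i) {
    d <- dirqa:::field_matrix(f2)[i, ] - dirqa:::field_matrix(f)[i, ]
    sqrt(sum(d^2))
  }, numeric(1))
  expect_equal(as.numeric(got$values), want, tolerance = 1e-12)
  # symmetry in the two arguments
  expect_equal(tre_map(f2, f)$values, got$values)
})

test_that("ROI TRE statistics match counting and a one-pass loop oracle", {
  g <- image_grid(c(6, 6, 6))
  mask <- make_mask(g, 1:216)
  const2 <- scalar_volume(g, rep(2, 216))
  s <- roi_tre_stats(const2, mask)
  expect_equal(s$tre_mean, 2)
  expect_equal(s$tre_sd, 0)
  expect_equal(s$tre_max, 2)
  half <- scalar_volume(g, rep(c(1, 3), each = 108))
  s2 <- roi_tre_stats(half, mask)
  expect_equal(s2$tre_mean, 2)
  expect_equal(s2$tre_max, 3)
  expect_equal(s2$frac_within_2mm, 0.5)
  # random map vs plain-loop oracle (population SD)
  set.seed(43)
  v <- scalar_volume(g, abs(rnorm(216)))
  sub <- make_mask(g, sample(216, 80))
  s3 <- roi_tre_stats(v, sub)
  vals <- v$values[sub$membership]
  acc_n <- 0; acc_s <- 0; acc_s2 <- 0; mx <- -Inf; within <- 0
  for (x in vals) {
    acc_n <- acc_n + 1; acc_s <- acc_s + x; acc_s2 <- acc_s2 + x^2
    if (x > mx) mx <- x
    if (x <= 2) within <- within + 1
  }
  expect_equal(s3$tre_mean, acc_s / acc_n, tolerance = 1e-12)
  expect_equal(s3$tre_sd, sqrt(acc_s2 / acc_n - (acc_s / acc_n)^2),
               tolerance = 1e-9)
  expect_equal(s3$tre_max, mx)
  expect_equal(s3$frac_within_2mm, within / acc_n)
  expect_equal(s3$n_voxels, 80L)
  # statistics respect map bounds
  expect_gte(s3$tre_mean, min(vals))
  expect_lte(s3$tre_mean, max(vals))
})

test_that("the TG-132 goal check applies the 95%-within-2mm threshold", {
  g <- image_grid(c(5, 5, 4))
  mask <- make_mask(g, 1:100)
  expect_true(tg132_check(roi_tre_stats(scalar_volume(g, rep(1, 100)), mask)))
  expect_false(tg132_check(roi_tre_stats(scalar_volume(g, rep(3, 100)), mask)))
  split <- scalar_volume(g, c(rep(1, 96), rep(5, 4)))
  expect_true(tg132_check(roi_tre_stats(split, mask)))
  split2 <- scalar_volume(g, c(rep(1, 94), rep(5, 6)))
  expect_false(tg132_check(roi_tre_stats(split2, mask)))
})

test_that("the two-SD failure rule flags outliers and only outliers", {
  # all equal: zero SD, no flags
  expect_false(any(flag_failures(rep(1.3, 5))))
  # worked boundary example: pooled mean 2.8, population SD 3.6
  fl <- flag_failures(c(1, 1, 1, 1, 10))
  expect_equal(as.logical(fl), c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(attr(fl, "tre_avg"), 2.8)
  # order invariance
  fl2 <- flag_failures(c(10, 1, 1, 1, 1))
  expect_equal(as.logical(fl2), c(TRUE, FALSE, FALSE, FALSE, FALSE))
  # suite-shaped fixture: 50 entries, exactly 3 planted outliers
  set.seed(44)
  tab <- c(runif(47, 0.5, 1.5), 9, 11, 10)
  fl3 <- flag_failures(tab)
  expect_equal(which(as.logical(fl3)), 48:50)
  expect_error(flag_failures(c(1, 2)), "at least 3")
})

test_that("DICE similarity handles identical, disjoint and nested masks", {
  g <- image_grid(c(6, 6, 6))
  a <- make_mask(g, 1:40, "a")
  expect_equal(dice(a, a), 1.0)
  b <- make_mask(g, 41:80, "b")
  expect_equal(dice(a, b), 0.0)
  big <- make_mask(g, 1:40, "big")
  nested <- make_mask(g, 1:20, "nested")
  expect_equal(dice(big, nested), 2 * 20 / (40 + 20))
})

test_that("TRE histograms bin correctly and conserve counts", {
  g <- image_grid(c(6, 6, 6))
  mask <- make_mask(g, 1:216)
  h <- tre_histogram(scalar_volume(g, rep(1.2, 216)), mask, 0.5)
  expect_equal(sum(h$counts), 216)
  expect_equal(sum(h$counts > 0), 1L)
  expect_equal(h$counts[3], 216)  # [1.0, 1.5)
  # bimodal map: the long-tail shape appears as two separated nonzero bins
  bi <- scalar_volume(g, rep(c(1, 15), times = c(200, 16)))
  h2 <- tre_histogram(bi, mask, 0.5)
  expect_equal(sum(h2$counts), 216)
  expect_equal(which(h2$counts > 0), c(3L, 31L))
  expect_equal(h2$counts[c(3, 31)], c(200L, 16L))
  # histogram-derived mean is within half a bin of the exact mean
  set.seed(45)
  v <- scalar_volume(g, 4 * abs(rnorm(216)))
  h3 <- tre_histogram(v, mask, 0.5)
  mids <- utils::head(h3$bin_edges, -1) + 0.25
  expect_lt(abs(sum(mids * h3$counts) / 216 - mean(v$values)), 0.25)
})

test_that("scaling the field difference scales TRE statistics exactly", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 2))
  gt <- smooth_random_field(g, 2, seed = 46)
  err <- smooth_random_field(g, 1, seed = 47)
  mask <- make_mask(g, 1:512)
  for (k in c(0.5, 2)) {
    test_k <- vector_field(g, gt$displacements + k * err$displacements)
    base <- vector_field(g, gt$displacements + err$displacements)
    s_k <- roi_tre_stats(tre_map(gt, test_k), mask)
    s_1 <- roi_tre_stats(tre_map(gt, base), mask)
    expect_equal(s_k$tre_mean, k * s_1$tre_mean, tolerance = 1e-12)
    expect_equal(s_k$tre_max, k * s_1$tre_max, tolerance = 1e-12)
  }
})
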