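test_that("grid construction enforces geometry invariants", {
  g <- image_grid(c(4, 5, 6), c(1, 2, 3), c(-1, 0, 1))
  expect_equal(g$shape, c(4L, 5L, 6L))
  expect_error(image_grid(c(1, 4, 4)), "at least 2")
  expect_error(image_grid(c(4, 4, 4), c(1, -1, 1)), "positive")
  # voxel-center world mapping
  ax <- dirqa:::grid_axes(g)
  expect_equal(ax[[1]], c(-1, 0, 1, 2))
  expect_equal(ax[[3]], c(1, 4, 7, 10, 13, 16))
})

test_that("trilinear sampling reproduces nodes, midpoints and an affine map", {
  g <- image_grid(c(4, 4, 4), c(2, 2, 2))
  v <- scalar_volume(g, seq_len(64))
  # voxel center: the stored value
  expect_equal(as.numeric(trilinear_sample(v, c(2, 4, 6))),
               v$values[2, 3, 4])
  # midpoint between two adjacent centers with values 0 and 2 -> 1
  v2 <- scalar_volume(g, array(0, c(4, 4, 4)))
  v2$values[2, 2, 2] <- 0
  v2$values[3, 2, 2] <- 2
  expect_equal(as.numeric(trilinear_sample(v2, c(3, 2, 2))), 1.0)
  # exact reproduction of an affine scalar field at arbitrary interior points
  pts <- grid_points(g)
  aff <- scalar_volume(g, 2 * pts[, 1] - 3 * pts[, 2] + 0.5 * pts[, 3] + 7)
  set.seed(42)
  q <- random_interior_points(g, 50, margin = 0)
  expect_equal(as.numeric(trilinear_sample(aff, q)),
               2 * q[, 1] - 3 * q[, 2] + 0.5 * q[, 3] + 7, tolerance = 1e-12)
})

test_that("trilinear sampling matches the brute-force 8-neighbor oracle", {
  g <- image_grid(c(8, 8, 8), c(1.5, 2, 2.5), c(-3, 0, 5))
  set.seed(1)
  v <- scalar_volume(g, rnorm(512))
  q <- random_interior_points(g, 100, margin = 0)
  got <- as.numeric(trilinear_sample(v, q))
  want <- vapply(seq_len(nrow(q)), function(i) oracle_trilinear(v, q[i, ]),
                 numeric(1))
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("out-of-hull points are filled and flagged; bad input rejected", {
  g <- image_grid(c(4, 4, 4))
  v <- scalar_volume(g, rep(5, 64))
  s <- trilinear_sample(v, rbind(c(1, 1, 1), c(99, 0, 0)), fill = -7)
  expect_equal(as.numeric(s), c(5, -7))
  expect_equal(attr(s, "outside"), c(FALSE, TRUE))
  expect_error(trilinear_sample(v, c(NaN, 0, 0)), "finite")
})

test_that("warping with a zero field is the identity and an integer shift relabels", {
  g <- image_grid(c(6, 6, 6), c(2, 2, 2))
  set.seed(2)
  v <- scalar_volume(g, rnorm(216))
  expect_identical(warp_volume(v, zero_field(g))$values, v$values)
  # constant field of +1 voxel spacing along axis 1: out(i) = moving(i+1)
  u <- matrix(rep(c(2, 0, 0), each = 216), 216)
  shifted <- warp_volume(v, vector_field(g, array(u, c(6, 6, 6, 3))), fill = 0)
  expect_equal(shifted$values[1:5, , ], v$values[2:6, , ])
})

test_that("warping a smooth random field matches the per-voxel sampling oracle", {
  g <- image_grid(c(16, 16, 16), c(2, 2, 2))
  set.seed(3)
  v <- scalar_volume(g, rnorm(4096))
  f <- smooth_random_field(g, amplitude = 1.5, seed = 4)
  got <- warp_volume(v, f, fill = 0)
  pts <- grid_points(g) + dirqa:::field_matrix(f)
  want <- vapply(seq_len(nrow(pts)), function(i) {
    o <- oracle_trilinear(v, pts[i, ])
    if (is.na(o)) 0 else o
  }, numeric(1))
  expect_equal(as.numeric(got$values), want, tolerance = 1e-12)
})

test_that("field composition has the identity element and matches the chain oracle", {
  g <- image_grid(c(10, 10, 10), c(2, 2, 2))
  f <- smooth_random_field(g, amplitude = 1, seed = 5)
  z <- zero_field(g)
  expect_equal(compose_fields(f, z)$displacements, f$displacements)
  g2 <- smooth_random_field(g, amplitude = 1, seed = 6)
  w <- compose_fields(f, g2)
  # oracle: evaluate the mapping chain directly at every voxel
  pts <- grid_points(g)
  ui <- dirqa:::field_matrix(g2)
  uo <- dirqa:::sample_field(f, pts + ui)
  expect_equal(dirqa:::field_matrix(w), ui + uo, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("analytic rigid rotations compose and invert to identity", {
  g <- image_grid(c(12, 12, 12), c(2, 2, 2))
  pts <- grid_points(g)
  c0 <- c(11, 11, 11)
  rot_field <- function(deg) {
    th <- deg * pi / 180
    rel <- sweep(pts, 2, c0)
    vector_field(g, array(cbind(cos(th) * rel[, 1] - sin(th) * rel[, 2] - rel[, 1],
                                sin(th) * rel[, 1] + cos(th) * rel[, 2] - rel[, 2],
                                0), c(12, 12, 12, 3)))
  }
  w <- compose_fields(rot_field(4), rot_field(-4))
  mag <- sqrt(rowSums(dirqa:::field_matrix(w)^2))
  interior <- apply(dirqa:::world_to_index(g, pts), 1,
                    function(t) all(t >= 2 & t <= 9))
  expect_lt(max(mag[interior]), 1e-6)
  # numerical inverse matches the analytic inverse rotation within tol
  inv <- invert_field(rot_field(4), tol = 0.005)
  d <- dirqa:::field_matrix(inv) - dirqa:::field_matrix(rot_field(-4))
  expect_lt(max(sqrt(rowSums(d^2))[interior]), 0.005)
})

test_that("field inversion handles constants, the zero field and bad input", {
  g <- image_grid(c(8, 8, 8), c(3, 3, 3))
  n <- 512
  const <- vector_field(g, array(rep(c(1.5, -2, 0.5), each = n), c(8, 8, 8, 3)))
  inv <- invert_field(const)
  expect_equal(dirqa:::field_matrix(inv),
               matrix(rep(c(-1.5, 2, -0.5), each = n), n), tolerance = 1e-9)
  z <- invert_field(zero_field(g))
  expect_true(all(z$displacements == 0))
  # folding field (Jacobian <= 0) is rejected
  pts <- grid_points(g)
  fold <- vector_field(g, array(cbind(-2 * (pts[, 1] - 10), 0 * pts[, 1],
                                      0 * pts[, 1]), c(8, 8, 8, 3)))
  expect_error(invert_field(fold), "not invertible")
})

test_that("Jacobian determinant is exact for identity, scaling and rotation", {
  g <- image_grid(c(8, 8, 8), c(2, 2, 2))
  expect_equal(jacobian_determinant(zero_field(g))$values,
               array(1, c(8, 8, 8)))
  pts <- grid_points(g)
  scale <- vector_field(g, array(0.1 * sweep(pts, 2, c(7, 7, 7)),
                                 c(8, 8, 8, 3)))
  jd <- jacobian_determinant(scale)
  expect_equal(jd$values[3:6, 3:6, 3:6], array(1.1^3, c(4, 4, 4)),
               tolerance = 1e-9)
  th <- 10 * pi / 180
  rel <- sweep(pts, 2, c(7, 7, 7))
  rot <- vector_field(g, array(cbind(cos(th) * rel[, 1] - sin(th) * rel[, 2] - rel[, 1],
                                     sin(th) * rel[, 1] + cos(th) * rel[, 2] - rel[, 2],
                                     0), c(8, 8, 8, 3)))
  jr <- jacobian_determinant(rot)
  expect_equal(jr$values[3:6, 3:6, 3:6], array(1, c(4, 4, 4)),
               tolerance = 1e-6)
})

test_that("volume and field resampling agree with direct sampling", {
  g <- image_grid(c(12, 12, 12), c(2, 2, 2))
  set.seed(8)
  v <- scalar_volume(g, rnorm(12^3))
  g2 <- image_grid(c(6, 6, 6), c(4, 4, 4), c(1, 1, 1))
  r <- resample_volume(v, g2, fill = 0)
  expect_equal(as.numeric(r$values),
               as.numeric(trilinear_sample(v, grid_points(g2), fill = 0)))
  f <- smooth_random_field(g, 1, seed = 9)
  rf <- resample_field(f, g2)
  expect_equal(dirqa:::field_matrix(rf),
               dirqa:::sample_field(f, grid_points(g2)), ignore_attr = TRUE)
})
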