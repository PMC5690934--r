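# Independent brute-force oracles and small fixtures. Oracles are written as
# plain per-point loops, deliberately sharing no code with the package
# internals they check.

# explicit 8-neighbor trilinear interpolation at a single world point
oracle_trilinear <- function(volume, p) {
  g <- volume$grid
  t <- (p - g$origin) / g$spacing
  if (any(t < 0) || any(t > g$shape - 1)) return(NA_real_)
  i0 <- pmin(floor(t), g$shape - 2)
  f <- t - i0
  acc <- 0
  for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
    w <- (if (dx == 1) f[1] else 1 - f[1]) *
         (if (dy == 1) f[2] else 1 - f[2]) *
         (if (dz == 1) f[3] else 1 - f[3])
    acc <- acc + w * volume$values[i0[1] + dx + 1, i0[2] + dy + 1, i0[3] + dz + 1]
  }
  acc
}

# textbook product-moment correlation
oracle_pearson <- function(x, y) {
  n <- length(x)
  mx <- sum(x) / n
  my <- sum(y) / n
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# random world points strictly inside the grid hull
random_interior_points <- function(grid, n, margin = 0.5) {
  lo <- grid$origin + margin * grid$spacing
  hi <- grid$origin + (grid$shape - 1 - margin) * grid$spacing
  cbind(runif(n, lo[1], hi[1]), runif(n, lo[2], hi[2]), runif(n, lo[3], hi[3]))
}

# a smooth random displacement field (sum of a few sinusoids), amplitude mm
smooth_random_field <- function(grid, amplitude = 2, seed = 1) {
  set.seed(seed)
  pts <- grid_points(grid)
  ext <- (grid$shape - 1) * grid$spacing
  u <- sapply(1:3, function(c_) {
    a <- runif(3, -1, 1)
    ph <- runif(3, 0, 2 * pi)
    amplitude * (a[1] * sin(2 * pi * pts[, 1] / ext[1] + ph[1]) +
                 a[2] * sin(2 * pi * pts[, 2] / ext[2] + ph[2]) +
                 a[3] * sin(2 * pi * pts[, 3] / ext[3] + ph[3])) / 3
  })
  vector_field(grid, array(u, dim = c(grid$shape, 3)))
}

# coarse phantom configuration for module tests: same 192 mm anatomy on a
# 32^3 grid of 6 mm voxels, so a phantom builds in a couple of seconds.
# The round-trip fidelity tolerance is relaxed accordingly: interpolation
# error at tissue boundaries grows with voxel size (the 2% bound belongs to
# the 3 mm study grid).
small_phantom_config <- function(..., build_tol = 0.05) {
  phantom_config(grid = image_grid(c(32, 32, 32), c(6, 6, 6)),
                 build_tol = build_tol, ...)
}

# cached small phantom shared across test files (built once per test run)
small_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(small_phantom_config(), seed = 7L)
    cache
  }
})

# cached full-resolution phantom (the 64^3 / 3 mm study grid), shared by the
# fidelity and registration acceptance checks
full_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_phantom(phantom_config(), seed = 1L)
    cache
  }
})
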