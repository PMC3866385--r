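test_that("correlation matrix is exact on affine and sign-flipped series", {
  x <- sin(seq(0, 6 * pi, length.out = 50))
  cm <- correlation_matrix(rbind(x, 2 * x + 3))
  expect_equal(cm$values[1, 2], 1)
  cm2 <- correlation_matrix(rbind(x, -x))
  expect_equal(cm2$values[1, 2], -1)
  expect_equal(unname(diag(cm$values)), c(1, 1))
})

test_that("zero-variance series error unless dropped", {
  d <- rbind(rnorm(20), rep(1, 20), rnorm(20))
  expect_error(correlation_matrix(d), "Zero-variance")
  expect_warning(cm <- correlation_matrix(d, drop_zero_variance = TRUE),
                 "dropped")
  expect_equal(cm$n, 2)
})

test_that("off-diagonal entry count matches the voxel-scale mask", {
  expect_identical(offdiagonal_count(15996), 255856020)
  cm <- correlation_matrix(matrix(rnorm(5 * 30), 5))
  expect_equal(cm$n_offdiagonal, 20)
})

test_that("central density: uniform at t = 4, symmetric, normalized", {
  r <- seq(-0.95, 0.95, by = 0.05)
  expect_equal(central_corr_density(r, 4), rep(0.5, length(r)))
  for (t in c(5, 30, 120)) {
    f <- central_corr_density(r, t)
    expect_equal(f, rev(f))
    int <- integrate(function(x) central_corr_density(x, t), -1, 1,
                     rel.tol = 1e-10)$value
    expect_equal(int, 1, tolerance = 1e-8)
  }
  expect_error(central_corr_density(0.1, 3), "undefined")
})

test_that("non-central density reduces to central at rho = 0", {
  r <- c(-0.6, -0.1, 0, 0.1, 0.35)
  expect_equal(noncentral_corr_density(r, 120, 0),
               central_corr_density(r, 120), tolerance = 1e-12)
  # rho exactly zero short-circuits; tiny rho must agree closely too
  expect_equal(noncentral_corr_density(0.1, 120, 1e-12),
               central_corr_density(0.1, 120), tolerance = 1e-8)
})

test_that("non-central density normalizes with the rho^2 base", {
  for (case in list(c(120, 0.3), c(30, 0.6), c(5, 0.3))) {
    int <- integrate(function(x) noncentral_corr_density(x, case[1], case[2]),
                     -1, 1, rel.tol = 1e-9, subdivisions = 400)$value
    expect_equal(int, 1, tolerance = 1e-6)
  }
  # the as-printed base under-normalizes by (1+rho)^((t-1)/2); kept only
  # behind the flag for comparison
  int_printed <- integrate(function(x)
    noncentral_corr_density(x, 30, 0.6, base = "printed"),
    -1, 1, rel.tol = 1e-7)$value
  expect_equal(int_printed, (1 - 0.6)^(29 / 2) / (1 - 0.36)^(29 / 2),
               tolerance = 1e-5)
})

test_that("non-central mode shifts toward rho", {
  grid <- seq(-0.9, 0.9, by = 0.002)
  f <- noncentral_corr_density(grid, 120, 0.5)
  expect_gt(grid[which.max(f)], 0.4)
})

test_that("density matches Monte Carlo sample correlations (KS)", {
  set.seed(42)
  nrep <- 20000
  t <- 60
  rho <- 0.4
  x <- matrix(rnorm(nrep * t), nrep)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(nrep * t), nrep)
  xc <- x - rowMeans(x); yc <- y - rowMeans(y)
  r <- rowSums(xc * yc) / sqrt(rowSums(xc^2) * rowSums(yc^2))
  ks <- max(abs(corr_density_cdf(sort(r), t, rho) -
                  seq_len(nrep) / nrep))
  expect_lt(ks, 0.015)
})

test_that("distribution summary: moments and histogram bookkeeping", {
  v <- matrix(0.5, 4, 4); diag(v) <- 1
  s <- summarize_distribution(matrix_corr(v))
  expect_equal(s$mean, 0.5)
  expect_equal(s$sd, 0)
  expect_equal(sum(s$histogram$count), 6) # unordered pairs
  expect_equal(s$n_offdiagonal, 12)       # ordered count reported alongside

  set.seed(7)
  d <- matrix(rnorm(30 * 120), 30)
  s2 <- summarize_distribution(correlation_matrix(d))
  pairs <- 30 * 29 / 2
  expect_lt(abs(s2$mean), 3 / sqrt(pairs * (120 - 1)) + 3 / sqrt(119))
  r <- cor(t(d))[upper.tri(diag(30))]
  expect_equal(s2$mean, mean(r))
  expect_equal(s2$sd, sqrt(mean((r - mean(r))^2)))
})

test_that("blockwise summary equals the dense-matrix summary", {
  set.seed(8)
  d <- matrix(rnorm(67 * 40), 67)
  dense <- summarize_distribution(correlation_matrix(d), bins = 101)
  stream <- correlation_summary(d, bins = 101, block_size = 13)
  expect_equal(stream$mean, dense$mean, tolerance = 1e-12)
  expect_equal(stream$sd, dense$sd, tolerance = 1e-12)
  expect_equal(stream$skewness, dense$skewness, tolerance = 1e-10)
  expect_identical(stream$histogram$count, dense$histogram$count)
})
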