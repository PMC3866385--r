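test_that("expected_shared_correlation: closed form, bounds, errors", {
  expect_equal(expected_shared_correlation(1, 1, 0), 0)
  expect_equal(expected_shared_correlation(0, 0, 2), 1)
  expect_equal(expected_shared_correlation(1, 1, 1), 0.5)
  expect_equal(expected_shared_correlation(3, 1, 1), 1 / sqrt(8))
  expect_error(expected_shared_correlation(0, 1, 0), "zero total variance")
  expect_error(expected_shared_correlation(-1, 1, 1), "nonnegative")
})

test_that("expected_shared_correlation is monotone on a grid", {
  g <- seq(0.1, 3, by = 0.4)
  for (vy in c(0.5, 1, 2)) {
    vals <- vapply(g, function(x) expected_shared_correlation(vy, vy, x), 1)
    expect_true(all(diff(vals) > 0)) # nondecreasing in var_g
  }
  for (vg in c(0.5, 1, 2)) {
    vals <- vapply(g, function(x) expected_shared_correlation(x, 1, vg), 1)
    expect_true(all(diff(vals) < 0)) # nonincreasing in var_y1
  }
})

test_that("band-limited series have unit variance and in-band power only", {
  set.seed(2)
  x <- gsrnet:::bandlimited_series(8, 120, 2.5, c(0.009, 0.08))
  expect_equal(dim(x), c(8, 120))
  expect_equal(apply(x, 1, sd), rep(1, 8))
  expect_equal(rowMeans(x), rep(0, 8), tolerance = 1e-12)
  freqs <- (0:119) / (120 * 2.5)
  pw <- abs(stats::mvfft(t(x)))^2
  f_sym <- pmin(freqs, 1 / 2.5 - freqs) # folded frequency, band-edge tolerant
  out <- !(f_sym >= 0.009 - 1e-9 & f_sym <= 0.08 + 1e-9)
  expect_lt(sum(pw[out, ]) / sum(pw), 1e-20)
})

test_that("degenerate variance settings give the exact correlations", {
  ph <- plain_phantom(c(4, 4, 3), 2)
  # pure shared signal: every series identical up to scaling -> corr 1
  m <- plain_model(var_module = 0, var_noise = 0, var_global = 1)
  ts <- simulate_timeseries(ph, m)
  cm <- cor(t(ts$data))
  expect_equal(min(cm), 1, tolerance = 1e-10)
  # independent noise only: mean off-diagonal near 0
  m2 <- plain_model(var_module = 0, var_noise = 1, var_global = 0, seed = 31)
  ts2 <- simulate_timeseries(ph, m2)
  r2 <- cor(t(ts2$data))[upper.tri(diag(ph$n_nodes))]
  expect_lt(abs(mean(r2)), 4 / sqrt(length(r2)))
})

test_that("shared-signal phantom reproduces the closed-form mean correlation", {
  # Var(Y)=Var(G)=1: population correlation 0.5 for every pair; check the
  # Monte-Carlo mean over replicate datasets against 3 standard errors
  ph <- plain_phantom(c(5, 5, 2), 1)
  means <- vapply(1:20, function(s) {
    ts <- simulate_timeseries(ph, plain_model(var_module = 0, var_noise = 1,
                                              var_global = 1, seed = 100 + s))
    mean(cor(t(ts$data))[upper.tri(diag(ph$n_nodes))])
  }, numeric(1))
  target <- expected_shared_correlation(1, 1, 1)
  se <- sd(means) / sqrt(length(means))
  expect_lt(abs(mean(means) - target), 3 * se + 0.01)
})

test_that("same/different-module population correlations hold in sample", {
  ph <- plain_phantom(c(6, 6, 2), 2, seed = 3)
  same_target <- (1 + 0.6) / (1 + 0.6 + 1)
  diff_target <- 0.6 / (1 + 0.6 + 1)
  same <- diff <- numeric(15)
  for (s in 1:15) {
    ts <- simulate_timeseries(ph, plain_model(var_module = 1, var_noise = 1,
                                              var_global = 0.6, seed = 200 + s))
    cm <- cor(t(ts$data))
    in1 <- ph$true_module == 1
    same[s] <- mean(cm[in1, in1][upper.tri(diag(sum(in1)))])
    diff[s] <- mean(cm[in1, !in1])
  }
  expect_lt(abs(mean(same) - same_target), 3 * sd(same) / sqrt(15) + 0.01)
  expect_lt(abs(mean(diff) - diff_target), 3 * sd(diff) / sqrt(15) + 0.01)
})

test_that("simulation is bit-identical given the seed and carries motion", {
  ph <- plain_phantom()
  m <- plain_model(seed = 77)
  a <- simulate_timeseries(ph, m)
  b <- simulate_timeseries(ph, m)
  expect_identical(a$data, b$data)
  expect_identical(a$motion, b$motion)
  expect_equal(dim(a$motion), c(6, 120))
  expect_gt(sd(a$motion[1, ]), 0)
  c2 <- simulate_timeseries(ph, plain_model(seed = 78))
  expect_false(identical(a$data, c2$data))
})

test_that("wm-adjacent and midline loadings raise the intended variances", {
  ph <- generate_phantom(c(6, 6, 4), 2, wm_adjacent_fraction = 0.2,
                         midline_fraction = 0.2, seed = 9)
  m <- signal_model(var_module = 1, var_noise = 1, var_global = 1,
                    var_wm = 1, var_vent = 0, vent_gray_amp = 0,
                    wm_adjacent_loading = 8, wm_module_atten = 1,
                    midline_global_amp = 2.5, boundary_mixing = 0,
                    var_local = 0, seed = 5)
  ts <- simulate_timeseries(ph, m)
  v <- apply(ts$data, 1, var)
  wm <- ph$tissue == "gray_wm_adjacent"
  plain <- !wm & ph$midline_dist >= 2
  expect_gt(mean(v[wm]), mean(v[plain]) + 4) # ~8 extra variance units
  near <- !wm & ph$midline_dist <= 1
  expect_gt(mean(v[near]), mean(v[plain]) + 1) # midline global boost
})
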