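sinusoid_dataset <- function(freq, t = 240, tr = 2.5, n = 3) {
  tt <- seq_len(t) * tr
  matrix_dataset(t(replicate(n, sin(2 * pi * freq * tt + runif(1) * 2 * pi))),
                 tr = tr)
}

test_that("band-pass keeps in-band sinusoids and crushes out-of-band ones", {
  set.seed(1)
  for (method in c("butterworth", "fft")) {
    keep <- bandpass(sinusoid_dataset(0.04), 0.009, 0.08, method = method)
    expect_gt(var(keep$data[1, ]) / var(sinusoid_dataset(0.04)$data[1, ]), 0.9)
    stopb <- bandpass(sinusoid_dataset(0.15), 0.009, 0.08, method = method)
    expect_lt(var(stopb$data[1, ]) / var(sinusoid_dataset(0.15)$data[1, ]), 0.1)
  }
})

test_that("band-pass attenuates >= 20 dB at twice the band edge", {
  set.seed(2)
  at <- function(freq) {
    d <- sinusoid_dataset(freq)
    var(bandpass(d, 0.009, 0.08)$data[1, ]) / var(d$data[1, ])
  }
  expect_lt(10 * log10(at(0.16)), -20)
})

test_that("band-pass removes constants and rejects invalid bands", {
  d <- matrix_dataset(matrix(5, 2, 100))
  out <- bandpass(d, 0.009, 0.08)
  expect_equal(max(abs(out$data)), 0, tolerance = 1e-8)
  expect_error(bandpass(d, 0.1, 0.05), "Invalid band")
  expect_error(bandpass(d, 0, 0.3), "Invalid band") # above Nyquist at tr=2.5
  expect_match(out$provenance[length(out$provenance)], "bandpass")
})

test_that("nuisance extraction averages masks as defined", {
  x <- rnorm(50)
  aux <- rbind(x, -x, rnorm(50))
  d <- matrix_dataset(matrix(rnorm(100), 2), aux = aux,
                      aux_label = c("white_matter_sphere", "white_matter_sphere",
                                    "ventricle"))
  nu <- extract_nuisance(d)
  expect_equal(nu$white_matter, colMeans(aux[1:2, ]))
  expect_equal(nu$white_matter, rep(0, 50), tolerance = 1e-12) # x and -x cancel
  expect_equal(nu$ventricle, aux[3, ])                         # 1-voxel mask
  expect_equal(nu$whole_brain, colMeans(rbind(d$data, aux[1:2, ])))
  d2 <- matrix_dataset(matrix(rnorm(40), 2))
  expect_error(extract_nuisance(d2), "Empty auxiliary mask")
})

test_that("whole-brain mean tracks the latent global signal", {
  ph <- plain_phantom(c(6, 6, 3), 2)
  ts <- simulate_timeseries(ph, plain_model(var_module = 0, var_noise = 1,
                                            var_global = 1, seed = 4))
  nu <- extract_nuisance(ts)
  expect_gt(cor(nu$whole_brain, ts$latent$global), 0.95)
})

test_that("correction methods carry the fixed regressor sets", {
  expect_equal(correction_method("NoCorr")$regressors, "motion")
  expect_equal(correction_method("NoWB")$regressors,
               c("motion", "white_matter", "ventricle"))
  expect_equal(correction_method("WBonly")$regressors, c("motion", "whole_brain"))
  expect_equal(correction_method("Full")$regressors,
               c("motion", "white_matter", "ventricle", "whole_brain"))
  expect_error(correction_method("Median"))
})

test_that("residuals are orthogonal to every regressor and the intercept", {
  ph <- plain_phantom(c(5, 5, 2), 2)
  ts <- simulate_timeseries(ph, plain_model(seed = 12))
  nu <- extract_nuisance(ts)
  for (meth in c("NoCorr", "NoWB", "WBonly", "Full")) {
    res <- regress_out(ts, meth, nu)
    expect_lt(max(abs(rowMeans(res$data))), 1e-10)
    regs <- rbind(nu$motion, nu$whole_brain, nu$white_matter, nu$ventricle)
    regs <- sweep(regs, 1, rowMeans(regs))
    ip <- abs(res$data %*% t(regs))
    norms <- outer(sqrt(rowSums(res$data^2)), sqrt(rowSums(regs^2)))
    sel <- switch(meth, NoCorr = 1:6, NoWB = c(1:6, 8, 9),
                  WBonly = c(1:6, 7), Full = 1:9)
    expect_lt(max((ip / norms)[, sel]), 1e-8)
  }
})

test_that("regression is idempotent and exact for a known shared signal", {
  ph <- plain_phantom(c(5, 5, 2), 1)
  ts <- simulate_timeseries(ph, plain_model(var_module = 0, var_noise = 1,
                                            var_global = 1, seed = 6))
  nu <- extract_nuisance(ts)
  once <- regress_out(ts, "Full", nu)
  twice <- regress_out(once, "Full", nu)
  expect_equal(twice$data, once$data, tolerance = 1e-10)
  # with the shared signal removed, residual correlations centre on zero
  r <- cor(t(once$data))[upper.tri(diag(ph$n_nodes))]
  expect_lt(abs(mean(r)), 0.03)
  r_raw <- cor(t(ts$data))[upper.tri(diag(ph$n_nodes))]
  expect_gt(mean(r_raw), 0.4)
})

test_that("NoCorr with zero-amplitude motion only de-means", {
  ph <- plain_phantom(c(4, 4, 2), 1)
  ts <- simulate_timeseries(ph, plain_model(motion_amplitude = 0, seed = 8))
  out <- regress_out(ts, "NoCorr", extract_nuisance(ts))
  expect_equal(out$data, ts$data - rowMeans(ts$data), tolerance = 1e-12)
})

test_that("collinear regressors error with names", {
  d <- matrix_dataset(matrix(rnorm(200), 4),
                      aux = rbind(rnorm(50), rnorm(50)),
                      aux_label = c("white_matter_sphere", "ventricle"),
                      motion = matrix(rnorm(300), 6))
  nu <- extract_nuisance(d)
  nu$white_matter <- 2 * nu$ventricle + 3 # exact collinearity
  expect_error(regress_out(d, "NoWB", nu), "[Rr]ank|collinear")
})

test_that("global-signal bias ordering holds across replicate phantoms", {
  ph <- plain_phantom(c(5, 5, 3), 2, seed = 2)
  means <- sapply(1:10, function(s) {
    ts <- simulate_timeseries(ph, plain_model(var_module = 0.5, var_noise = 1,
                                              var_global = 1, seed = 300 + s))
    nu <- extract_nuisance(ts)
    vapply(c("NoCorr", "NoWB", "Full"), function(meth) {
      mean(cor(t(regress_out(ts, meth, nu)$data))[upper.tri(diag(ph$n_nodes))])
    }, numeric(1))
  })
  expect_true(all(means["NoCorr", ] >= means["NoWB", ] - 0.02))
  expect_true(all(means["NoWB", ] > means["Full", ]))
  expect_lt(max(abs(means["Full", ])), 0.05)
})
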