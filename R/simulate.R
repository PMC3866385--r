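#' Expected correlation between two series sharing a common signal
#'
#' For series `W1 = Y1 + G`, `W2 = Y2 + G` with `Cov(Y1, G) = Cov(Y2, G) =
#' Cov(Y1, Y2) = 0`, the population correlation is
#' `Var(G) / sqrt((Var(Y1) + Var(G)) (Var(Y2) + Var(G)))`, which is strictly
#' positive whenever the shared-signal variance is positive. This is the bias
#' a shared global signal injects into every pairwise correlation.
#'
#' @param var_y1,var_y2 Intrinsic variances of the two series (>= 0).
#' @param var_g Variance of the shared signal (>= 0).
#' @return The population correlation, in `[0, 1]`.
#' @examples
#' expected_shared_correlation(1, 1, 1) # 0.5
#' @export
expected_shared_correlation <- function(var_y1, var_y2, var_g) {
  if (any(c(var_y1, var_y2, var_g) < 0)) {
    stop("Variances must be nonnegative.", call. = FALSE)
  }
  d1 <- var_y1 + var_g
  d2 <- var_y2 + var_g
  if (d1 <= 0 || d2 <= 0) {
    stop("Undefined correlation: a series has zero total variance.", call. = FALSE)
  }
  var_g / sqrt(d1 * d2)
}

#' Band-limited unit-variance Gaussian series
#'
#' Draws white Gaussian noise, keeps only the FFT bins inside the passband, and
#' rescales each series to zero mean and unit sample variance, so that the
#' variance bookkeeping of the signal model holds exactly in-sample.
#'
#' @param n Number of series.
#' @param t Time points.
#' @param tr Sampling interval (s).
#' @param passband `(low, high)` Hz.
#' @return An `n x t` matrix of series with sample mean 0 and variance 1.
#' @keywords internal
bandlimited_series <- function(n, t, tr, passband) {
  freqs <- (0:(t - 1)) / (t * tr)
  nyq <- floor(t / 2)
  half <- freqs[2:(nyq + 1)]
  keep_half <- which(half >= passband[1] & half <= passband[2])
  if (length(keep_half) == 0L) {
    stop("Passband contains no Fourier bins at this t and tr.", call. = FALSE)
  }
  keep <- c(1L + keep_half, t + 1L - keep_half) # symmetric bins, DC excluded
  x <- matrix(stats::rnorm(n * t), nrow = t, ncol = n)
  xf <- stats::mvfft(x)
  mask <- rep(0, t)
  mask[unique(keep)] <- 1
  xf <- xf * mask
  out <- Re(stats::mvfft(xf, inverse = TRUE)) / t
  out <- sweep(out, 2, colMeans(out))
  sdv <- apply(out, 2, stats::sd)
  out <- sweep(out, 2, sdv, "/")
  t(out)
}

# spatially smooth a stack of per-voxel series with a Gaussian kernel over
# the lattice; rows are renormalized to unit variance so `var_local` is exact
smooth_field <- function(raw, coords, sigma) {
  d2 <- as.matrix(stats::dist(coords))^2
  W <- exp(-d2 / (2 * sigma^2))
  W <- W / sqrt(rowSums(W^2)) # unit-variance rows for iid unit-variance input
  out <- W %*% raw
  out <- out - rowMeans(out)
  out / apply(out, 1, stats::sd)
}

smooth_motion <- function(t, amplitude) {
  rw <- apply(matrix(stats::rnorm(6 * t), nrow = 6), 1, cumsum) # t x 6 walks
  sm <- apply(rw, 2, function(v) stats::filter(v, rep(1 / 5, 5), sides = 2))
  sm[is.na(sm)] <- 0
  sm <- scale(sm) # unit-variance columns
  t(sm) * amplitude
}

#' Simulate phantom voxel time series
#'
#' Generates the node-by-time data a resting-state acquisition would yield
#' after alignment: every latent signal (module, global, tissue, noise) is
#' band-limited Gaussian noise in the model passband, composed per node
#' according to its labels. White-matter-adjacent nodes receive extra shared
#' white-matter-signal variance (`var_wm * wm_adjacent_loading`) and an
#' attenuated module loading; midline nodes receive a boosted global-signal
#' amplitude; bridge nodes split their module variance across their two
#' modules. Auxiliary white-matter-sphere and ventricle voxels carry their
#' tissue signal plus noise. Six smooth motion regressors are generated and
#' (by default) not leaked into the data.
#'
#' @param phantom A [generate_phantom()] object.
#' @param model A [signal_model()].
#' @return An object of class `ts_data`: list with `data` (n_nodes x t),
#'   `aux` (auxiliary-voxel series matrix), `aux_label`, `motion` (6 x t),
#'   `tr`, node metadata (`tissue`, `true_module`, `second_module`, `midline`,
#'   `coords`), `latent` (the latent global/wm/vent series, for validation),
#'   and `provenance`.
#' @examples
#' ph <- generate_phantom(c(4, 4, 3), n_modules = 2, wm_adjacent_fraction = 0,
#'                        midline_fraction = 0, bridge_fraction = 0)
#' ts <- simulate_timeseries(ph, signal_model(t = 40, seed = 7))
#' dim(ts$data)
#' @export
simulate_timeseries <- function(phantom, model) {
  stopifnot(inherits(phantom, "phantom"), inherits(model, "signal_model"))
  n <- phantom$n_nodes
  t <- model$t
  n_mod <- phantom$n_modules
  n_aux <- nrow(phantom$aux$white_matter_sphere) + nrow(phantom$aux$ventricle)

  withr_seed(model$seed, {
    M <- bandlimited_series(n_mod, t, model$tr, model$passband)
    LOC <- if (model$var_local > 0) {
      raw <- bandlimited_series(n, t, model$tr, model$passband)
      smooth_field(raw, phantom$coords, model$local_sigma)
    } else NULL
    G <- bandlimited_series(1, t, model$tr, model$passband)[1, ]
    WM <- bandlimited_series(1, t, model$tr, model$passband)[1, ]
    V <- bandlimited_series(1, t, model$tr, model$passband)[1, ]
    E <- bandlimited_series(n, t, model$tr, model$passband)
    E_aux <- bandlimited_series(n_aux, t, model$tr, model$passband)
    motion <- smooth_motion(t, model$motion_amplitude)
    load_jit <- if (model$loading_sd > 0) {
      exp(stats::rnorm(n, -model$loading_sd^2 / 2, model$loading_sd))
    } else rep(1, n)
    leak <- if (model$motion_leak > 0) {
      matrix(stats::rnorm(n * 6), n, 6) * model$motion_leak
    } else NULL
  })

  a_mod <- sqrt(model$var_module)
  a_glo <- sqrt(model$var_global)
  a_vent <- model$vent_gray_amp * sqrt(model$var_vent)
  a_wm_extra <- sqrt(model$var_wm * model$wm_adjacent_loading)

  wm_adj <- phantom$tissue == "gray_wm_adjacent"
  bridge <- !is.na(phantom$second_module)

  # per-node SNR heterogeneity: log-normal module-loading multipliers make
  # each module's thresholded subgraph core-periphery rather than uniform
  mod_amp <- a_mod * load_jit
  mod_amp[wm_adj] <- mod_amp[wm_adj] * model$wm_module_atten
  # global-signal loading peaks along the lattice midplane(s) and decays
  # smoothly: axis-1 band = interhemispheric fissure analogue, optional
  # axis-2 band = transverse sinus analogue; homogeneous when the peak is 1
  prox <- exp(-phantom$midline_dist / model$midline_range)
  if (model$midline_planes >= 2L) {
    dy <- abs(phantom$coords[, 2] - (phantom$dims[2] - 1) / 2)
    prox <- pmax(prox, exp(-dy / model$midline_range))
  }
  glo_amp <- a_glo * (1 + (model$midline_global_amp - 1) * prox)

  # graded mixed membership: boundary nodes mix in the neighbouring module's
  # signal with amplitude decaying with distance from the module border; the
  # primary amplitude is reduced so the module-part variance stays var_module
  eta <- rep(0, n)
  if (model$boundary_mixing > 0 && phantom$n_modules > 1L) {
    eta <- model$boundary_mixing *
      exp(-(phantom$boundary_dist - 1) / model$mixing_range)
    eta[!is.finite(phantom$boundary_dist)] <- 0
  }
  data <- (mod_amp * sqrt(1 - eta^2)) * M[phantom$true_module, , drop = FALSE]
  mixed <- which(eta > 0)
  if (length(mixed)) {
    data[mixed, ] <- data[mixed, , drop = FALSE] +
      (mod_amp[mixed] * eta[mixed]) *
        M[phantom$neighbor_module[mixed], , drop = FALSE]
  }
  # discrete bridge nodes (if any) additionally carry their second module's
  # signal at full amplitude
  if (any(bridge)) {
    data[bridge, ] <- data[bridge, , drop = FALSE] +
      a_mod * M[phantom$second_module[bridge], , drop = FALSE]
  }
  data <- data +
    tcrossprod(glo_amp, G) +
    tcrossprod(rep(a_vent, n), V) +
    sqrt(model$var_noise) * E
  if (!is.null(LOC)) data <- data + sqrt(model$var_local) * LOC
  if (any(wm_adj)) {
    data[wm_adj, ] <- data[wm_adj, , drop = FALSE] +
      tcrossprod(rep(a_wm_extra, sum(wm_adj)), WM)
  }
  if (!is.null(leak)) data <- data + leak %*% motion

  n_wm_vox <- nrow(phantom$aux$white_matter_sphere)
  aux <- sqrt(model$var_noise) * E_aux
  aux[seq_len(n_wm_vox), ] <- aux[seq_len(n_wm_vox), , drop = FALSE] +
    tcrossprod(rep(sqrt(model$var_wm), n_wm_vox), WM)
  vent_rows <- (n_wm_vox + 1):n_aux
  aux[vent_rows, ] <- aux[vent_rows, , drop = FALSE] +
    tcrossprod(rep(sqrt(model$var_vent), length(vent_rows)), V)
  aux_label <- c(rep("white_matter_sphere", n_wm_vox),
                 rep("ventricle", length(vent_rows)))

  structure(list(
    data = data,
    aux = aux,
    aux_label = aux_label,
    motion = motion,
    tr = model$tr,
    t = t,
    tissue = phantom$tissue,
    true_module = phantom$true_module,
    second_module = phantom$second_module,
    midline = phantom$midline,
    coords = phantom$coords,
    latent = list(global = G, white_matter = WM, ventricle = V),
    model = model,
    provenance = "simulate"
  ), class = "ts_data")
}

#' @export
print.ts_data <- function(x, ...) {
  cat("<ts_data> ", nrow(x$data), " nodes x ", ncol(x$data), " time points (tr ",
      x$tr, " s)\n", sep = "")
  cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}
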