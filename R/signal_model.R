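#' Specify the phantom signal model
#'
#' Collects every variance and loading used by [simulate_timeseries()]. Each
#' gray node's series is a sum of band-limited unit-variance latent signals:
#' its module's intrinsic signal, the global signal shared by all voxels, the
#' ventricle (physiological) signal, and — for white-matter-adjacent nodes — the
#' deep white-matter signal, plus independent band-limited node noise. With all
#' optional loadings at zero, two same-module nodes have population correlation
#' `(var_module + var_global) / (var_module + var_global + var_noise)` and two
#' different-module nodes `var_global / (var_module + var_global + var_noise)`.
#'
#' @param t Number of time points (>= 5; the correlation density requires it).
#' @param tr Sampling interval in seconds.
#' @param var_module Variance of each module's shared intrinsic signal.
#' @param var_noise Variance of per-node independent noise.
#' @param var_global Variance of the global signal present in every voxel.
#' @param var_wm,var_vent Variances of the deep white-matter and ventricle
#'   nuisance signals (carried by their auxiliary masks).
#' @param wm_adjacent_loading Multiplier of the white-matter nuisance variance
#'   on `gray_wm_adjacent` nodes: they receive extra variance
#'   `var_wm * wm_adjacent_loading` from the shared white-matter signal.
#' @param wm_module_atten Multiplier (< 1 attenuates) of the module-signal
#'   amplitude on `gray_wm_adjacent` nodes.
#' @param vent_gray_amp Amplitude multiplier of the ventricle signal on all
#'   gray nodes (broadly shared physiological noise). Set 0 to confine the
#'   ventricle signal to its mask.
#' @param midline_global_amp Peak amplitude multiplier of the global signal at
#'   the lattice midplane (the interhemispheric-fissure analogue). Per-node
#'   global amplitude is `1 + (midline_global_amp - 1) * exp(-d / midline_range)`
#'   with `d` the node's distance from the midplane; 1 gives a homogeneous
#'   global signal.
#' @param midline_range Decay length (voxels) of the midline loading profile.
#' @param midline_planes 1 restricts the elevated-loading profile to the
#'   first-axis midplane (interhemispheric fissure analogue); 2 adds a second
#'   band along the second-axis midplane (transverse sinus analogue), so the
#'   high-loading region crosses the module lattice.
#' @param loading_sd Log-normal standard deviation of the per-node module
#'   loading multiplier (voxel-to-voxel SNR heterogeneity). 0 gives every
#'   node the same loading.
#' @param var_local Variance of the spatially smooth local field: Gaussian
#'   noise shared between nearby voxels (the phantom's stand-in for spatial
#'   smoothness of acquired volumes). 0 disables.
#' @param local_sigma Spatial kernel width (voxels) of the local field.
#' @param boundary_mixing Maximum amplitude fraction of the neighbouring
#'   module's signal mixed into a node at a module boundary (graded mixed
#'   membership; 0 disables). Mixing decays with distance from the boundary.
#' @param mixing_range Decay length (voxels) of the boundary mixing gradient.
#' @param motion_amplitude Scale of the six synthetic motion regressors.
#' @param motion_leak Amplitude of per-node leakage of motion regressors into
#'   the node series (0 = motion exists but does not contaminate the data).
#' @param passband Length-2 numeric, `(low, high)` Hz; all latent signals are
#'   band-limited to this band. Must satisfy `0 <= low < high < 1/(2 tr)`.
#' @param seed Integer seed; simulation is deterministic given the model.
#'
#' @return An object of class `signal_model` (a validated list).
#' @examples
#' signal_model(var_module = 0, var_global = 1, var_noise = 1,
#'              var_wm = 0, var_vent = 0)
#' @export
signal_model <- function(t = 120, tr = 2.5,
                         var_module = 1, var_noise = 1, var_global = 1,
                         var_wm = 1, var_vent = 1,
                         wm_adjacent_loading = 8, wm_module_atten = 0.8,
                         vent_gray_amp = 1.2, midline_global_amp = 2.5,
                         midline_range = 1.5, midline_planes = 1L,
                         loading_sd = 0,
                         var_local = 0, local_sigma = 1,
                         boundary_mixing = 0.7, mixing_range = 2,
                         motion_amplitude = 1, motion_leak = 0,
                         passband = c(0.009, 0.08), seed = 1L) {
  m <- list(t = as.integer(t), tr = tr,
            var_module = var_module, var_noise = var_noise,
            var_global = var_global, var_wm = var_wm, var_vent = var_vent,
            wm_adjacent_loading = wm_adjacent_loading,
            wm_module_atten = wm_module_atten,
            vent_gray_amp = vent_gray_amp,
            midline_global_amp = midline_global_amp,
            midline_range = midline_range,
            midline_planes = as.integer(midline_planes),
            loading_sd = loading_sd,
            var_local = var_local, local_sigma = local_sigma,
            boundary_mixing = boundary_mixing, mixing_range = mixing_range,
            motion_amplitude = motion_amplitude, motion_leak = motion_leak,
            passband = as.numeric(passband), seed = as.integer(seed))
  validate_signal_model(m)
}

validate_signal_model <- function(m) {
  vars <- c("var_module", "var_noise", "var_global", "var_wm", "var_vent",
            "wm_adjacent_loading", "motion_amplitude", "var_local", "loading_sd")
  bad <- vars[vapply(vars, function(v) !is.numeric(m[[v]]) || m[[v]] < 0, logical(1))]
  if (length(bad)) {
    stop("Negative or non-numeric variance/loading: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (m$boundary_mixing < 0 || m$boundary_mixing >= 1) {
    stop("`boundary_mixing` must lie in [0, 1).", call. = FALSE)
  }
  if (m$mixing_range <= 0) stop("`mixing_range` must be positive.", call. = FALSE)
  if (m$midline_range <= 0) stop("`midline_range` must be positive.", call. = FALSE)
  if (m$local_sigma <= 0) stop("`local_sigma` must be positive.", call. = FALSE)
  if (!m$midline_planes %in% c(1L, 2L)) {
    stop("`midline_planes` must be 1 or 2.", call. = FALSE)
  }
  if (m$midline_global_amp < 0) stop("`midline_global_amp` must be >= 0.", call. = FALSE)
  if (m$t < 5L) stop("`t` must be >= 5 for a bounded correlation density.", call. = FALSE)
  if (m$tr <= 0) stop("`tr` must be positive.", call. = FALSE)
  pb <- m$passband
  if (length(pb) != 2L || pb[1] < 0 || pb[1] >= pb[2] || pb[2] >= 1 / (2 * m$tr)) {
    stop("`passband` must satisfy 0 <= low < high < 1/(2*tr) = ",
         signif(1 / (2 * m$tr), 4), " Hz.", call. = FALSE)
  }
  structure(m, class = "signal_model")
}

#' @export
print.signal_model <- function(x, ...) {
  cat("<signal_model> t =", x$t, " tr =", x$tr, "s  band =",
      paste(x$passband, collapse = "-"), "Hz\n")
  cat("  variances: module", x$var_module, "noise", x$var_noise,
      "global", x$var_global, "wm", x$var_wm, "vent", x$var_vent, "\n")
  cat("  loadings: wm-adjacent", x$wm_adjacent_loading,
      "(module atten", x$wm_module_atten, ") vent-on-gray", x$vent_gray_amp,
      "midline-global", x$midline_global_amp, "\n")
  invisible(x)
}
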