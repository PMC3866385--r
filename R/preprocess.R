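#' Band-pass filter voxel time series
#'
#' Zero-phase 4th-order Butterworth band-pass (forward-backward
#' `signal::filtfilt`) applied to every node and auxiliary-voxel series; an
#' ideal FFT brick-wall filter is available as an alternative. Filtering always
#' removes the series mean (DC is outside any valid band). Filtering precedes
#' nuisance regression in the pipeline runner.
#'
#' @param dataset A `ts_data` object.
#' @param low,high Band edges in Hz, `0 <= low < high <` Nyquist.
#' @param method `"butterworth"` (default) or `"fft"`.
#' @return The filtered `ts_data`, provenance updated.
#' @export
bandpass <- function(dataset, low = 0.009, high = 0.08,
                     method = c("butterworth", "fft")) {
  stopifnot(inherits(dataset, "ts_data"))
  method <- match.arg(method)
  nyq <- 1 / (2 * dataset$tr)
  if (low < 0 || low >= high || high >= nyq) {
    stop("Invalid band for tr = ", dataset$tr, ": need 0 <= low < high < ",
         signif(nyq, 4), " Hz.", call. = FALSE)
  }
  filt <- make_bandpass_filter(low, high, dataset$tr, ncol(dataset$data), method)
  dataset$data <- t(apply(dataset$data, 1, filt))
  if (!is.null(dataset$aux) && nrow(dataset$aux) > 0) {
    dataset$aux <- t(apply(dataset$aux, 1, filt))
  }
  dataset$provenance <- c(dataset$provenance,
                          sprintf("bandpass(%g-%g Hz, %s)", low, high, method))
  dataset
}

make_bandpass_filter <- function(low, high, tr, t, method) {
  if (method == "butterworth") {
    nyq <- 1 / (2 * tr)
    bf <- signal::butter(2, c(low, high) / nyq, type = "pass")
    function(v) {
      v <- v - mean(v)
      as.numeric(signal::filtfilt(bf, v))
    }
  } else {
    freqs <- (0:(t - 1)) / (t * tr)
    f_sym <- pmin(freqs, 1 / tr - freqs)
    mask <- as.numeric(f_sym >= low & f_sym <= high)
    function(v) {
      v <- v - mean(v)
      Re(stats::fft(stats::fft(v) * mask, inverse = TRUE)) / length(v)
    }
  }
}

#' Extract nuisance mean time courses
#'
#' Computes the three tissue mean series used by the correction methods: the
#' whole-brain (parenchyma) mean over the network nodes plus the deep
#' white-matter sphere voxels — the ventricle mask is excluded from the
#' parenchyma, a reading of the "gray and white matter" mask definition — the
#' deep white-matter sphere mean, and the ventricle mean. Motion regressors are
#' passed through from the dataset.
#'
#' @param dataset A `ts_data` object carrying auxiliary voxel series.
#' @return An object of class `nuisance_set`: list with `motion` (6 x t),
#'   `whole_brain`, `white_matter`, `ventricle` (each length t).
#' @export
extract_nuisance <- function(dataset) {
  stopifnot(inherits(dataset, "ts_data"))
  wm_rows <- which(dataset$aux_label == "white_matter_sphere")
  vent_rows <- which(dataset$aux_label == "ventricle")
  if (length(wm_rows) == 0L || length(vent_rows) == 0L) {
    stop("Empty auxiliary mask: cannot extract nuisance series.", call. = FALSE)
  }
  parenchyma <- rbind(dataset$data, dataset$aux[wm_rows, , drop = FALSE])
  structure(list(
    motion = dataset$motion,
    whole_brain = colMeans(parenchyma),
    white_matter = colMeans(dataset$aux[wm_rows, , drop = FALSE]),
    ventricle = colMeans(dataset$aux[vent_rows, , drop = FALSE])
  ), class = "nuisance_set")
}

#' Global-signal correction methods
#'
#' The four regression schemes compared by the pipeline, each a fixed ordered
#' set of nuisance regressors (an intercept is always added):
#' * `NoCorr` — motion only;
#' * `NoWB` — motion, white matter, ventricle (no whole-brain signal);
#' * `WBonly` — motion and the whole-brain signal;
#' * `Full` — motion, white matter, ventricle, and the whole-brain signal.
#'
#' @param name One of `"NoCorr"`, `"NoWB"`, `"WBonly"`, `"Full"`.
#' @return An object of class `correction_method` with `name` and `regressors`.
#' @export
correction_method <- function(name = c("NoCorr", "NoWB", "WBonly", "Full")) {
  name <- match.arg(name)
  regressors <- switch(name,
    NoCorr = "motion",
    NoWB   = c("motion", "white_matter", "ventricle"),
    WBonly = c("motion", "whole_brain"),
    Full   = c("motion", "white_matter", "ventricle", "whole_brain")
  )
  structure(list(name = name, regressors = regressors),
            class = "correction_method")
}

#' Regress nuisance signals out of every node series
#'
#' Ordinary least squares per node with an intercept; the selected regressors
#' are de-meaned before fitting and the residuals replace the data, so every
#' node series ends orthogonal to every regressor and mean-free. Near-collinear
#' regressor matrices (condition number > 1e8) are an error, not a silent drop.
#'
#' @param dataset A `ts_data` object.
#' @param method A [correction_method()] (or its name).
#' @param nuisance A [extract_nuisance()] result; extracted from `dataset` if
#'   omitted.
#' @param bandpass_regressors If `TRUE`, band-pass the regressors (model
#'   passband) before regression, addressing the filter-then-regress critique;
#'   off by default to match the reference pipeline order.
#' @return The residual `ts_data`, provenance updated with the method name.
#' @export
regress_out <- function(dataset, method, nuisance = NULL,
                        bandpass_regressors = FALSE) {
  stopifnot(inherits(dataset, "ts_data"))
  if (is.character(method)) method <- correction_method(method)
  if (is.null(nuisance)) nuisance <- extract_nuisance(dataset)
  t_len <- ncol(dataset$data)

  cols <- list()
  for (r in method$regressors) {
    if (r == "motion") {
      mm <- t(nuisance$motion)
      colnames(mm) <- paste0("motion", seq_len(ncol(mm)))
      cols <- c(cols, list(mm))
    } else {
      v <- matrix(nuisance[[r]], ncol = 1)
      colnames(v) <- r
      cols <- c(cols, list(v))
    }
  }
  X <- do.call(cbind, cols)
  if (nrow(X) != t_len) stop("Regressor length mismatch.", call. = FALSE)
  if (bandpass_regressors) {
    pb <- dataset$model$passband %||% c(0.009, 0.08)
    filt <- make_bandpass_filter(pb[1], pb[2], dataset$tr, t_len, "butterworth")
    X <- apply(X, 2, filt)
  }
  X <- sweep(X, 2, colMeans(X))
  keep <- apply(X, 2, function(v) stats::sd(v) > 0)
  X <- X[, keep, drop = FALSE]
  Xfull <- cbind(`(Intercept)` = 1, X)
  if (ncol(X) > 0) {
    qrX <- qr(Xfull)
    Xunit <- sweep(X, 2, apply(X, 2, stats::sd), "/") # conditioning is scale-free
    if (qrX$rank < ncol(Xfull)) {
      dropped <- colnames(Xfull)[qrX$pivot[(qrX$rank + 1):ncol(Xfull)]]
      stop("Rank-deficient regressors: ", paste(dropped, collapse = ", "),
           call. = FALSE)
    }
    if (kappa(Xunit, exact = TRUE) > 1e8) {
      stop("Near-collinear regressors (condition number > 1e8): ",
           paste(colnames(X), collapse = ", "), call. = FALSE)
    }
    res <- t(qr.resid(qrX, t(dataset$data)))
    if (!is.null(dataset$aux) && nrow(dataset$aux) > 0) {
      dataset$aux <- t(qr.resid(qrX, t(dataset$aux)))
    }
  } else {
    res <- dataset$data - rowMeans(dataset$data)
  }
  dataset$data <- res
  dataset$provenance <- c(dataset$provenance, paste0("regress_out(", method$name, ")"))
  dataset
}

#' Apply a full correction scheme
#'
#' Convenience wrapper: extract nuisance series, then regress them out under
#' the chosen method.
#'
#' @inheritParams regress_out
#' @return The corrected `ts_data`.
#' @export
apply_correction <- function(dataset, method, bandpass_regressors = FALSE) {
  regress_out(dataset, method, extract_nuisance(dataset),
              bandpass_regressors = bandpass_regressors)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
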