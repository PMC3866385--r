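#' Cross-correlation matrix of a dataset
#'
#' Pearson correlation between every pair of node series: symmetric, unit
#' diagonal, `n (n - 1)` off-diagonal entries. Zero-variance node series are an
#' error by default; `drop_zero_variance = TRUE` drops them with a warning.
#'
#' @param dataset A `ts_data` object (or a bare node-by-time matrix).
#' @param drop_zero_variance Drop constant series instead of erroring.
#' @return Object of class `corr_matrix`: list with `values` (n x n), `n`, `t`,
#'   and `n_offdiagonal` (`n (n - 1)`, the ordered off-diagonal entry count).
#' @export
correlation_matrix <- function(dataset, drop_zero_variance = FALSE) {
  data <- if (inherits(dataset, "ts_data")) dataset$data else as.matrix(dataset)
  v <- apply(data, 1, stats::var)
  if (any(v == 0)) {
    if (!drop_zero_variance) {
      stop("Zero-variance node series at index: ",
           paste(utils::head(which(v == 0), 5), collapse = ", "),
           ". Use drop_zero_variance = TRUE to drop them.", call. = FALSE)
    }
    warning(sum(v == 0), " zero-variance node series dropped.", call. = FALSE)
    data <- data[v > 0, , drop = FALSE]
  }
  vals <- stats::cor(t(data))
  vals <- (vals + t(vals)) / 2
  diag(vals) <- 1
  n <- nrow(vals)
  structure(list(values = vals, n = n, t = ncol(data),
                 n_offdiagonal = offdiagonal_count(n)),
            class = "corr_matrix")
}

#' Ordered off-diagonal entry count of an n-node correlation matrix
#'
#' The number of correlation coefficients in an `n x n` matrix excluding the
#' unit diagonal, counting ordered pairs: `n (n - 1)`. Summaries over unordered
#' pairs use half this count.
#'
#' @param n Node count.
#' @return `n * (n - 1)` as a double (exact for n well beyond 1e5).
#' @examples
#' offdiagonal_count(15996) # 255,856,020
#' @export
offdiagonal_count <- function(n) {
  n <- as.numeric(n)
  n * (n - 1)
}

#' Central density of the sample correlation coefficient
#'
#' Exact marginal density of the Pearson correlation of `t` independent
#' bivariate-normal samples with population correlation zero:
#' `f(r) = Gamma((t-1)/2) / (sqrt(pi) Gamma((t-2)/2)) (1 - r^2)^((t-4)/2)`,
#' computed via log-gamma. At `t = 4` this is the uniform density 1/2.
#'
#' @param r Numeric vector in `(-1, 1)` (values outside return 0).
#' @param t Number of time points; must exceed 3.
#' @return Density values.
#' @examples
#' central_corr_density(0.3, 120)
#' @export
central_corr_density <- function(r, t) {
  if (t <= 3) stop("`t` must exceed 3: the density is undefined in this form.",
                   call. = FALSE)
  out <- numeric(length(r))
  inside <- abs(r) < 1
  lc <- lgamma((t - 1) / 2) - 0.5 * log(pi) - lgamma((t - 2) / 2)
  out[inside] <- exp(lc + ((t - 4) / 2) * log1p(-r[inside]^2))
  if (t == 4) out[inside] <- 0.5
  out
}

#' Non-central density of the sample correlation coefficient
#'
#' Series form of the density of the sample correlation when the population
#' correlation is `rho`:
#' `f(r) = (1 - rho^2)^((t-1)/2) (1 - r^2)^((t-4)/2) /
#'   (sqrt(pi) Gamma((t-1)/2) Gamma((t-2)/2)) *
#'   sum_j Gamma((t-1+j)/2)^2 (2 rho r)^j / j!`.
#' With the `(1 - rho^2)` base (the default) the density integrates to 1 and
#' reduces to [central_corr_density()] at `rho = 0`; the `"printed"` variant
#' replaces the base by `(1 - rho)`, a form that appears in parts of the
#' applied literature but integrates to `(1 + rho)^-((t-1)/2)` and is kept only
#' for comparison. Terms are evaluated with log-gamma and summed by
#' log-sum-exp; the series is truncated when the relative term drops below
#' `tol` (error if not converged by `max_terms`).
#'
#' @param r Numeric vector in `(-1, 1)`.
#' @param t Number of time points (> 4; `t = 4` allowed).
#' @param rho Population correlation in `(-1, 1)`.
#' @param base `"rho2"` (normalized, default) or `"printed"`.
#' @param tol Relative-term truncation tolerance.
#' @param max_terms Series cap; non-convergence at the cap is an error.
#' @return Density values.
#' @examples
#' noncentral_corr_density(0.5, 120, rho = 0.5)
#' @export
noncentral_corr_density <- function(r, t, rho, base = c("rho2", "printed"),
                                    tol = 1e-12, max_terms = 500L) {
  base <- match.arg(base)
  if (t <= 3) stop("`t` must exceed 3.", call. = FALSE)
  if (abs(rho) >= 1) stop("`rho` must lie in (-1, 1).", call. = FALSE)
  if (rho == 0) return(central_corr_density(r, t))

  bterm <- if (base == "rho2") 1 - rho^2 else 1 - rho
  j <- 0:max_terms
  lgam <- 2 * lgamma((t - 1 + j) / 2) - lfactorial(j)

  out <- numeric(length(r))
  inside <- abs(r) < 1
  for (i in which(inside)) {
    x <- 2 * rho * r[i]
    logpre <- ((t - 1) / 2) * log(bterm) + ((t - 4) / 2) * log1p(-r[i]^2) -
      0.5 * log(pi) - lgamma((t - 1) / 2) - lgamma((t - 2) / 2)
    if (x == 0) {
      out[i] <- exp(logpre + 2 * lgamma((t - 1) / 2))
      next
    }
    lterm <- lgam + j * log(abs(x))
    m <- max(lterm)
    last_rel <- exp(lterm[length(lterm)] - m)
    if (last_rel >= tol) {
      stop(sprintf(paste0("Correlation-density series did not converge within %d ",
                          "terms (t = %s, rho = %s, r = %s; last relative term %.2e)."),
                   max_terms, t, rho, r[i], last_rel), call. = FALSE)
    }
    sgn <- if (x < 0) (-1)^j else rep(1, length(j))
    s <- sum(sgn * exp(lterm - m))
    out[i] <- if (s <= 0) 0 else exp(logpre + m + log(s))
  }
  out
}

#' CDF of the sample correlation coefficient by quadrature
#'
#' Integrates [noncentral_corr_density()] (or the central density) on a fine
#' grid over `(-1, 1)` with the trapezoid rule and interpolates, giving the
#' distribution function used for Kolmogorov-Smirnov comparison against
#' simulated sample correlations.
#'
#' @param q Quantiles.
#' @param t Time points.
#' @param rho Population correlation.
#' @param grid_n Grid resolution.
#' @inheritParams noncentral_corr_density
#' @return `P(R <= q)` values.
#' @export
corr_density_cdf <- function(q, t, rho = 0, base = c("rho2", "printed"),
                             grid_n = 8001L) {
  base <- match.arg(base)
  eps <- 1e-9
  grid <- seq(-1 + eps, 1 - eps, length.out = grid_n)
  f <- if (rho == 0) central_corr_density(grid, t) else {
    noncentral_corr_density(grid, t, rho, base = base)
  }
  h <- diff(grid)
  cum <- c(0, cumsum((f[-1] + f[-length(f)]) / 2 * h))
  cum <- cum / cum[length(cum)]
  stats::approx(grid, cum, xout = q, yleft = 0, yright = 1, rule = 2)$y
}

#' Summarize the off-diagonal correlation distribution
#'
#' Mean, standard deviation, skewness and a histogram on `[-1, 1]` of the
#' unordered off-diagonal correlations (each pair counted once; the ordered
#' count `n (n - 1)` is carried alongside). A positive mean signals the bias a
#' shared, uncorrected global signal injects into the matrix.
#'
#' @param matrix A `corr_matrix`.
#' @param bins Number of equal-width histogram bins on `[-1, 1]`.
#' @return Object of class `corr_summary`: tibble-backed list with `mean`,
#'   `sd`, `skewness`, `histogram` (tibble of bin mids and counts),
#'   `n_pairs` (unordered), `n_offdiagonal` (ordered), `convention`.
#' @export
summarize_distribution <- function(matrix, bins = 201L) {
  stopifnot(inherits(matrix, "corr_matrix"))
  if (matrix$n < 2) stop("Need at least 2 nodes.", call. = FALSE)
  r <- matrix$values[upper.tri(matrix$values)]
  new_corr_summary(
    sums = c(length(r), sum(r), sum(r^2), sum(r^3)),
    counts = bin_counts(r, bins),
    bins = bins, n = matrix$n, t = matrix$t
  )
}

bin_counts <- function(r, bins) {
  edges <- seq(-1, 1, length.out = bins + 1L)
  idx <- pmin(pmax(findInterval(r, edges, rightmost.closed = TRUE), 1L), bins)
  tabulate(idx, nbins = bins)
}

new_corr_summary <- function(sums, counts, bins, n, t) {
  m <- sums[2] / sums[1]
  m2 <- sums[3] / sums[1] - m^2
  m3 <- sums[4] / sums[1] - 3 * m * (sums[3] / sums[1]) + 2 * m^3
  edges <- seq(-1, 1, length.out = bins + 1L)
  structure(list(
    mean = m,
    sd = sqrt(max(m2, 0)),
    skewness = if (m2 > 0) m3 / m2^1.5 else NA_real_,
    histogram = tibble::tibble(
      mid = (edges[-1] + edges[-length(edges)]) / 2,
      count = counts
    ),
    n_pairs = sums[1],
    n_offdiagonal = offdiagonal_count(n),
    n = n, t = t,
    convention = "unordered pairs"
  ), class = "corr_summary")
}

#' Streamed correlation summary without the dense matrix
#'
#' Computes the same summary as [summarize_distribution()] directly from the
#' dataset in row blocks, never materializing the full n-by-n matrix, so that
#' distribution summaries stay in memory for voxel-scale masks (tens of
#' thousands of nodes).
#'
#' @param dataset A `ts_data` object or node-by-time matrix.
#' @param bins Histogram bins on `[-1, 1]`.
#' @param block_size Rows per block.
#' @return A `corr_summary`.
#' @export
correlation_summary <- function(dataset, bins = 201L, block_size = 512L) {
  data <- if (inherits(dataset, "ts_data")) dataset$data else as.matrix(dataset)
  n <- nrow(data)
  if (n < 2) stop("Need at least 2 nodes.", call. = FALSE)
  v <- apply(data, 1, stats::var)
  if (any(v == 0)) stop("Zero-variance node series present.", call. = FALSE)
  x <- data - rowMeans(data)
  x <- x / sqrt(rowSums(x^2))
  sums <- c(0, 0, 0, 0)
  counts <- integer(bins)
  starts <- seq(1L, n, by = block_size)
  for (bi in starts) {
    ei <- min(bi + block_size - 1L, n)
    ri <- bi:ei
    for (bj in starts[starts >= bi]) {
      ej <- min(bj + block_size - 1L, n)
      rj <- bj:ej
      blk <- x[ri, , drop = FALSE] %*% t(x[rj, , drop = FALSE])
      vals <- if (bi == bj) blk[upper.tri(blk)] else as.numeric(blk)
      sums <- sums + c(length(vals), sum(vals), sum(vals^2), sum(vals^3))
      counts <- counts + bin_counts(vals, bins)
    }
  }
  new_corr_summary(sums, counts, bins, n, ncol(data))
}

#' @export
print.corr_summary <- function(x, ...) {
  cat(sprintf("<corr_summary> n = %d (%s: %s pairs)\n  mean %.5f  sd %.4f  skewness %.3f\n",
              x$n, x$convention, format(x$n_pairs, big.mark = ","),
              x$mean, x$sd, x$skewness))
  invisible(x)
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat("<corr_matrix> ", x$n, " nodes (", format(x$n_offdiagonal, big.mark = ","),
      " off-diagonal entries), t = ", x$t, "\n", sep = "")
  invisible(x)
}
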