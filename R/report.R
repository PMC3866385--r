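#' Paired two-sample t test
#'
#' Classical paired t on the per-subject differences, two-sided p value.
#' Zero-variance differences are reported as a degenerate error rather than a
#' p value.
#'
#' @param values_a,values_b Equal-length numeric vectors (>= 2 subjects),
#'   matched by subject.
#' @return List with `t`, `df`, `p`, `mean_diff`.
#' @examples
#' paired_t(c(1, 2, 3), c(3, 2, 1)) # t = 0, p = 1
#' @export
paired_t <- function(values_a, values_b) {
  if (length(values_a) != length(values_b) || length(values_a) < 2) {
    stop("Need two equal-length samples of at least 2 values.", call. = FALSE)
  }
  d <- values_a - values_b
  sd_d <- stats::sd(d)
  if (sd_d == 0) {
    stop("Degenerate comparison: differences have zero variance.", call. = FALSE)
  }
  n <- length(d)
  tstat <- mean(d) / (sd_d / sqrt(n))
  list(t = tstat, df = n - 1,
       p = 2 * stats::pt(-abs(tstat), df = n - 1),
       mean_diff = mean(d))
}

#' Variance-ratio F test
#'
#' Compares the variances of two samples with `F` = larger sample variance /
#' smaller sample variance (the convention is recorded in the result) and a
#' two-sided p value from the F distribution.
#'
#' @param values_a,values_b Numeric samples (>= 2 values each).
#' @return List with `F`, `df1`, `df2`, `p`, `larger` (`"a"` or `"b"`).
#' @export
variance_F <- function(values_a, values_b) {
  if (length(values_a) < 2 || length(values_b) < 2) {
    stop("Each sample needs at least 2 values.", call. = FALSE)
  }
  va <- stats::var(values_a)
  vb <- stats::var(values_b)
  if (min(va, vb) == 0) {
    stop("Zero variance in the denominator sample.", call. = FALSE)
  }
  if (va >= vb) {
    Fstat <- va / vb; df1 <- length(values_a) - 1; df2 <- length(values_b) - 1
    larger <- "a"
  } else {
    Fstat <- vb / va; df1 <- length(values_b) - 1; df2 <- length(values_a) - 1
    larger <- "b"
  }
  p <- min(1, 2 * stats::pf(Fstat, df1, df2, lower.tail = FALSE))
  list(F = Fstat, df1 = df1, df2 = df2, p = p, larger = larger)
}

#' Study configuration
#'
#' Bundles every knob of the simulated comparison study: phantom geometry,
#' signal model, subject seeds, threshold target and analysis options. Model
#' parameters default to [signal_model()]'s defaults; subject seeds are
#' derived from `seed` (one replicate "subject" per seed, sharing geometry but
#' not signals).
#'
#' @param seed Base integer seed.
#' @param n_subjects Number of replicate subjects.
#' @param dims,n_modules,wm_adjacent_fraction,midline_fraction,bridge_fraction
#'   Phantom geometry, see [generate_phantom()].
#' @param model Named list of [signal_model()] arguments (without `seed`).
#' @param S_target Threshold target for `S = log(N)/log(K)`.
#' @param methods Correction methods to run.
#' @param hub_top_fraction Hub-set fraction of nodes.
#' @param bins Correlation-histogram bins.
#' @param filter Band-pass the simulated series before regression (the
#'   pipeline's filter-then-regress order).
#' @param c_denominator Clustering-coefficient denominator, see
#'   [clustering_coefficient()].
#' @param adjust_p Add Benjamini-Hochberg adjusted p columns (raw p values are
#'   always reported; no correction is applied by default).
#' @return A list of class `study_config`.
#' @export
study_config <- function(seed = 1L, n_subjects = 10L,
                         dims = c(10L, 10L, 6L), n_modules = 6L,
                         wm_adjacent_fraction = 0.08, midline_fraction = 0.1,
                         bridge_fraction = 0,
                         model = list(),
                         S_target = 3,
                         methods = c("NoCorr", "NoWB", "WBonly", "Full"),
                         hub_top_fraction = 0.2, bins = 201L,
                         filter = TRUE,
                         c_denominator = c("deg2", "all"),
                         adjust_p = FALSE) {
  structure(list(
    seed = as.integer(seed),
    n_subjects = as.integer(n_subjects),
    subject_seeds = as.integer(seed) * 100L + seq_len(n_subjects),
    phantom_seed = as.integer(seed),
    dims = dims, n_modules = n_modules,
    wm_adjacent_fraction = wm_adjacent_fraction,
    midline_fraction = midline_fraction,
    bridge_fraction = bridge_fraction,
    model = model,
    S_target = S_target,
    methods = match.arg(methods, several.ok = TRUE),
    hub_top_fraction = hub_top_fraction,
    bins = as.integer(bins),
    filter = filter,
    c_denominator = match.arg(c_denominator),
    adjust_p = adjust_p
  ), class = "study_config")
}

#' Run the full correction-method comparison study
#'
#' For every subject seed and every correction method: simulate (or reuse) the
#' phantom series, band-pass filter, extract nuisance series and regress them
#' out, compute the correlation matrix and its distribution summary, threshold
#' at the target S, compute component, clustering, path-length and degree
#' metrics, parcellate the giant component, count white-matter-adjacent junk
#' nodes, and rebuild the network without wm-adjacent nodes. Then compare
#' every method pair by paired t tests on each metric and by F tests on the
#' variance of the maximum degree. Stage failures are recorded per cell and
#' the run continues. P values are reported raw (no multiple-testing
#' correction), matching the reference analysis; `adjust_p = TRUE` adds
#' Benjamini-Hochberg columns.
#'
#' @param config A [study_config()].
#' @return Object of class `gsr_study`: list with tibbles `metrics` (one row
#'   per subject x method), `comparisons` (paired t per metric and method
#'   pair), `ftests` (max-degree variance F per method pair), lists
#'   `hub_overlap`, `module_overlap`, `junk_overlap` (per method), the
#'   `phantom`, and the `config`.
#' @export
run_study <- function(config = study_config()) {
  stopifnot(inherits(config, "study_config"))
  phantom <- generate_phantom(
    dims = config$dims, n_modules = config$n_modules,
    wm_adjacent_fraction = config$wm_adjacent_fraction,
    seed = config$phantom_seed,
    midline_fraction = config$midline_fraction,
    bridge_fraction = config$bridge_fraction
  )
  methods <- config$methods
  seeds <- config$subject_seeds

  hub_masks <- stats::setNames(vector("list", length(methods)), methods)
  junk_masks <- stats::setNames(vector("list", length(methods)), methods)
  partitions <- stats::setNames(vector("list", length(methods)), methods)

  rows <- list()
  for (si in seq_along(seeds)) {
    model <- do.call(signal_model, c(config$model, list(seed = seeds[si])))
    ts_raw <- simulate_timeseries(phantom, model)
    if (config$filter) {
      ts_raw <- bandpass(ts_raw, model$passband[1], model$passband[2])
    }
    nuis <- extract_nuisance(ts_raw)
    for (meth in methods) {
      row <- tibble::tibble(subject = si, seed = seeds[si], method = meth)
      cell <- tryCatch({
        corrected <- regress_out(ts_raw, meth, nuis)
        cm <- correlation_matrix(corrected)
        summ <- summarize_distribution(cm, config$bins)
        net <- threshold_for_S(cm, config$S_target)
        comps <- network_components(net)
        dd <- degree_distribution(net)
        part <- qcut_partition(net, seed = seeds[si])
        jw <- junk_wm_count(part, phantom)
        ex <- exclude_wm_adjacent_rerun(cm, phantom, config$S_target)
        hub_masks[[meth]][[si]] <- hub_mask(net, config$hub_top_fraction)
        junk_masks[[meth]][[si]] <- part$module == part$junk_id
        partitions[[meth]][[si]] <- part
        tibble::tibble(
          mean_corr = summ$mean, sd_corr = summ$sd, skew_corr = summ$skewness,
          threshold = net$threshold, S_achieved = net$S_achieved, K = net$K,
          C = clustering_coefficient(net, config$c_denominator),
          L = path_length(net),
          Nc = comps$giant_size,
          connected_fraction = comps$connected_fraction,
          max_degree = dd$max_degree,
          Q = part$Q, n_modules = part$n_modules,
          n_junk = jw$n_junk, n_junk_wm_adjacent = jw$n_junk_wm_adjacent,
          L_without_wm_adjacent = ex$L_without,
          status = "ok"
        )
      }, error = function(e) {
        tibble::tibble(mean_corr = NA_real_, sd_corr = NA_real_,
                       skew_corr = NA_real_, threshold = NA_real_,
                       S_achieved = NA_real_, K = NA_real_, C = NA_real_,
                       L = NA_real_, Nc = NA_integer_,
                       connected_fraction = NA_real_, max_degree = NA_integer_,
                       Q = NA_real_, n_modules = NA_integer_,
                       n_junk = NA_integer_, n_junk_wm_adjacent = NA_integer_,
                       L_without_wm_adjacent = NA_real_,
                       status = paste0("failed: ", conditionMessage(e)))
      })
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(row, cell)
    }
  }
  metrics <- dplyr::bind_rows(rows)

  cmp_metrics <- c("mean_corr", "C", "L", "Nc", "connected_fraction",
                   "max_degree", "Q", "n_modules", "n_junk_wm_adjacent",
                   "L_without_wm_adjacent")
  pairs <- utils::combn(methods, 2, simplify = FALSE)
  comparisons <- purrr::map_dfr(pairs, function(pr) {
    purrr::map_dfr(cmp_metrics, function(mt) {
      a <- metrics[[mt]][metrics$method == pr[1]]
      b <- metrics[[mt]][metrics$method == pr[2]]
      keep <- stats::complete.cases(a, b)
      res <- tryCatch(paired_t(as.numeric(a[keep]), as.numeric(b[keep])),
                      error = function(e) NULL)
      tibble::tibble(
        metric = mt, method_a = pr[1], method_b = pr[2],
        mean_a = mean(a[keep]), mean_b = mean(b[keep]),
        t = if (is.null(res)) NA_real_ else res$t,
        df = if (is.null(res)) NA_integer_ else res$df,
        p = if (is.null(res)) NA_real_ else res$p,
        note = if (is.null(res)) "degenerate or incomplete" else ""
      )
    })
  })
  ftests <- purrr::map_dfr(pairs, function(pr) {
    a <- metrics$max_degree[metrics$method == pr[1]]
    b <- metrics$max_degree[metrics$method == pr[2]]
    keep <- stats::complete.cases(a, b)
    res <- tryCatch(variance_F(as.numeric(a[keep]), as.numeric(b[keep])),
                    error = function(e) NULL)
    tibble::tibble(
      metric = "max_degree_variance", method_a = pr[1], method_b = pr[2],
      var_a = stats::var(a[keep]), var_b = stats::var(b[keep]),
      F = if (is.null(res)) NA_real_ else res$F,
      p = if (is.null(res)) NA_real_ else res$p,
      note = if (is.null(res)) "degenerate or incomplete" else ""
    )
  })
  if (config$adjust_p) {
    comparisons$p_bh <- stats::p.adjust(comparisons$p, method = "BH")
    ftests$p_bh <- stats::p.adjust(ftests$p, method = "BH")
  }

  dmn_seed <- which(phantom$true_module == 1L & phantom$tissue == "gray" &
                      !phantom$midline & is.na(phantom$second_module))
  hub_overlap <- purrr::map(hub_masks, overlap_map)
  junk_overlap <- purrr::map(junk_masks, overlap_map)
  mod_overlap <- purrr::map(partitions, module_overlap, seed_nodes = dmn_seed)

  structure(list(
    metrics = metrics,
    comparisons = comparisons,
    ftests = ftests,
    hub_overlap = hub_overlap,
    junk_overlap = junk_overlap,
    module_overlap = mod_overlap,
    dmn_seed_nodes = dmn_seed,
    phantom = phantom,
    config = config,
    note = "p values are raw (no multiple-testing correction by default)"
  ), class = "gsr_study")
}

#' @export
print.gsr_study <- function(x, ...) {
  cat("<gsr_study> ", x$config$n_subjects, " subjects x ",
      length(x$config$methods), " methods; ", x$phantom$n_nodes,
      " nodes, S_target = ", x$config$S_target, "\n", sep = "")
  means <- dplyr::summarise(
    dplyr::group_by(x$metrics, .data$method),
    dplyr::across(c("mean_corr", "C", "L", "Nc", "connected_fraction",
                    "Q", "n_modules", "n_junk_wm_adjacent"),
                  ~ mean(.x, na.rm = TRUE))
  )
  print(means, n = Inf)
  invisible(x)
}
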