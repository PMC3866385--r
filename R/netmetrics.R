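#' Mean clustering coefficient
#'
#' Watts-Strogatz local clustering — triangles through a node divided by
#' `k (k - 1) / 2` — averaged over nodes. Nodes of degree < 2 have local
#' clustering 0; the default denominator averages over nodes of degree >= 2
#' only (`"deg2"`), which keeps C comparable across networks with different
#' disconnected-node counts; `"all"` averages the zero-filled values over
#' every node.
#'
#' @param network A `binary_network`.
#' @param denominator `"deg2"` (default) or `"all"`.
#' @return The mean clustering coefficient in `[0, 1]`.
#' @export
clustering_coefficient <- function(network, denominator = c("deg2", "all")) {
  stopifnot(inherits(network, "binary_network"))
  denominator <- match.arg(denominator)
  lc <- igraph::transitivity(network$graph, type = "local", isolates = "NaN")
  if (denominator == "deg2") {
    lc <- lc[!is.nan(lc)]
    if (length(lc) == 0L) return(0)
    mean(lc)
  } else {
    lc[is.nan(lc)] <- 0
    mean(lc)
  }
}

#' Harmonic-mean path length
#'
#' `L = 1 / E_glob` where `E_glob` is the global efficiency: the mean of
#' `1 / d(i, j)` over all `n (n - 1)` ordered node pairs of the full node set,
#' with `1 / Inf = 0` for disconnected pairs. Disconnected components therefore
#' register as increased path length rather than being dropped.
#'
#' @param network A `binary_network`.
#' @return Path length `L >= 1`.
#' @export
path_length <- function(network) {
  stopifnot(inherits(network, "binary_network"))
  if (igraph::ecount(network$graph) == 0L) {
    stop("Network has no edges: efficiency is 0 and L is undefined.", call. = FALSE)
  }
  d <- igraph::distances(network$graph)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  eff <- sum(inv) / (network$n * (network$n - 1))
  1 / eff
}

#' Empirical degree distribution
#'
#' Counts per observed degree value plus the maximum degree (the statistic
#' whose across-subject variance the study compares by F-test).
#'
#' @param network A `binary_network`.
#' @return List with `histogram` (tibble `degree`, `count`), `degree` (per
#'   node) and `max_degree`.
#' @export
degree_distribution <- function(network) {
  stopifnot(inherits(network, "binary_network"))
  deg <- igraph::degree(network$graph)
  tab <- table(factor(deg, levels = sort(unique(deg))))
  list(
    histogram = tibble::tibble(degree = as.integer(names(tab)),
                               count = as.integer(tab)),
    degree = as.integer(deg),
    max_degree = max(deg)
  )
}

#' Hub mask: top-degree nodes
#'
#' Selects exactly `floor(top_fraction * n)` nodes by descending degree, ties
#' broken by ascending node index, so the selection is deterministic.
#'
#' @param network A `binary_network`.
#' @param top_fraction Fraction of nodes to select, in `(0, 1]` (0.2 marks the
#'   conventional hub set).
#' @return Logical vector over the node set.
#' @export
hub_mask <- function(network, top_fraction = 0.2) {
  stopifnot(inherits(network, "binary_network"))
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1].", call. = FALSE)
  }
  k <- floor(top_fraction * network$n)
  deg <- igraph::degree(network$graph)
  sel <- order(-deg, seq_along(deg))[seq_len(k)]
  out <- rep(FALSE, network$n)
  out[sel] <- TRUE
  out
}

#' Across-subject overlap map
#'
#' Per-node count of subjects whose mask (hub set, module membership, junk
#' membership) includes the node. All masks must cover the same node set.
#'
#' @param masks List of logical vectors of equal length.
#' @return Object of class `overlap_map`: list with `count` (per node) and
#'   `n_subjects`.
#' @export
overlap_map <- function(masks) {
  if (length(masks) == 0L) stop("Need at least one mask.", call. = FALSE)
  len <- unique(lengths(masks))
  if (length(len) != 1L) stop("Masks cover mismatched node sets.", call. = FALSE)
  cnt <- Reduce(`+`, lapply(masks, as.integer))
  structure(list(count = cnt, n_subjects = length(masks)),
            class = "overlap_map")
}

#' @export
print.overlap_map <- function(x, ...) {
  cat("<overlap_map> ", length(x$count), " nodes, ", x$n_subjects,
      " subjects; max overlap ", max(x$count), "\n", sep = "")
  invisible(x)
}
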