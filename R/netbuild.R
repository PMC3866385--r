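#' Threshold a correlation matrix at a target S = log(N)/log(K)
#'
#' Builds the binary undirected network whose edges are the node pairs with
#' correlation strictly above a positive threshold, choosing the threshold so
#' that `S = log(N) / log(K)` (N the full mask node count, K the mean degree)
#' is as close as possible to `S_target`. Only positive correlations are edge
#' candidates. The search is exact: every realizable edge set corresponds to a
#' distinct observed positive value (plus a cut below the minimum), and all of
#' them are scanned via cumulative counts; ties in `|S - S_target|` break
#' toward the larger threshold (sparser network).
#'
#' @param matrix A `corr_matrix`.
#' @param S_target Target ratio, > 1 (3.0 in the reference analysis; the
#'   tested range is 2.5-3.5).
#' @return Object of class `binary_network`: list with `graph` (igraph, all n
#'   nodes including isolates), `n`, `threshold`, `K` (mean degree),
#'   `S_achieved`, `edge_rule = ">"`.
#' @export
threshold_for_S <- function(matrix, S_target = 3) {
  stopifnot(inherits(matrix, "corr_matrix"))
  if (S_target <= 1) stop("`S_target` must exceed 1.", call. = FALSE)
  n <- matrix$n
  vals <- matrix$values[upper.tri(matrix$values)]
  pos <- vals[vals > 0]
  if (length(pos) == 0L) {
    stop("No positive off-diagonal correlations: nothing to threshold.",
         call. = FALSE)
  }
  uniq <- sort(unique(pos))
  # edges(thr) with strict '>' for thr just below uniq[k] is the count of
  # values >= uniq[k]; thresholds AT uniq[k] keep values > uniq[k].
  tab <- tabulate(match(pos, uniq), nbins = length(uniq))
  cnt_ge <- rev(cumsum(rev(tab))) # values >= uniq[k]
  thresholds <- c(uniq[1] / 2, uniq) # first candidate admits every positive value
  edge_counts <- c(cnt_ge[1], cnt_ge - tab) # strict '>' at each candidate
  K <- 2 * edge_counts / n
  ok <- K > 1
  if (!any(ok)) {
    stop("No threshold yields mean degree K > 1; S is undefined.", call. = FALSE)
  }
  S <- ifelse(ok, log(n) / log(K), NA_real_)
  gap <- abs(S - S_target)
  best <- which(gap == min(gap, na.rm = TRUE)) # ties -> larger threshold
  best <- best[length(best)]
  thr <- thresholds[best]

  adj <- which(upper.tri(matrix$values) & matrix$values > thr, arr.ind = TRUE)
  g <- igraph::graph_from_edgelist(adj, directed = FALSE)
  g <- igraph::add_vertices(g, n - igraph::vcount(g))
  structure(list(
    graph = g,
    n = n,
    threshold = thr,
    K = K[best],
    S_achieved = S[best],
    edge_rule = ">"
  ), class = "binary_network")
}

#' Construct a binary network from an explicit edge list
#'
#' Plumbing used by tests and oracles: wraps an edge list (or igraph graph)
#' into the `binary_network` container without thresholding.
#'
#' @param edges Two-column matrix of 1-based node indices, or an igraph graph.
#' @param n Total node count (isolates included).
#' @param threshold Optional threshold annotation.
#' @return A `binary_network`.
#' @export
as_binary_network <- function(edges, n, threshold = NA_real_) {
  g <- if (inherits(edges, "igraph")) edges else {
    e <- as.matrix(edges)
    if (nrow(e) > 0 && any(e[, 1] == e[, 2])) stop("Self-loops are not allowed.",
                                                   call. = FALSE)
    igraph::graph_from_edgelist(e, directed = FALSE)
  }
  g <- igraph::simplify(g)
  if (igraph::vcount(g) < n) g <- igraph::add_vertices(g, n - igraph::vcount(g))
  K <- 2 * igraph::ecount(g) / n
  structure(list(graph = g, n = n, threshold = threshold, K = K,
                 S_achieved = if (K > 1) log(n) / log(K) else NA_real_,
                 edge_rule = ">"),
            class = "binary_network")
}

#' Connected components of a binary network
#'
#' Labels every node's component, the giant-component size `Nc`, and the
#' proportion of connected nodes (degree >= 1), all over the full n-node set.
#'
#' @param network A `binary_network`.
#' @return Object of class `component_labeling`: list with `component` (id per
#'   node), `giant_size`, `giant_id`, `connected_fraction`, `n_components`.
#' @export
network_components <- function(network) {
  stopifnot(inherits(network, "binary_network"))
  comp <- igraph::components(network$graph)
  sizes <- comp$csize
  giant <- which.max(sizes) # ties resolve to the lowest id (deterministic)
  structure(list(
    component = comp$membership,
    giant_size = max(sizes),
    giant_id = giant,
    connected_fraction = mean(igraph::degree(network$graph) >= 1),
    n_components = comp$no
  ), class = "component_labeling")
}

#' @export
print.binary_network <- function(x, ...) {
  cat(sprintf("<binary_network> n = %d, edges = %d, K = %.3f, threshold = %.4f (rule %s), S = %.3f\n",
              x$n, igraph::ecount(x$graph), x$K, x$threshold, x$edge_rule,
              x$S_achieved))
  invisible(x)
}
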