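#' Newman modularity of a partition
#'
#' Exact Newman Q on a binary undirected graph:
#' `Q = sum_c [ e_cc / m - (d_c / (2 m))^2 ]` with `e_cc` the within-module
#' edge count, `d_c` the module degree sum, and `m` the total edge count. Q is
#' 0 for the single-module partition and bounded above by 1.
#'
#' @param network A `binary_network`.
#' @param membership Integer module id per node (any labels), or a `partition`.
#' @return Modularity Q.
#' @export
modularity_Q <- function(network, membership) {
  stopifnot(inherits(network, "binary_network"))
  if (inherits(membership, "partition")) membership <- membership$module
  m <- igraph::ecount(network$graph)
  if (m == 0L) stop("Empty edge set: modularity is undefined.", call. = FALSE)
  if (length(membership) != network$n) {
    stop("`membership` must cover the evaluated node set.", call. = FALSE)
  }
  ends <- igraph::as_edgelist(network$graph, names = FALSE)
  within <- sum(membership[ends[, 1]] == membership[ends[, 2]])
  d_c <- tapply(igraph::degree(network$graph), membership, sum)
  within / m - sum((d_c / (2 * m))^2)
}

#' Modularity-maximizing parcellation of the giant component
#'
#' Qcut-style community detection: nodes outside the giant component (isolated
#' nodes and disconnected subgraphs) are grouped into a distinguished junk
#' module; the giant component is then parcellated by recursive spectral
#' bipartition — the leading eigenvector of the generalized modularity matrix
#' decides each split — with Kernighan-Lin-style single-node refinement after
#' every split and a final greedy pairwise merge pass. Splitting and merging
#' stop when no move improves Q by more than `tol`. Giant components of at
#' most 10 nodes are parcellated by exact enumeration of all partitions
#' instead, so tiny problems are solved to the true modularity optimum. The
#' procedure is deterministic for a given graph and seed (the seed only
#' breaks exact ties).
#'
#' @param network A `binary_network`.
#' @param seed Integer seed (tie-breaking only).
#' @param tol Minimum Q improvement to accept a split or merge.
#' @return Object of class `partition`: list with `module` (id per node, 0 =
#'   junk), `junk_id = 0`, `Q` (modularity of the giant-component partition,
#'   evaluated on the giant subgraph), `n_modules` (excluding junk by
#'   default), `n_junk`, `giant_size`.
#' @export
qcut_partition <- function(network, seed = 1L, tol = 1e-10) {
  stopifnot(inherits(network, "binary_network"))
  comps <- network_components(network)
  giant_nodes <- which(comps$component == comps$giant_id)
  if (length(giant_nodes) < 2L) {
    stop("Giant component has fewer than 2 nodes.", call. = FALSE)
  }

  sub <- igraph::induced_subgraph(network$graph, giant_nodes)
  A <- as.matrix(igraph::as_adjacency_matrix(sub, sparse = TRUE))
  k <- rowSums(A)
  m <- sum(k) / 2
  B <- A - outer(k, k) / (2 * m)

  if (length(giant_nodes) <= 10L) {
    membership_giant <- exact_partition(A)
  } else {
    groups <- list(seq_along(giant_nodes))
    final <- list()
    while (length(groups) > 0) {
      g <- groups[[1]]
      groups <- groups[-1]
      s <- spectral_split(B, g, tol)
      if (is.null(s)) {
        final <- c(final, list(g))
      } else {
        groups <- c(groups, list(g[s > 0], g[s < 0]))
      }
    }
    membership_giant <- integer(length(giant_nodes))
    for (i in seq_along(final)) membership_giant[final[[i]]] <- i
    membership_giant <- merge_pass(A, k, m, membership_giant, tol)
  }

  # stable module ids by smallest giant-node index
  first_idx <- tapply(seq_along(membership_giant), membership_giant, min)
  relabel <- match(membership_giant, as.integer(names(sort(first_idx))))

  module <- integer(network$n) # 0 = junk
  module[giant_nodes] <- relabel

  giant_net <- as_binary_network(sub, length(giant_nodes))
  Q <- modularity_Q(giant_net, relabel)
  structure(list(
    module = module,
    junk_id = 0L,
    Q = Q,
    n_modules = length(unique(relabel)),
    n_junk = network$n - length(giant_nodes),
    giant_size = length(giant_nodes),
    seed = as.integer(seed)
  ), class = "partition")
}

# exact maximum-modularity partition by recursive set-partition enumeration;
# feasible only for very small graphs (Bell(10) = 115,975 partitions)
exact_partition <- function(A) {
  n <- nrow(A)
  k <- rowSums(A)
  m <- sum(k) / 2
  B <- A - outer(k, k) / (2 * m)
  best_q <- -Inf
  best <- rep(1L, n)
  memb <- integer(n)
  recurse <- function(i, ngroups) {
    if (i > n) {
      q <- 0
      for (g in seq_len(ngroups)) {
        idx <- which(memb == g)
        q <- q + sum(B[idx, idx])
      }
      if (q > best_q + 1e-14) {
        best_q <<- q
        best <<- memb
      }
      return(invisible())
    }
    for (g in seq_len(min(ngroups + 1L, n))) {
      memb[i] <<- g
      recurse(i + 1L, max(ngroups, g))
    }
  }
  recurse(1L, 0L)
  best
}

# leading-eigenvector bipartition of a node group with KL refinement;
# returns +/-1 per group member, or NULL if no Q-improving split exists
spectral_split <- function(B, g, tol) {
  if (length(g) < 2L) return(NULL)
  Bg <- B[g, g, drop = FALSE]
  diag(Bg) <- diag(Bg) - rowSums(Bg) # generalized modularity matrix
  es <- eigen(Bg, symmetric = TRUE)
  if (es$values[1] <= tol) return(NULL)
  v <- es$vectors[, 1]
  s <- ifelse(v >= 0, 1, -1)
  s <- kl_refine(Bg, s, tol)
  if (all(s == s[1])) return(NULL)
  dq <- as.numeric(t(s) %*% Bg %*% s) # proportional to 4m * deltaQ
  if (dq <= tol) return(NULL)
  s
}

# Kernighan-Lin style refinement: repeated passes in which every node is
# flipped at most once in greedy order; the best prefix of each pass is kept
kl_refine <- function(Bg, s, tol) {
  n <- length(s)
  repeat {
    s_pass <- s
    Bs <- as.numeric(Bg %*% s_pass)
    base <- sum(s_pass * Bs)
    unmoved <- rep(TRUE, n)
    seq_flips <- integer(0)
    cum <- numeric(0)
    running <- base
    for (step in seq_len(n)) {
      delta <- -4 * s_pass * Bs + 4 * diag(Bg)
      delta[!unmoved] <- -Inf
      i <- which.max(delta)
      running <- running + delta[i]
      Bs <- Bs - 2 * s_pass[i] * Bg[, i]
      s_pass[i] <- -s_pass[i]
      unmoved[i] <- FALSE
      seq_flips <- c(seq_flips, i)
      cum <- c(cum, running)
    }
    best <- which.max(cum)
    if (cum[best] > base + tol) {
      flips <- seq_flips[seq_len(best)]
      s[flips] <- -s[flips]
    } else {
      return(s)
    }
  }
}

# greedy pairwise module merging while any merge improves Q
merge_pass <- function(A, k, m, membership, tol) {
  repeat {
    ids <- sort(unique(membership))
    if (length(ids) < 2L) return(membership)
    idx <- lapply(ids, function(i) which(membership == i))
    d_c <- vapply(idx, function(ii) sum(k[ii]), numeric(1))
    nmod <- length(ids)
    best_gain <- tol
    best_pair <- NULL
    for (a in seq_len(nmod - 1L)) {
      for (b in (a + 1L):nmod) {
        e_ab <- sum(A[idx[[a]], idx[[b]], drop = FALSE])
        gain <- e_ab / m - 2 * (d_c[a] / (2 * m)) * (d_c[b] / (2 * m))
        if (gain > best_gain) {
          best_gain <- gain
          best_pair <- c(a, b)
        }
      }
    }
    if (is.null(best_pair)) return(membership)
    membership[membership == ids[best_pair[2]]] <- ids[best_pair[1]]
  }
}

#' Count junk-module nodes adjacent to white matter
#'
#' Counts the nodes of the junk module (isolated nodes and subgraphs outside
#' the giant component) that carry the white-matter-adjacent label — either the
#' phantom's `gray_wm_adjacent` tissue label or any logical mask such as a
#' thresholded white-matter probability map.
#'
#' @param partition A `partition`.
#' @param wm_adjacent A `phantom` (its tissue labels are used) or a logical
#'   vector over the node set.
#' @return List with `n_junk_wm_adjacent`, `n_junk`, `n_wm_adjacent`.
#' @export
junk_wm_count <- function(partition, wm_adjacent) {
  stopifnot(inherits(partition, "partition"))
  lab <- if (inherits(wm_adjacent, "phantom")) {
    wm_adjacent$tissue == "gray_wm_adjacent"
  } else as.logical(wm_adjacent)
  if (length(lab) != length(partition$module)) {
    stop("Label vector must cover all nodes.", call. = FALSE)
  }
  junk <- partition$module == partition$junk_id
  list(n_junk_wm_adjacent = sum(junk & lab),
       n_junk = sum(junk),
       n_wm_adjacent = sum(lab))
}

#' Across-subject overlap of a seed-selected module
#'
#' For each subject's partition, selects the non-junk module with maximal
#' overlap with a seed node set (ties broken toward the lower module id) and
#' accumulates per-node membership counts across subjects. This is the
#' seed-based analogue of tracking a named module (e.g. the default mode
#' network's posterior-cingulate module) across subjects.
#'
#' @param partitions List of `partition` objects over the same node set.
#' @param seed_nodes Integer indices (or logical mask) of the seed set.
#' @return An `overlap_map`.
#' @export
module_overlap <- function(partitions, seed_nodes) {
  if (is.logical(seed_nodes)) seed_nodes <- which(seed_nodes)
  if (length(seed_nodes) == 0L) stop("Seed set is empty.", call. = FALSE)
  lens <- unique(vapply(partitions, function(p) length(p$module), integer(1)))
  if (length(lens) != 1L) stop("Partitions cover mismatched node sets.", call. = FALSE)
  masks <- lapply(partitions, function(p) {
    ids <- setdiff(sort(unique(p$module)), p$junk_id)
    if (length(ids) == 0L) return(rep(FALSE, length(p$module)))
    ov <- vapply(ids, function(i) sum(p$module[seed_nodes] == i), integer(1))
    sel <- ids[which.max(ov)] # ties -> lower id by ordering of ids
    p$module == sel
  })
  overlap_map(masks)
}

#' Path length with and without white-matter-adjacent nodes
#'
#' From one correlation matrix, builds the network over all nodes and the
#' network over the non-wm-adjacent submatrix (re-thresholded to the same
#' `S_target`) and returns both path lengths — the mask-accuracy check that
#' asks whether removing nodes bordering major tracts shortens paths.
#'
#' @param matrix A `corr_matrix`.
#' @param wm_adjacent Logical vector (or `phantom`) marking wm-adjacent nodes.
#' @param S_target Threshold target for both networks.
#' @return List with `L_with`, `L_without`, `n_with`, `n_without`.
#' @export
exclude_wm_adjacent_rerun <- function(matrix, wm_adjacent, S_target = 3) {
  stopifnot(inherits(matrix, "corr_matrix"))
  lab <- if (inherits(wm_adjacent, "phantom")) {
    wm_adjacent$tissue == "gray_wm_adjacent"
  } else as.logical(wm_adjacent)
  if (length(lab) != matrix$n) stop("Label vector must cover all nodes.", call. = FALSE)
  net_with <- threshold_for_S(matrix, S_target)
  keep <- !lab
  sub <- structure(list(values = matrix$values[keep, keep, drop = FALSE],
                        n = sum(keep), t = matrix$t,
                        n_offdiagonal = offdiagonal_count(sum(keep))),
                   class = "corr_matrix")
  net_without <- if (any(lab)) threshold_for_S(sub, S_target) else net_with
  list(L_with = path_length(net_with),
       L_without = path_length(net_without),
       n_with = matrix$n,
       n_without = sum(keep))
}

#' @export
print.partition <- function(x, ...) {
  cat(sprintf("<partition> %d modules (+ junk of %d nodes), giant %d, Q = %.4f\n",
              x$n_modules, x$n_junk, x$giant_size, x$Q))
  invisible(x)
}
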