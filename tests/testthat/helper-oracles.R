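# Independent brute-force oracles, deliberately naive: these never reuse the
# package's graph code paths.

# random simple graph as an edge list over n nodes
random_graph <- function(n, p, seed) {
  set.seed(seed)
  pairs <- t(utils::combn(n, 2))
  pairs[stats::runif(nrow(pairs)) < p, , drop = FALSE]
}

adj_from_edges <- function(edges, n) {
  A <- matrix(0L, n, n)
  if (nrow(edges)) {
    A[edges] <- 1L
    A[edges[, c(2, 1), drop = FALSE]] <- 1L
  }
  A
}

# mean local clustering by explicit triangle counting
oracle_clustering <- function(A, denominator = "deg2") {
  n <- nrow(A)
  deg <- rowSums(A)
  lc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(A[i, ] == 1)
    k <- length(nb)
    if (k < 2) { lc[i] <- 0; next }
    tri <- sum(A[nb, nb]) / 2
    lc[i] <- tri / (k * (k - 1) / 2)
  }
  if (denominator == "deg2") {
    keep <- deg >= 2
    if (!any(keep)) return(0)
    mean(lc[keep])
  } else mean(lc)
}

# all-pairs BFS distances
oracle_distances <- function(A) {
  n <- nrow(A)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  for (s in seq_len(n)) {
    dist <- rep(Inf, n)
    dist[s] <- 0
    frontier <- s
    d <- 0
    while (length(frontier)) {
      d <- d + 1
      nxt <- unique(unlist(lapply(frontier, function(v) which(A[v, ] == 1))))
      nxt <- nxt[dist[nxt] == Inf]
      dist[nxt] <- d
      frontier <- nxt
    }
    D[s, ] <- dist
  }
  D
}

# harmonic-mean path length over all ordered pairs (1/Inf = 0)
oracle_path_length <- function(A) {
  D <- oracle_distances(A)
  inv <- 1 / D
  diag(inv) <- 0
  1 / (sum(inv) / (nrow(A) * (nrow(A) - 1)))
}

# Newman Q by the definitional double loop
oracle_modularity <- function(A, membership) {
  m <- sum(A) / 2
  deg <- rowSums(A)
  q <- 0
  n <- nrow(A)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (membership[i] == membership[j]) {
        q <- q + A[i, j] - deg[i] * deg[j] / (2 * m)
      }
    }
  }
  q / (2 * m)
}

# exhaustive-search maximum modularity over all partitions (set partitions
# enumerated recursively; feasible to ~10 nodes)
oracle_best_partition <- function(A) {
  n <- nrow(A)
  best <- list(Q = -Inf, membership = rep(1L, n))
  assign_next <- function(membership, i, k) {
    if (i > n) {
      q <- oracle_modularity(A, membership)
      if (q > best$Q) best <<- list(Q = q, membership = membership)
      return(invisible())
    }
    for (g in seq_len(k + 1)) {
      membership[i] <- g
      assign_next(membership, i + 1L, max(k, g))
    }
  }
  assign_next(integer(n), 1L, 0L)
  best
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / ch2(n)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# planted-partition graph: k blocks of size b
planted_partition_graph <- function(k, b, p_in, p_out, seed) {
  set.seed(seed)
  n <- k * b
  block <- rep(seq_len(k), each = b)
  pairs <- t(utils::combn(n, 2))
  same <- block[pairs[, 1]] == block[pairs[, 2]]
  keep <- stats::runif(nrow(pairs)) < ifelse(same, p_in, p_out)
  list(edges = pairs[keep, , drop = FALSE], block = block, n = n)
}
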