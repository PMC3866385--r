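two_clique_bridge <- function() {
  edges <- rbind(t(utils::combn(4, 2)), t(utils::combn(4, 2)) + 4L, c(4L, 5L))
  as_binary_network(edges, 8)
}

test_that("modularity Q: single module is 0; two-clique value is exact", {
  net <- two_clique_bridge()
  expect_equal(modularity_Q(net, rep(1, 8)), 0, tolerance = 1e-12)
  # m = 13, e_cc = 6 each, d_c = 13 each: Q = 12/13 - 1/2
  expect_equal(modularity_Q(net, rep(1:2, each = 4)), 12 / 13 - 0.5)
  expect_error(modularity_Q(as_binary_network(matrix(integer(0), 0, 2), 4),
                            rep(1, 4)), "Empty edge set")
})

test_that("Q matches the double-loop oracle and igraph on random partitions", {
  for (seed in 1:5) {
    n <- sample(8:25, 1)
    edges <- random_graph(n, 0.3, seed + 40)
    if (nrow(edges) == 0) next
    net <- as_binary_network(edges, n)
    A <- adj_from_edges(edges, n)
    set.seed(seed)
    memb <- sample(1:3, n, replace = TRUE)
    q <- modularity_Q(net, memb)
    expect_equal(q, oracle_modularity(A, memb), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(net$graph, memb), tolerance = 1e-12)
  }
})

test_that("qcut recovers the two-clique optimum found by exhaustive search", {
  net <- two_clique_bridge()
  part <- qcut_partition(net)
  expect_equal(part$n_modules, 2)
  expect_equal(part$Q, 12 / 13 - 0.5, tolerance = 1e-9)
  expect_equal(part$module[1:4], rep(part$module[1], 4))
  expect_equal(part$module[5:8], rep(part$module[5], 4))
  A <- adj_from_edges(igraph::as_edgelist(net$graph, names = FALSE), 8)
  best <- oracle_best_partition(A)
  expect_equal(part$Q, best$Q, tolerance = 1e-9)
})

test_that("qcut attains the exhaustive optimum on small random graphs", {
  found <- 0
  for (seed in 1:12) {
    n <- sample(5:8, 1)
    edges <- random_graph(n, 0.45, seed + 300)
    net <- as_binary_network(edges, n)
    comps <- network_components(net)
    if (comps$giant_size < 3) next
    found <- found + 1
    part <- qcut_partition(net)
    giant <- which(comps$component == comps$giant_id)
    Ag <- adj_from_edges(igraph::as_edgelist(
      igraph::induced_subgraph(net$graph, giant), names = FALSE), length(giant))
    best <- oracle_best_partition(Ag)
    expect_gte(part$Q, best$Q - 1e-9)
  }
  expect_gte(found, 6)
})

test_that("qcut: no community structure in a complete graph; junk assembled", {
  k10 <- as_binary_network(t(utils::combn(10, 2)), 12) # 2 isolated nodes
  part <- qcut_partition(k10)
  expect_equal(part$n_modules, 1)
  expect_equal(part$Q, 0, tolerance = 1e-9)
  expect_equal(part$module[11:12], c(0L, 0L))
  expect_equal(part$n_junk, 2)
  expect_error(qcut_partition(as_binary_network(matrix(integer(0), 0, 2), 3)),
               "Giant component|no edges|fewer than 2")
})

test_that("qcut beats single-module and random partitions of equal size", {
  for (seed in c(2, 5)) {
    g <- planted_partition_graph(3, 12, 0.6, 0.05, seed)
    net <- as_binary_network(g$edges, g$n)
    part <- qcut_partition(net)
    expect_gte(part$Q, 0)
    giant_net <- net
    set.seed(seed)
    rand_memb <- sample(part$module)
    expect_gte(part$Q + 1e-12, modularity_Q(giant_net, rand_memb))
  }
})

test_that("qcut recovers planted partitions with high adjusted agreement", {
  aris <- vapply(1:10, function(seed) {
    g <- planted_partition_graph(4, 25, 0.5, 0.02, seed + 500)
    net <- as_binary_network(g$edges, g$n)
    part <- qcut_partition(net, seed = seed)
    giant <- part$module > 0
    adjusted_rand(part$module[giant], g$block[giant])
  }, numeric(1))
  expect_gte(mean(aris >= 0.9), 0.9)
  # cross-check one case against mclust's ARI implementation
  skip_if_not_installed("mclust")
  g <- planted_partition_graph(4, 25, 0.5, 0.02, 501)
  part <- qcut_partition(as_binary_network(g$edges, g$n), seed = 1)
  giant <- part$module > 0
  expect_equal(adjusted_rand(part$module[giant], g$block[giant]),
               mclust::adjustedRandIndex(part$module[giant], g$block[giant]))
})

test_that("qcut is deterministic", {
  g <- planted_partition_graph(4, 20, 0.4, 0.05, 9)
  net <- as_binary_network(g$edges, g$n)
  expect_identical(qcut_partition(net, seed = 3), qcut_partition(net, seed = 3))
})

test_that("junk-WM counting respects labels and bounds", {
  part <- structure(list(module = c(0L, 0L, 1L, 1L, 2L, 0L), junk_id = 0L),
                    class = "partition")
  lab <- c(TRUE, FALSE, TRUE, FALSE, FALSE, TRUE)
  res <- junk_wm_count(part, lab)
  expect_equal(res$n_junk_wm_adjacent, 2)
  expect_equal(res$n_junk, 3)
  part2 <- structure(list(module = c(1L, 1L, 2L), junk_id = 0L), class = "partition")
  expect_equal(junk_wm_count(part2, c(TRUE, TRUE, TRUE))$n_junk_wm_adjacent, 0)
  expect_equal(junk_wm_count(part, rep(TRUE, 6))$n_junk_wm_adjacent, 3)
  expect_error(junk_wm_count(part, lab[1:3]), "cover all nodes")
})

test_that("module overlap selects the seed-dominant module deterministically", {
  p <- structure(list(module = c(1L, 1L, 2L, 2L, 0L), junk_id = 0L),
                 class = "partition")
  om <- module_overlap(replicate(5, p, simplify = FALSE), seed_nodes = c(1, 2))
  expect_equal(om$count, c(5L, 5L, 0L, 0L, 0L))
  # seed straddling two modules equally -> lower module id wins
  om2 <- module_overlap(list(p), seed_nodes = c(2, 3))
  expect_equal(om2$count, c(1L, 1L, 0L, 0L, 0L))
  expect_error(module_overlap(list(p), integer(0)), "empty")
})

test_that("wm-exclusion rerun: identity at zero fraction, drop for isolates", {
  set.seed(11)
  v <- cor(matrix(rnorm(30 * 40), nrow = 40)) # 30 nodes in columns
  cm <- matrix_corr(v)
  same <- exclude_wm_adjacent_rerun(cm, rep(FALSE, 30), 3)
  expect_equal(same$L_with, same$L_without)
  expect_equal(same$n_with, same$n_without + 0)
  # removing nodes that are isolated in the thresholded graph lowers L
  net <- threshold_for_S(cm, 3)
  iso <- igraph::degree(net$graph) == 0
  if (any(iso)) {
    res <- exclude_wm_adjacent_rerun(cm, iso, 3)
    expect_lt(res$L_without, res$L_with)
  }
})
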