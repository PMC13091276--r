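make_named <- function(g) { igraph::V(g)$name <- paste0("v", seq_len(igraph::vcount(g))); g }

test_that("pruning removes isolated vertices always and tiny components only for display", {
  g <- igraph::make_full_graph(4) |> make_named()
  g <- igraph::add_vertices(g, 3)
  igraph::V(g)$name[5:7] <- paste0("iso", 1:3)
  pruned <- prune_network(g)
  expect_equal(igraph::vcount(pruned), 4)
  # a 2-node component survives metric pruning but not the viz export
  h <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(2)) |>
    make_named()
  expect_equal(igraph::vcount(prune_network(h)), 6)
  expect_equal(igraph::vcount(prune_network(h, for_visualization = TRUE)), 4)
  empty <- igraph::make_empty_graph(0, directed = FALSE)
  expect_equal(nrow(global_metrics(prune_network(empty))), 1)
})

test_that("global metrics match closed forms on canonical graphs", {
  k3 <- make_named(igraph::make_full_graph(3))
  gm <- global_metrics(k3)
  expect_equal(gm$transitivity, 1)
  expect_equal(gm$density, 1)
  expect_equal(gm$diameter, 1)
  p3 <- make_named(igraph::make_ring(3, circular = FALSE))
  gm3 <- global_metrics(p3)
  expect_equal(gm3$transitivity, 0)
  expect_equal(gm3$diameter, 2)
  two_k5 <- make_named(igraph::disjoint_union(igraph::make_full_graph(5),
                                              igraph::make_full_graph(5)))
  expect_equal(signed_modularity(two_k5, rep(1:2, each = 5)), 0.5)
})

test_that("node metrics match closed forms on stars and cycles", {
  st <- make_named(igraph::make_star(21, mode = "undirected"))
  nm <- node_metrics(st)
  hub <- nm[which.max(nm$degree), ]
  expect_equal(hub$degree, 20L)
  expect_equal(hub$betweenness, 20 * 19 / 2)
  expect_equal(hub$closeness, max(nm$closeness))
  cyc <- make_named(igraph::make_ring(8))
  nmc <- node_metrics(cyc)
  for (col in c("degree", "betweenness", "closeness", "eigen_centrality",
                "local_transitivity"))
    expect_lt(diff(range(nmc[[col]])), 1e-9)
})

test_that("node metrics agree with brute-force oracles on random 12-node graphs", {
  for (s in 1:6) {
    rg <- random_test_graph(12, seed = s)
    nm <- node_metrics(rg$graph)
    expect_equal(nm$degree, unname(rowSums(rg$adj)))
    expect_equal(nm$betweenness, bf_betweenness(rg$adj), tolerance = 1e-9)
    expect_equal(nm$closeness, bf_harmonic_closeness(rg$adj), tolerance = 1e-9)
    # eigen-centrality: leading eigenvector of the adjacency
    ev <- eigen(rg$adj, symmetric = TRUE)$vectors[, 1]
    ev <- abs(ev) / max(abs(ev))
    expect_equal(nm$eigen_centrality, ev, tolerance = 1e-6)
    # global transitivity: 3 * triangles / connected triples
    tri <- sum(diag(rg$adj %*% rg$adj %*% rg$adj)) / 6
    triples <- sum(choose(rowSums(rg$adj), 2))
    gm <- global_metrics(rg$graph)
    expect_equal(gm$transitivity, 3 * tri / triples, tolerance = 1e-12)
  }
})

test_that("signed community detection keeps negatively linked cliques apart", {
  single <- make_named(igraph::make_full_graph(5))
  cm0 <- detect_communities(single, seed = 1)
  expect_equal(length(unique(cm0$community)), 1)
  g2 <- igraph::disjoint_union(igraph::make_full_graph(4), igraph::make_full_graph(4)) |>
    make_named()
  igraph::E(g2)$weight <- 1
  g2 <- igraph::add_edges(g2, c(1, 5), attr = list(weight = -0.5))
  cm <- detect_communities(g2, resolution = 0.5, seed = 1)
  expect_equal(length(unique(cm$community)), 2)
  expect_equal(length(unique(cm$community[1:4])), 1)
  expect_equal(length(unique(cm$community[5:8])), 1)
  # achieved Q at least matches the trivial one-community partition
  q <- attr(cm, "modularity")
  expect_gte(q, signed_modularity(g2, rep(1L, 8), resolution = 0.5))
})

test_that("keystone scoring z-scores the four centralities and handles degeneracy", {
  st <- make_named(igraph::make_star(21, mode = "undirected"))
  ks <- keystone_taxa(node_metrics(st))
  expect_equal(ks$node[which.max(ks$combined_score)],
               ks$node[ks$degree == 20])
  expect_true(attr(ks, "tie_flagged"))  # all leaves tie at the cutoff
  cyc <- make_named(igraph::make_ring(10))
  ksc <- keystone_taxa(node_metrics(cyc))
  expect_true(all(abs(ksc$combined_score) < 1e-9))
  expect_true(attr(ksc, "tie_flagged"))
  # adding edges to one node raises its degree z-score
  g <- make_named(igraph::make_ring(10))
  nm1 <- keystone_taxa(node_metrics(g))
  g2 <- igraph::add_edges(g, c(1, 4, 1, 5, 1, 6))
  nm2 <- keystone_taxa(node_metrics(g2))
  expect_gt(nm2$z_degree[nm2$node == "v1"], nm1$z_degree[nm1$node == "v1"])
})

test_that("keystone set size is ceil(5% of nodes) absent ties and label-invariant", {
  rg <- random_test_graph(40, p_edge = 0.2, seed = 3)
  nm <- node_metrics(rg$graph)
  ks <- keystone_taxa(nm, 0.05)
  if (!attr(ks, "tie_flagged")) expect_equal(sum(ks$is_keystone), ceiling(0.05 * 40))
  perm <- sample(40)
  g2 <- igraph::permute(rg$graph, perm)
  ks2 <- keystone_taxa(node_metrics(g2), 0.05)
  expect_setequal(ks2$node[ks2$is_keystone], ks$node[ks$is_keystone])
})

test_that("robustness curves match closed forms on complete graphs and stars", {
  k20 <- make_named(igraph::make_full_graph(20))
  rb <- robustness(k20, "targeted_betweenness")
  expect_equal(rb$auc, 0.5, tolerance = 1e-12)
  expect_equal(rb$curve$lcc_fraction, (20:0) / 20)
  st <- make_named(igraph::make_star(21, mode = "undirected"))
  rbs <- robustness(st, "targeted_betweenness")
  expect_equal(rbs$curve$lcc_fraction[2], 1 / 21)
  expect_equal(rbs$r50, 1 / 21)
  expect_error(robustness(igraph::make_empty_graph(0, directed = FALSE)), "empty")
})

test_that("targeted attacks dominate random failure on synthetic graphs", {
  set.seed(4)
  worse <- logical(8)
  for (i in seq_len(8)) {
    g <- igraph::sample_gnp(30, 0.12)
    while (igraph::components(g)$no > 3) g <- igraph::sample_gnp(30, 0.12)
    g <- make_named(g)
    tg <- robustness(g, "targeted_betweenness", seed = i)
    rd <- robustness(g, "random", n_random_reps = 20, seed = i)
    worse[i] <- tg$auc <= rd$auc + 1e-9
  }
  expect_true(all(worse))
})

test_that("network reports carry the full metric vocabulary", {
  om <- make_precision_matrix("cluster", 15, 0.3)
  counts <- sample_network_counts(om, 120, 8000, seed = 2)
  net <- infer_network(counts, prevalence = 0, n_reps = 10, seed = 5)
  rp <- network_report(net, with_random = TRUE, n_random_reps = 5)
  expect_true(all(c("modularity", "transitivity", "density", "avg_path_length",
                    "diameter", "n_positive", "n_negative") %in% names(rp$global)))
  expect_true(all(c("degree", "betweenness", "closeness", "eigen_centrality",
                    "hub_score", "local_transitivity") %in% names(rp$nodes)))
  expect_s3_class(rp$robustness_targeted, "robustness_curve")
  expect_true(rp$robustness_targeted$auc >= 0 && rp$robustness_targeted$auc <= 1)
})
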