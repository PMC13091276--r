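# Small fixtures built in code.

toy_counts <- function() {
  m <- matrix(c(5L, 3L, 0L, 2L,
                1L, 0L, 4L, 4L,
                2L, 2L, 2L, 2L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), c("asv1", "asv2", "asv3", "asv4")))
  as_count_tbl(m)
}

toy_taxonomy <- function() {
  tibble::tibble(
    taxon_id = c("asv1", "asv2", "asv3", "asv4"),
    kingdom = "Bacteria",
    phylum = c("Bacillota", "Bacillota", "Bacteroidota", "Bacteroidota"),
    class = NA_character_, order = NA_character_,
    family = c("f1", "f1", "f2", "f2"),
    genus = c("GenA", "GenA", "GenB", "GenC"))
}

# Independent brute-force centrality oracles (adjacency-matrix based,
# sharing no code with the package).
bf_shortest_paths <- function(adj) {
  n <- nrow(adj)
  d <- ifelse(adj > 0, adj, Inf); diag(d) <- 0
  cnt <- ifelse(adj > 0, 1, 0); diag(cnt) <- 0
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    alt <- d[i, k] + d[k, j]
    if (alt < d[i, j] - 1e-12) {
      d[i, j] <- alt
      cnt[i, j] <- cnt[i, k] * cnt[k, j]
    } else if (is.finite(alt) && abs(alt - d[i, j]) < 1e-12 && k != i && k != j) {
      cnt[i, j] <- cnt[i, j] + cnt[i, k] * cnt[k, j]
    }
  }
  list(d = d, cnt = cnt)
}

bf_betweenness <- function(adj) {
  n <- nrow(adj)
  sp <- bf_shortest_paths(adj)
  bt <- numeric(n)
  for (v in seq_len(n)) {
    adj2 <- adj; adj2[v, ] <- 0; adj2[, v] <- 0
    sp2 <- bf_shortest_paths(adj2)
    for (s in seq_len(n)) for (t in seq_len(n)) {
      if (s >= t || s == v || t == v) next
      if (!is.finite(sp$d[s, t]) || sp$cnt[s, t] == 0) next
      # paths through v: total minus those avoiding v at the same length
      thr <- sp$cnt[s, t]
      if (is.finite(sp2$d[s, t]) && abs(sp2$d[s, t] - sp$d[s, t]) < 1e-12)
        thr <- thr - sp2$cnt[s, t]
      bt[v] <- bt[v] + thr / sp$cnt[s, t]
    }
  }
  bt
}

bf_harmonic_closeness <- function(adj) {
  sp <- bf_shortest_paths(adj)
  n <- nrow(adj)
  sapply(seq_len(n), function(v) sum(1 / sp$d[v, -v][is.finite(sp$d[v, -v])]) / (n - 1))
}

random_test_graph <- function(n, p_edge = 0.35, seed = 1) {
  set.seed(seed)
  repeat {
    adj <- matrix(0, n, n)
    adj[upper.tri(adj)] <- rbinom(n * (n - 1) / 2, 1, p_edge)
    adj <- adj + t(adj)
    if (all(rowSums(adj) > 0)) break
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  igraph::V(g)$name <- paste0("v", seq_len(n))
  list(graph = g, adj = adj)
}
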