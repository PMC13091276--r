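# Graph-level and node-level metrics, signed community detection,
# keystone identification, pruning, and targeted-attack robustness.

as_graph <- function(net) {
  if (inherits(net, "mb_network")) net$graph
  else if (igraph::is_igraph(net)) net
  else abort("expected an mb_network or igraph graph")
}

edge_distances <- function(g, weighted = TRUE) {
  if (!weighted || igraph::ecount(g) == 0 || is.null(igraph::E(g)$weight))
    return(NULL)
  1 / abs(igraph::E(g)$weight)   # strong associations = short distances
}

#' Prune a network before metrics or visualization
#'
#' Isolated vertices (degree 0) are always removed. With
#' `for_visualization = TRUE`, connected components of 2 or fewer nodes
#' are also dropped — a display rule only, never applied before metrics.
#'
#' @param net `mb_network` or igraph graph.
#' @param for_visualization also drop components of <= 2 nodes.
#' @return igraph graph.
#' @export
prune_network <- function(net, for_visualization = FALSE) {
  g <- as_graph(net)
  g <- igraph::delete_vertices(g, which(igraph::degree(g) == 0))
  if (for_visualization && igraph::vcount(g) > 0) {
    cmp <- igraph::components(g)
    small <- which(cmp$csize[cmp$membership] <= 2)
    g <- igraph::delete_vertices(g, small)
  }
  g
}

#' Signed modularity Q+ - Q-
#'
#' Newman modularity of the positive-edge subgraph (at the given
#' resolution) minus modularity of the negative-edge subgraph (absolute
#' weights, resolution 1). Empty layers contribute 0.
#'
#' @param net `mb_network` or igraph graph (edge attribute `weight`).
#' @param membership integer community membership per vertex.
#' @param resolution resolution for the positive layer.
#' @return numeric modularity.
#' @export
signed_modularity <- function(net, membership, resolution = 1) {
  g <- as_graph(net)
  if (igraph::ecount(g) == 0) return(0)
  w <- igraph::E(g)$weight %||% rep(1, igraph::ecount(g))
  layer_q <- function(keep, res) {
    sub <- igraph::subgraph_from_edges(g, which(keep), delete.vertices = FALSE)
    if (igraph::ecount(sub) == 0) return(0)
    ws <- igraph::E(sub)$weight %||% rep(1, igraph::ecount(sub))
    igraph::modularity(sub, membership, weights = abs(ws), resolution = res)
  }
  layer_q(w > 0, resolution) - layer_q(w < 0, 1)
}

#' Global network metrics
#'
#' Modularity is the signed convention of [signed_modularity()] on the
#' supplied partition; transitivity is the global clustering coefficient
#' (3 x triangles / connected triples); density `m / (n(n-1)/2)`; average
#' path length and diameter are computed on the largest connected
#' component using `1/|weight|` distances (flagged when the graph is
#' disconnected).
#'
#' @param net `mb_network` or igraph graph.
#' @param membership community membership (default: every node its own
#'   community is avoided — connected components are used).
#' @param resolution resolution for the signed modularity.
#' @param weighted use `1/|weight|` path distances.
#' @return one-row tibble of global metrics.
#' @export
global_metrics <- function(net, membership = NULL, resolution = 1, weighted = TRUE) {
  g <- as_graph(net)
  n <- igraph::vcount(g); m <- igraph::ecount(g)
  if (n == 0)
    return(tibble::tibble(n_nodes = 0L, n_edges = 0L, n_positive = 0L,
                          n_negative = 0L, density = NA_real_,
                          transitivity = NA_real_, modularity = NA_real_,
                          avg_path_length = NA_real_, diameter = NA_real_,
                          lcc_flagged = FALSE))
  if (is.null(membership)) membership <- igraph::components(g)$membership
  w <- if (m > 0) igraph::E(g)$weight %||% rep(1, m) else numeric(0)
  cmp <- igraph::components(g)
  lcc <- igraph::induced_subgraph(g, which(cmp$membership == which.max(cmp$csize)))
  dl <- edge_distances(lcc, weighted)
  apl <- if (igraph::vcount(lcc) > 1)
    igraph::mean_distance(lcc, weights = dl, directed = FALSE) else NA_real_
  diam <- if (igraph::vcount(lcc) > 1)
    igraph::diameter(lcc, weights = dl, directed = FALSE) else NA_real_
  tibble::tibble(
    n_nodes = n, n_edges = m,
    n_positive = sum(w > 0), n_negative = sum(w < 0),
    density = if (n > 1) m / (n * (n - 1) / 2) else NA_real_,
    transitivity = igraph::transitivity(g, type = "global", isolates = "zero"),
    modularity = signed_modularity(g, membership, resolution),
    avg_path_length = apl, diameter = diam,
    lcc_flagged = cmp$no > 1)
}

#' Node-level centrality metrics
#'
#' Degree (unweighted count), betweenness on `1/|weight|` shortest-path
#' distances, harmonic closeness on the same distances, eigen-centrality
#' and hub score on absolute weights (identical up to scale for
#' undirected graphs; both reported), and local transitivity.
#'
#' @param net `mb_network` or igraph graph (>= 2 nodes).
#' @param weighted use edge weights as above.
#' @return tibble, one row per node.
#' @export
node_metrics <- function(net, weighted = TRUE) {
  g <- as_graph(net)
  if (igraph::vcount(g) < 2) abort("need at least two nodes")
  dl <- edge_distances(g, weighted)
  wa <- if (weighted && !is.null(igraph::E(g)$weight)) abs(igraph::E(g)$weight) else NULL
  # ARPACK draws its start vector from the RNG; pin it for determinism
  eig <- with_seed(1L, igraph::eigen_centrality(g, weights = wa)$vector)
  hub <- with_seed(1L, igraph::hits_scores(g, weights = wa)$hub)
  lt <- igraph::transitivity(g, type = "local", isolates = "zero")
  tibble::tibble(
    node = igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g))),
    kingdom = igraph::V(g)$kingdom %||% NA_character_,
    degree = as.integer(igraph::degree(g)),
    betweenness = unname(igraph::betweenness(g, weights = dl, directed = FALSE)),
    closeness = unname(igraph::harmonic_centrality(g, weights = dl,
                                                   normalized = TRUE)),
    eigen_centrality = unname(eig),
    hub_score = unname(hub),
    local_transitivity = unname(lt))
}

#' Signed community detection (Leiden + signed refinement)
#'
#' Starts from a Leiden modularity partition of the positive-edge layer
#' (resolution applied there), then greedily relocates single nodes while
#' the signed modularity `Q+ - Q-` strictly improves. Deterministic for a
#' given seed.
#'
#' @param net `mb_network` or igraph graph.
#' @param resolution Leiden resolution for the positive layer
#'   (default 0.5).
#' @param seed RNG seed.
#' @param max_passes cap on refinement sweeps.
#' @return tibble with `node` and `community`; achieved signed modularity
#'   in `attr(, "modularity")`.
#' @export
detect_communities <- function(net, resolution = 0.5, seed = 1L, max_passes = 20) {
  g <- as_graph(net)
  n <- igraph::vcount(g)
  if (n == 0) return(tibble::tibble(node = character(0), community = integer(0)))
  w <- if (igraph::ecount(g)) igraph::E(g)$weight %||% rep(1, igraph::ecount(g)) else numeric(0)
  gp <- igraph::subgraph_from_edges(g, which(w > 0), delete.vertices = FALSE)
  memb <- if (igraph::ecount(gp) > 0) {
    wp <- igraph::E(gp)$weight %||% rep(1, igraph::ecount(gp))
    cl <- with_seed(seed, igraph::cluster_leiden(
      gp, objective_function = "modularity", resolution = resolution,
      weights = abs(wp), n_iterations = 5))
    igraph::membership(cl)
  } else seq_len(n)
  memb <- as.integer(memb)
  # Greedy single-node relocation on signed modularity Q+ - Q-, with O(deg)
  # per-layer Louvain deltas: moving v from a to b changes a layer's Q by
  # (k_vb - k_va')/m - gamma * d_v (d_b - d_a + d_v) / (2 m^2).
  el <- igraph::as_edgelist(g, names = FALSE)
  ew <- if (igraph::ecount(g)) igraph::E(g)$weight %||% rep(1, igraph::ecount(g)) else numeric(0)
  layers <- list(pos = list(sel = ew > 0, gamma = resolution),
                 neg = list(sel = ew < 0, gamma = 1))
  st <- lapply(layers, function(ly) {
    e <- el[ly$sel, , drop = FALSE]; w <- abs(ew[ly$sel])
    deg <- numeric(n)
    for (i in seq_len(nrow(e))) {
      deg[e[i, 1]] <- deg[e[i, 1]] + w[i]
      deg[e[i, 2]] <- deg[e[i, 2]] + w[i]
    }
    nb <- lapply(seq_len(n), function(i) integer(0))
    nw <- lapply(seq_len(n), function(i) numeric(0))
    for (i in seq_len(nrow(e))) {
      a <- e[i, 1]; b <- e[i, 2]
      nb[[a]] <- c(nb[[a]], b); nw[[a]] <- c(nw[[a]], w[i])
      nb[[b]] <- c(nb[[b]], a); nw[[b]] <- c(nw[[b]], w[i])
    }
    list(m = sum(w), deg = deg, nb = nb, nw = nw, gamma = ly$gamma)
  })
  comm_deg <- lapply(st, function(s) {
    cd <- numeric(max(memb) + n)
    for (v in seq_len(n)) cd[memb[v]] <- cd[memb[v]] + s$deg[v]
    cd
  })
  sgn <- c(pos = 1, neg = -1)
  delta_move <- function(v, a, b) {
    total <- 0
    for (lname in names(st)) {
      s <- st[[lname]]
      if (s$m == 0) next
      kva <- 0; kvb <- 0
      nbs <- s$nb[[v]]; nws <- s$nw[[v]]
      for (i in seq_along(nbs)) {
        cc <- memb[nbs[i]]
        if (cc == a && nbs[i] != v) kva <- kva + nws[i]
        if (cc == b) kvb <- kvb + nws[i]
      }
      dv <- s$deg[v]
      da <- comm_deg[[lname]][a] - dv
      db <- comm_deg[[lname]][b]
      dq <- (kvb - kva) / s$m - s$gamma * dv * (db - da) / (2 * s$m^2)
      total <- total + sgn[[lname]] * dq
    }
    total
  }
  next_comm <- max(memb) + 1L
  for (pass in seq_len(max_passes)) {
    moved <- FALSE
    for (v in seq_len(n)) {
      a <- memb[v]
      cand <- unique(c(memb[c(st$pos$nb[[v]], st$neg$nb[[v]])], next_comm))
      cand <- setdiff(cand, a)
      best_d <- 1e-12; best_c <- a
      for (cc in cand) {
        d <- delta_move(v, a, cc)
        if (d > best_d) { best_d <- d; best_c <- cc }
      }
      if (best_c != a) {
        memb[v] <- best_c
        for (lname in names(st)) {
          dv <- st[[lname]]$deg[v]
          comm_deg[[lname]][a] <- comm_deg[[lname]][a] - dv
          comm_deg[[lname]][best_c] <- comm_deg[[lname]][best_c] + dv
        }
        if (best_c == next_comm) {
          next_comm <- next_comm + 1L
          for (lname in names(st))
            if (length(comm_deg[[lname]]) < next_comm)
              comm_deg[[lname]][next_comm] <- 0
        }
        moved <- TRUE
      }
    }
    if (!moved) break
  }
  q <- signed_modularity(g, memb, resolution)
  memb <- as.integer(factor(memb))   # compact labels
  out <- tibble::tibble(node = igraph::V(g)$name %||% as.character(seq_len(n)),
                        community = memb)
  attr(out, "modularity") <- q
  out
}

#' Keystone taxa by combined z-scored centrality
#'
#' Z-scores degree, betweenness, closeness and eigen-centrality across
#' nodes (a zero-variance metric contributes zeros), sums them, and
#' returns the top `ceil(top_fraction * n)` nodes; ties at the cutoff are
#' all included and flagged.
#'
#' @param metrics node-metric tibble from [node_metrics()].
#' @param top_fraction keystone fraction (default 0.05).
#' @return `metrics` with z-score columns, `combined_score` and
#'   `is_keystone`; cutoff ties flagged in `attr(, "tie_flagged")`.
#' @export
keystone_taxa <- function(metrics, top_fraction = 0.05) {
  if (nrow(metrics) < 2) abort("need at least two nodes")
  zs <- function(v) {
    s <- stats::sd(v)
    # a numerically constant metric (e.g. on a vertex-transitive graph)
    # contributes zeros rather than amplified rounding noise
    if (is.na(s) || s <= 1e-8 * (max(abs(v)) + 1e-12)) rep(0, length(v))
    else (v - mean(v)) / s
  }
  out <- metrics |>
    dplyr::mutate(z_degree = zs(.data$degree),
                  z_betweenness = zs(.data$betweenness),
                  z_closeness = zs(.data$closeness),
                  z_eigen = zs(.data$eigen_centrality),
                  combined_score = .data$z_degree + .data$z_betweenness +
                    .data$z_closeness + .data$z_eigen)
  k <- ceiling(top_fraction * nrow(out))
  cutoff <- sort(out$combined_score, decreasing = TRUE)[k]
  out$is_keystone <- out$combined_score >= cutoff - 1e-12
  tie <- sum(out$is_keystone) > k
  out <- dplyr::arrange(out, dplyr::desc(.data$combined_score))
  attr(out, "tie_flagged") <- tie
  out
}

lcc_size <- function(g) {
  if (igraph::vcount(g) == 0) return(0L)
  max(igraph::components(g)$csize)
}

# LCC size after each prefix removal of `ord` (vertex indices), by adding
# vertices back in reverse with union-find; O((n + m) alpha) per order.
lcc_after_removals <- function(n, edges, ord) {
  parent <- integer(n); sz <- integer(n)
  root <- function(i) {
    while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }
    i
  }
  alive <- logical(n)
  inc <- lapply(seq_len(n), function(i) integer(0))
  if (nrow(edges)) {
    for (e in seq_len(nrow(edges))) {
      inc[[edges[e, 1]]] <- c(inc[[edges[e, 1]]], e)
      inc[[edges[e, 2]]] <- c(inc[[edges[e, 2]]], e)
    }
  }
  best <- 0L
  out <- integer(n + 1)   # out[k+1] = LCC size after removing first k of ord
  out[n + 1] <- 0L
  for (k in n:1) {
    v <- ord[k]
    alive[v] <- TRUE; parent[v] <- v; sz[v] <- 1L
    best <- max(best, 1L)
    for (e in inc[[v]]) {
      u <- edges[e, 1] + edges[e, 2] - v
      if (alive[u]) {
        ru <- root(u); rv <- root(v)
        if (ru != rv) {
          if (sz[ru] < sz[rv]) { tmp <- ru; ru <- rv; rv <- tmp }
          parent[rv] <- ru
          sz[ru] <- sz[ru] + sz[rv]
          if (sz[ru] > best) best <- sz[ru]
        }
      }
    }
    out[k] <- best
  }
  out
}

#' Attack-robustness curve with AUC and R50
#'
#' Runs on the largest connected component. Targeted mode removes, one
#' node at a time, the currently highest-betweenness node (recomputed
#' after each removal by default; `adaptive = FALSE` uses the initial
#' ranking). Random mode averages uniform removal orders over
#' `n_random_reps` seeds. The curve records the largest-connected-
#' component fraction (of the initial LCC) at removal fractions
#' `0, 1/n, ..., 1`; AUC is the trapezoidal integral and R50 the smallest
#' removal fraction at which the LCC fraction drops to 0.5 or below.
#'
#' @param net `mb_network` or igraph graph.
#' @param strategy `"targeted_betweenness"` or `"random"`.
#' @param n_random_reps replicates for random mode.
#' @param seed RNG seed (random mode).
#' @param adaptive recompute betweenness after each removal.
#' @param weighted use `1/|weight|` distances for betweenness.
#' @return a `robustness_curve`: list with `curve` tibble, `auc`, `r50`,
#'   `strategy`.
#' @export
robustness <- function(net, strategy = c("targeted_betweenness", "random"),
                       n_random_reps = 50, seed = 1L, adaptive = TRUE,
                       weighted = TRUE) {
  strategy <- match.arg(strategy)
  g0 <- as_graph(net)
  if (igraph::vcount(g0) == 0) abort("empty graph")
  cmp <- igraph::components(g0)
  g0 <- igraph::induced_subgraph(g0, which(cmp$membership == which.max(cmp$csize)))
  n0 <- igraph::vcount(g0)
  one_run <- function(order_fn) {
    g <- g0
    fr <- numeric(n0 + 1)
    fr[1] <- 1
    for (k in seq_len(n0)) {
      v <- order_fn(g, k)
      g <- igraph::delete_vertices(g, v)
      fr[k + 1] <- lcc_size(g) / n0
    }
    fr
  }
  if (strategy == "targeted_betweenness") {
    if (adaptive) {
      fr <- one_run(function(g, k) {
        bt <- igraph::betweenness(g, weights = edge_distances(g, weighted),
                                  directed = FALSE)
        nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
        nm[order(-bt, nm)[1]]   # deterministic tie-break by name
      })
    } else {
      bt <- igraph::betweenness(g0, weights = edge_distances(g0, weighted),
                                directed = FALSE)
      nm <- igraph::V(g0)$name %||% as.character(seq_len(n0))
      ord <- order(-bt, nm)
      edges <- igraph::as_edgelist(g0, names = FALSE)
      storage.mode(edges) <- "integer"
      fr <- lcc_after_removals(n0, edges, ord) / n0
    }
  } else {
    edges <- igraph::as_edgelist(g0, names = FALSE)
    storage.mode(edges) <- "integer"
    runs <- with_seed(seed, replicate(n_random_reps, sample.int(n0), simplify = FALSE))
    mat <- sapply(runs, function(ord) lcc_after_removals(n0, edges, ord) / n0)
    fr <- rowMeans(mat)
  }
  frac_removed <- seq(0, 1, length.out = n0 + 1)
  auc <- sum(diff(frac_removed) * (utils::head(fr, -1) + utils::tail(fr, -1)) / 2)
  below <- which(fr <= 0.5)
  r50 <- if (length(below)) frac_removed[min(below)] else 1
  structure(list(curve = tibble::tibble(fraction_removed = frac_removed,
                                        lcc_fraction = fr),
                 auc = auc, r50 = r50, strategy = strategy,
                 n_random_reps = if (strategy == "random") n_random_reps else NA_integer_,
                 seed = seed),
            class = "robustness_curve")
}

#' @export
print.robustness_curve <- function(x, ...) {
  cat("Robustness curve (", x$strategy, ")\n", sep = "")
  cat("  AUC:", signif(x$auc, 4), " R50:", signif(x$r50, 4), "\n")
  invisible(x)
}

#' Full network report
#'
#' Bundles pruning, community detection, global and node metrics,
#' keystone identification and the targeted-attack robustness curve.
#'
#' @param net `mb_network` or igraph graph.
#' @param resolution Leiden resolution (default 0.5).
#' @param top_fraction keystone fraction (default 0.05).
#' @param seed RNG seed.
#' @param with_random also compute the random-removal curve.
#' @param n_random_reps replicates for the random curve.
#' @return a `network_report` list.
#' @export
network_report <- function(net, resolution = 0.5, top_fraction = 0.05, seed = 1L,
                           with_random = TRUE, n_random_reps = 50) {
  g <- prune_network(net)
  if (igraph::vcount(g) == 0) {
    return(structure(list(global = global_metrics(g), nodes = tibble::tibble(),
                          communities = tibble::tibble(), keystones = tibble::tibble(),
                          robustness_targeted = NULL, robustness_random = NULL),
                     class = "network_report"))
  }
  comm <- detect_communities(g, resolution = resolution, seed = seed)
  nm <- node_metrics(g)
  ks <- if (nrow(nm) >= 2) keystone_taxa(nm, top_fraction) else nm
  structure(list(
    global = global_metrics(g, membership = comm$community, resolution = resolution),
    nodes = nm,
    communities = comm,
    keystones = ks,
    robustness_targeted = robustness(g, "targeted_betweenness", seed = seed),
    robustness_random = if (with_random)
      robustness(g, "random", n_random_reps = n_random_reps, seed = seed) else NULL),
    class = "network_report")
}

#' Write a network report to files
#'
#' Emits `<base>_global.json` (global metrics + provenance when the
#' source network is given), `<base>_nodes.tsv` (node metrics joined
#' with community and keystone assignments), `<base>_robustness.tsv`
#' (curve with an AUC/R50 summary header), and `<base>_viz.graphml`
#' (display graph: tiny components removed, community and keystone
#' vertex attributes attached).
#'
#' @param report a `network_report`.
#' @param base output path prefix.
#' @param net optional `mb_network` the report was computed from.
#' @return `base`, invisibly.
#' @export
write_network_report <- function(report, base, net = NULL) {
  glob <- as.list(report$global)
  if (!is.null(net) && inherits(net, "mb_network"))
    glob$provenance <- net$provenance[c("lambda_path", "lambda_star", "n_reps",
                                        "subsample_fraction", "beta", "seed", "flag")]
  jsonlite::write_json(glob, paste0(base, "_global.json"), auto_unbox = TRUE)
  nodes <- report$nodes
  if (nrow(nodes)) {
    nodes <- dplyr::left_join(nodes, report$communities, by = "node")
    if ("is_keystone" %in% names(report$keystones))
      nodes <- dplyr::left_join(
        nodes, report$keystones[, c("node", "combined_score", "is_keystone")],
        by = "node")
    utils::write.table(nodes, paste0(base, "_nodes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$robustness_targeted)) {
    rb <- report$robustness_targeted
    con <- file(paste0(base, "_robustness.tsv"), "w")
    writeLines(sprintf("# strategy=%s AUC=%.6f R50=%.6f", rb$strategy, rb$auc, rb$r50), con)
    utils::write.table(rb$curve, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  if (!is.null(net)) {
    g <- prune_network(net, for_visualization = TRUE)
    if (igraph::vcount(g) > 0 && nrow(report$communities)) {
      idx <- match(igraph::V(g)$name, report$communities$node)
      igraph::V(g)$community <- report$communities$community[idx]
      if ("is_keystone" %in% names(report$keystones)) {
        ki <- match(igraph::V(g)$name, report$keystones$node)
        igraph::V(g)$keystone <- report$keystones$is_keystone[ki]
        igraph::V(g)$keystone_score <- report$keystones$combined_score[ki]
      }
    }
    igraph::write_graph(g, paste0(base, "_viz.graphml"), format = "graphml")
  }
  invisible(base)
}

#' @export
print.network_report <- function(x, ...) {
  cat("Network report\n")
  print(x$global)
  if (!is.null(x$robustness_targeted))
    cat("targeted attack: AUC", signif(x$robustness_targeted$auc, 3),
        " R50", signif(x$robustness_targeted$r50, 3), "\n")
  ksn <- if (nrow(x$keystones) && "is_keystone" %in% names(x$keystones))
    x$keystones$node[x$keystones$is_keystone] else character(0)
  if (length(ksn)) cat("keystones:", paste(ksn, collapse = ", "), "\n")
  invisible(x)
}
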