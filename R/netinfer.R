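# Sparse signed association-network inference: graphical lasso on the
# covariance of CLR-transformed abundances, with StARS stability selection
# of the regularization parameter (repeated 80% subsampling).

#' Graphical lasso precision estimate
#'
#' Maximizes `log det(Theta) - tr(S Theta) - lambda * ||Theta||_1` by
#' block coordinate descent (the classical formulation, which penalizes
#' the diagonal as well — equivalent sparsity pattern, and the ridge-like
#' diagonal term stabilizes rank-deficient covariances from small
#' samples). Convergence is assessed on the working covariance; the
#' returned duality gap measures remaining suboptimality.
#'
#' @param S symmetric covariance matrix.
#' @param lambda l1 penalty (>= 0).
#' @param tol convergence tolerance (default 1e-4).
#' @param max_iter sweep cap.
#' @param warm optional warm start (a previous `glasso` result).
#' @return list with `theta`, `w`, `gap`, `iterations`, `converged`.
#' @export
glasso <- function(S, lambda, tol = 1e-4, max_iter = 500, warm = NULL) {
  if (lambda < 0) abort("lambda must be non-negative")
  S <- as.matrix(S)
  if (!isSymmetric(unname(S), tol = 1e-8)) abort("S must be symmetric")
  fit <- glasso_cpp(unname(S), lambda, tol, max_iter,
                    if (is.null(warm)) NULL else warm$w,
                    if (is.null(warm)) NULL else warm$beta)
  if (!fit$converged)
    abort(paste0("glasso did not converge (duality gap ", signif(fit$gap, 4), ")"))
  dimnames(fit$theta) <- dimnames(S)
  fit
}

#' Default log-spaced lambda path
#'
#' 30 values log-spaced from `lambda_max = max |S_offdiag|` down to
#' `lambda_max * min_ratio`.
#'
#' @param S covariance matrix.
#' @param n_lambda path length.
#' @param min_ratio smallest/largest lambda ratio.
#' @return decreasing numeric vector.
#' @export
lambda_path <- function(S, n_lambda = 30, min_ratio = 0.01) {
  off <- abs(S); diag(off) <- 0
  lmax <- max(off, 1e-6)
  exp(seq(log(lmax), log(lmax * min_ratio), length.out = n_lambda))
}

#' StARS stability selection of the glasso penalty
#'
#' Fits the glasso on repeated subsamples (default 80% of samples, 50
#' repetitions) along a decreasing lambda path. Per lambda, the edge
#' instability is the mean over node pairs of `2 theta (1 - theta)` where
#' `theta` is the edge selection frequency; the path statistic is
#' monotonized (running max from the sparse end) and the selected
#' `lambda*` is the smallest lambda whose monotonized instability stays
#' at or below `beta`. Because the monotonized statistic cannot decrease,
#' fitting stops at the first lambda that exceeds `beta`.
#'
#' @param x CLR-transformed data matrix (samples x taxa) or count tibble
#'   of CLR values.
#' @param lambdas decreasing lambda path (`NULL` = [lambda_path()] of the
#'   full-data covariance).
#' @param subsample_fraction fraction of samples per subsample.
#' @param n_reps number of subsamples (>= 2).
#' @param beta instability threshold (StARS default 0.05).
#' @param seed RNG seed for the subsample draws.
#' @param fit_tol convergence tolerance for the subsample glasso fits;
#'   looser than the final fit since only edge sets are consumed.
#' @return list with `lambda_star`, `lambdas` (evaluated portion),
#'   `instability`, `monotonized`, `stability` (edge selection-frequency
#'   matrix at `lambda_star`), and `flag` ("ok" or "no_lambda_met_beta").
#' @export
stars_select <- function(x, lambdas = NULL, subsample_fraction = 0.8,
                         n_reps = 50, beta = 0.05, seed = 1L, fit_tol = 1e-3) {
  if (is.data.frame(x)) x <- count_matrix(x)
  stopifnot(n_reps >= 2, subsample_fraction > 0, subsample_fraction <= 1)
  n <- nrow(x); p <- ncol(x)
  if (is.null(lambdas)) lambdas <- lambda_path(stats::cov(x))
  if (is.unsorted(rev(lambdas))) abort("lambda path must be decreasing")
  b <- max(2L, floor(subsample_fraction * n))
  subs <- with_seed(seed, replicate(n_reps, sample.int(n, b), simplify = FALSE))
  # duplicate subsamples (common at small n) give identical fits: cache them
  keys <- vapply(subs, function(i) paste(sort(i), collapse = ","), character(1))
  uniq <- !duplicated(keys)
  rep_of <- match(keys, keys[uniq])
  covs <- purrr::map(subs[uniq], ~stats::cov(x[.x, , drop = FALSE]))
  n_uniq <- sum(uniq)
  warms <- vector("list", n_uniq)
  n_pairs <- p * (p - 1) / 2
  instab <- rep(NA_real_, length(lambdas))
  mono <- rep(NA_real_, length(lambdas))
  freq_at <- vector("list", length(lambdas))
  running <- 0
  evaluated <- 0
  for (li in seq_along(lambdas)) {
    freq <- matrix(0, p, p)
    mult <- tabulate(rep_of, n_uniq)
    for (r in seq_len(n_uniq)) {
      fit <- glasso(covs[[r]], lambdas[li], tol = fit_tol, warm = warms[[r]])
      warms[[r]] <- fit
      adj <- (abs(fit$theta) > 1e-8) * mult[r]
      diag(adj) <- 0
      freq <- freq + adj
    }
    freq <- freq / n_reps
    instab[li] <- sum(2 * freq * (1 - freq)) / 2 / n_pairs
    running <- max(running, instab[li])
    mono[li] <- running
    freq_at[[li]] <- freq
    evaluated <- li
    if (running > beta) break   # monotonized instability cannot recover
  }
  ok <- which(mono[seq_len(evaluated)] <= beta)
  if (length(ok)) {
    sel <- max(ok)   # smallest lambda (densest graph) meeting beta
    flag <- "ok"
  } else {
    sel <- 1L
    flag <- "no_lambda_met_beta"
  }
  stab <- freq_at[[sel]]
  dimnames(stab) <- list(colnames(x), colnames(x))
  list(lambda_star = lambdas[sel], lambdas = lambdas[seq_len(evaluated)],
       instability = instab[seq_len(evaluated)],
       monotonized = mono[seq_len(evaluated)],
       stability = stab, subsample_fraction = subsample_fraction,
       n_reps = n_reps, beta = beta, seed = seed, flag = flag)
}

#' Infer a signed association network from count tables
#'
#' Pipeline: prevalence filter (default 20%) per table, CLR transform
#' (pseudocount 1), column-concatenate kingdoms over shared samples,
#' covariance, StARS-selected graphical lasso, and extraction of signed
#' edges weighted by partial correlation
#' `rho_ij = -theta_ij / sqrt(theta_ii * theta_jj)`.
#'
#' @param tables a count tibble or named list of count tibbles (names are
#'   kingdom tags, e.g. `list(bacterial = ..., fungal = ...)`); multiple
#'   tables must share an identical sample set.
#' @param prevalence minimum presence fraction per taxon (default 0.20).
#' @param pseudocount CLR pseudocount (default 1).
#' @param lambdas optional explicit lambda path.
#' @inheritParams stars_select
#' @return an `mb_network`: igraph graph plus inference provenance.
#' @export
infer_network <- function(tables, prevalence = 0.20, pseudocount = 1,
                          lambdas = NULL, subsample_fraction = 0.8,
                          n_reps = 50, beta = 0.05, seed = 1L) {
  if (is.data.frame(tables)) tables <- list(all = tables)
  if (is.null(names(tables))) names(tables) <- paste0("kingdom", seq_along(tables))
  ids <- tables[[1]]$sample_id
  for (k in seq_along(tables)) {
    if (!identical(sort(tables[[k]]$sample_id), sort(ids)))
      abort(paste0("sample mismatch between tables: ",
                   paste(utils::head(c(setdiff(ids, tables[[k]]$sample_id),
                                       setdiff(tables[[k]]$sample_id, ids)), 5),
                         collapse = ", ")))
    tables[[k]] <- tables[[k]][match(ids, tables[[k]]$sample_id), ]
  }
  clrs <- purrr::imap(tables, function(tb, kg) {
    filt <- prevalence_filter(tb, prevalence)
    m <- count_matrix(clr_transform(filt, pseudocount))
    attr(m, "kingdom") <- kg
    m
  })
  kingdom <- unlist(purrr::imap(clrs, ~rep(.y, ncol(.x))))
  x <- do.call(cbind, unname(clrs))
  if (anyDuplicated(colnames(x)))
    colnames(x) <- make.unique(colnames(x))
  sel <- stars_select(x, lambdas = lambdas,
                      subsample_fraction = subsample_fraction,
                      n_reps = n_reps, beta = beta, seed = seed)
  fit <- glasso(stats::cov(x), sel$lambda_star)
  theta <- fit$theta
  pcor <- -theta / sqrt(diag(theta) %o% diag(theta))
  diag(pcor) <- 0
  pcor[abs(theta) <= 1e-8] <- 0
  g <- igraph::graph_from_adjacency_matrix(pcor, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  igraph::V(g)$kingdom <- kingdom[match(igraph::V(g)$name, colnames(x))]
  igraph::V(g)$genus <- igraph::V(g)$name
  if (igraph::ecount(g) > 0)
    igraph::E(g)$sign <- ifelse(igraph::E(g)$weight > 0, "+", "-")
  structure(list(graph = g,
                 provenance = list(lambda_path = sel$lambdas,
                                   lambda_star = sel$lambda_star,
                                   instability = sel$instability,
                                   stability = sel$stability,
                                   subsample_fraction = subsample_fraction,
                                   n_reps = n_reps, beta = beta, seed = seed,
                                   flag = sel$flag, duality_gap = fit$gap),
                 theta = theta),
            class = "mb_network")
}

#' @export
print.mb_network <- function(x, ...) {
  g <- x$graph
  cat("Signed association network\n")
  cat("  nodes:", igraph::vcount(g), " edges:", igraph::ecount(g))
  if (igraph::ecount(g) > 0)
    cat(" (", sum(igraph::E(g)$weight > 0), "positive,",
        sum(igraph::E(g)$weight < 0), "negative )")
  cat("\n  lambda*:", signif(x$provenance$lambda_star, 4),
      " StARS flag:", x$provenance$flag, "\n")
  invisible(x)
}

#' Export a network as a GraphML file
#' @param net an `mb_network` or igraph graph.
#' @param path output path.
#' @export
write_network_graphml <- function(net, path) {
  g <- if (inherits(net, "mb_network")) net$graph else net
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Export a network edge list as TSV (source, target, weight, sign)
#' @param net an `mb_network` or igraph graph.
#' @param path output path.
#' @export
write_edge_list <- function(net, path) {
  g <- if (inherits(net, "mb_network")) net$graph else net
  el <- igraph::as_edgelist(g)
  df <- data.frame(source = el[, 1], target = el[, 2],
                   weight = if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0),
                   sign = if (igraph::ecount(g)) igraph::E(g)$sign else character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
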