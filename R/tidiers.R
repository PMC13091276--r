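# broom-style tidiers and ggplot2 autoplot methods for fitted objects.

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_segment
#'   geom_boxplot facet_wrap labs theme_minimal scale_colour_manual
#' @export
ggplot2::autoplot

#' @rdname fit_dmm
#' @param x a `dmm_fit`.
#' @param ... unused.
#' @export
tidy.dmm_fit <- function(x, ...) {
  purrr::map_dfr(seq_len(x$k), function(j)
    tibble::tibble(component = j, genus = x$genera,
                   alpha = x$alpha[, j],
                   mean_proportion = x$alpha[, j] / sum(x$alpha[, j]),
                   weight = x$weights[j]))
}

#' @rdname fit_dmm
#' @export
glance.dmm_fit <- function(x, ...) {
  tibble::tibble(k = x$k, n = x$n, loglik = x$loglik,
                 bic = unname(x$scores["bic"]), aic = unname(x$scores["aic"]),
                 laplace = unname(x$scores["laplace"]),
                 n_parameters = x$n_parameters, converged = x$converged)
}

#' @rdname select_k
#' @param x a `dmm_selection`.
#' @param ... unused.
#' @export
tidy.dmm_selection <- function(x, ...) x$scores

#' @rdname select_k
#' @export
glance.dmm_selection <- function(x, ...) {
  tibble::tibble(best_bic = unname(x$best["bic"]),
                 best_aic = unname(x$best["aic"]),
                 best_laplace = unname(x$best["laplace"]))
}

#' @rdname select_k
#' @param object a `dmm_selection`.
#' @export
autoplot.dmm_selection <- function(object, ...) {
  long <- tidyr::pivot_longer(object$scores, c("bic", "aic", "laplace"),
                              names_to = "criterion", values_to = "score")
  ggplot(long, aes(x = .data$k, y = .data$score, colour = .data$criterion)) +
    geom_line() + geom_point() +
    labs(x = "components (K)", y = "information criterion",
         title = "DMM model selection") +
    theme_minimal()
}

#' @rdname infer_network
#' @param x an `mb_network`.
#' @param ... unused.
#' @export
tidy.mb_network <- function(x, ...) {
  g <- x$graph
  if (igraph::ecount(g) == 0)
    return(tibble::tibble(from = character(0), to = character(0),
                          weight = numeric(0), sign = character(0)))
  el <- igraph::as_edgelist(g)
  tibble::tibble(from = el[, 1], to = el[, 2],
                 weight = igraph::E(g)$weight, sign = igraph::E(g)$sign)
}

#' @rdname infer_network
#' @export
glance.mb_network <- function(x, ...) {
  g <- x$graph
  w <- if (igraph::ecount(g)) igraph::E(g)$weight else numeric(0)
  tibble::tibble(n_nodes = igraph::vcount(g), n_edges = igraph::ecount(g),
                 n_positive = sum(w > 0), n_negative = sum(w < 0),
                 lambda_star = x$provenance$lambda_star,
                 stars_flag = x$provenance$flag)
}

#' @rdname infer_network
#' @param object an `mb_network`.
#' @param layout_seed seed for the force-directed layout.
#' @export
autoplot.mb_network <- function(object, layout_seed = 1L, ...) {
  g <- object$graph
  xy <- with_seed(layout_seed, igraph::layout_with_fr(g))
  nodes <- tibble::tibble(name = igraph::V(g)$name, x = xy[, 1], y = xy[, 2],
                          kingdom = igraph::V(g)$kingdom %||% "all")
  p <- ggplot(nodes, aes(x = .data$x, y = .data$y))
  if (igraph::ecount(g) > 0) {
    el <- igraph::as_edgelist(g)
    edges <- tibble::tibble(
      x = nodes$x[match(el[, 1], nodes$name)],
      y = nodes$y[match(el[, 1], nodes$name)],
      xend = nodes$x[match(el[, 2], nodes$name)],
      yend = nodes$y[match(el[, 2], nodes$name)],
      sign = igraph::E(g)$sign)
    p <- p + geom_segment(data = edges,
                          aes(x = .data$x, y = .data$y, xend = .data$xend,
                              yend = .data$yend, colour = .data$sign),
                          linewidth = 0.3, alpha = 0.7) +
      scale_colour_manual(values = c("+" = "#e83e8c", "-" = "#007bff"))
  }
  p + geom_point(aes(shape = .data$kingdom), size = 1.5) +
    labs(title = "Signed association network") +
    ggplot2::theme_void()
}

#' @rdname robustness
#' @param x a `robustness_curve`.
#' @param ... unused.
#' @export
tidy.robustness_curve <- function(x, ...) x$curve

#' @rdname robustness
#' @export
glance.robustness_curve <- function(x, ...) {
  tibble::tibble(strategy = x$strategy, auc = x$auc, r50 = x$r50)
}

#' @rdname robustness
#' @param object a `robustness_curve`.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$fraction_removed, y = .data$lcc_fraction)) +
    geom_line() +
    labs(x = "fraction of nodes removed", y = "LCC fraction",
         subtitle = sprintf("AUC = %.3f, R50 = %.3f (%s)",
                            object$auc, object$r50, object$strategy)) +
    theme_minimal()
}

#' Boxplots of alpha diversity by a metadata factor
#'
#' @param alpha output of [alpha_diversity()].
#' @param metadata sample metadata tibble.
#' @param by metadata column (default `"group"`).
#' @return a ggplot.
#' @export
plot_alpha_diversity <- function(alpha, metadata, by = "group") {
  merged <- dplyr::inner_join(alpha, metadata, by = "sample_id")
  long <- tidyr::pivot_longer(merged, c("richness", "shannon", "pielou"),
                              names_to = "metric", values_to = "value")
  ggplot(long, aes(x = .data[[by]], y = .data$value)) +
    geom_boxplot() +
    facet_wrap(~metric, scales = "free_y") +
    theme_minimal()
}
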