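# Alpha diversity, beta-diversity distances, PERMANOVA variance
# partitioning (sequential and marginal), pairwise comparisons with BH
# correction, and simple continuous correlations.

#' Per-sample alpha diversity
#'
#' Richness is the number of taxa with nonzero counts; Shannon uses the
#' natural log with the 0 log 0 := 0 convention; Pielou's evenness is
#' Shannon / ln(richness), defined as 0 when richness is 1.
#'
#' @param counts count tibble; all sample totals must be positive.
#' @return tibble with `sample_id`, `richness`, `shannon`, `pielou`.
#' @export
alpha_diversity <- function(counts) {
  check_counts(counts)
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0)) abort(paste0("empty sample: ", rownames(m)[tot == 0][1]))
  richness <- rowSums(m > 0)
  shannon <- vegan::diversity(m, index = "shannon")
  pielou <- ifelse(richness > 1, shannon / log(richness), 0)
  tibble::tibble(sample_id = rownames(m), richness = as.integer(richness),
                 shannon = unname(shannon), pielou = unname(pielou))
}

#' Beta-diversity distance matrix
#'
#' Bray-Curtis on counts (`sum|x-y| / sum(x+y)`) or Jaccard on
#' presence/absence (`1 - |intersection| / |union|`). Pairs of all-zero
#' samples get distance 0 with a warning.
#'
#' @param counts count tibble (>= 2 samples).
#' @param metric `"bray_curtis"` or `"jaccard"`.
#' @return a `dist` object with a `"metric"` attribute.
#' @export
beta_distance <- function(counts, metric = c("bray_curtis", "jaccard")) {
  metric <- match.arg(metric)
  check_counts(counts)
  m <- count_matrix(counts)
  if (nrow(m) < 2) abort("at least two samples are required")
  d <- if (metric == "bray_curtis") {
    vegan::vegdist(m, method = "bray")
  } else {
    vegan::vegdist(m, method = "jaccard", binary = TRUE)
  }
  if (anyNA(d)) {
    warn("all-zero sample pair(s): distance set to 0")
    d[is.na(d)] <- 0
  }
  attr(d, "metric") <- metric
  d
}

#' Write a distance matrix as square TSV
#' @param d `dist` object.
#' @param path output path.
#' @export
write_distance_matrix <- function(d, path) {
  m <- as.matrix(d)
  utils::write.table(data.frame(sample_id = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

align_meta <- function(d, metadata) {
  labs <- attr(d, "Labels") %||% labels(d)
  if (is.null(labs)) abort("distance matrix carries no sample labels")
  if (!all(labs %in% metadata$sample_id))
    abort(paste0("metadata missing sample: ", setdiff(labs, metadata$sample_id)[1]))
  metadata[match(labs, metadata$sample_id), , drop = FALSE]
}

#' PERMANOVA variance partitioning on a distance matrix
#'
#' Distance-based multivariate ANOVA with permutation p-values; reports
#' per-term R^2 (SS_term / SS_total). Without covariates the partition is
#' sequential and term + residual R^2 sum to 1. With covariates the focal
#' term is tested marginally (conditional on the covariates), mirroring
#' "adjusting for group" style analyses.
#'
#' @param d `dist` object from [beta_distance()].
#' @param metadata sample metadata tibble covering the distance labels.
#' @param term name of the focal metadata column.
#' @param covariates optional character vector of adjustment columns.
#' @param n_perm number of permutations (>= 99).
#' @param seed RNG seed for the permutation stream.
#' @return tibble with term/df/SS/R2/F/p plus provenance columns.
#' @export
permanova <- function(d, metadata, term, covariates = NULL, n_perm = 999, seed = 1L) {
  stopifnot(n_perm >= 99)
  meta <- align_meta(d, metadata)
  f <- meta[[term]]
  if (length(unique(f[!is.na(f)])) < 2)
    abort("no between-group df: factor has a single level")
  rhs <- paste(c(covariates, term), collapse = " + ")
  form <- stats::as.formula(paste("d ~", rhs))
  by_mode <- if (is.null(covariates)) "terms" else "margin"
  dat <- as.data.frame(meta)
  res <- with_seed(seed,
    vegan::adonis2(form, data = dat, permutations = n_perm, by = by_mode))
  tibble::tibble(term = rownames(res), df = res$Df, SS = res$SumOfSqs,
                 R2 = res$R2, F = res$F, p = res$`Pr(>F)`,
                 focal = rownames(res) == term, n_perm = n_perm, seed = seed,
                 adjustment = if (is.null(covariates)) "none"
                              else paste("marginal |", paste(covariates, collapse = "+")))
}

#' Pairwise PERMANOVA between factor levels with BH correction
#'
#' One test per unordered level pair on the corresponding sub-matrix;
#' p-values are BH-adjusted across the pairs.
#'
#' @inheritParams permanova
#' @return tibble with one row per level pair.
#' @export
pairwise_permanova <- function(d, metadata, term, n_perm = 999, seed = 1L) {
  meta <- align_meta(d, metadata)
  lv <- sort(unique(as.character(meta[[term]])))
  if (length(lv) < 2) abort("need at least two factor levels")
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  dm <- as.matrix(d)
  rows <- purrr::imap(pairs, function(pr, k) {
    sel <- meta[[term]] %in% pr
    sub <- stats::as.dist(dm[sel, sel, drop = FALSE])
    res <- permanova(sub, meta[sel, , drop = FALSE], term,
                     n_perm = n_perm, seed = seed + k)
    r <- res[res$term == term, ]
    tibble::tibble(level1 = pr[1], level2 = pr[2], df = r$df, SS = r$SS,
                   R2 = r$R2, F = r$F, p = r$p)
  })
  out <- dplyr::bind_rows(rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out
}

#' Continuous association by Pearson or Spearman correlation
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @param method `"pearson"` or `"spearman"`.
#' @return tibble with `estimate`, `p`, `method`, `n`.
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (length(x) != length(y) || length(x) < 3) abort("need equal lengths >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) abort("zero variance input")
  ct <- suppressWarnings(stats::cor.test(x, y, method = method))
  tibble::tibble(estimate = unname(ct$estimate), p = ct$p.value,
                 method = method, n = length(x))
}
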