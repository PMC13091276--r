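# Differential-abundance screening: Wilcoxon rank-sum with BH correction,
# prevalence filtering, covariate stratification (age tertiles), and the
# Basidiomycota/Ascomycota fungal dysbiosis ratio.

#' Wilcoxon rank-sum test
#'
#' Exact enumeration p-value when the combined sample size is at most 20
#' and there are no ties; otherwise the normal approximation with tie
#' correction (and continuity correction). Identical values across both
#' groups give p = 1.
#'
#' @param x,y non-empty numeric vectors.
#' @return tibble with `statistic`, `p`, `method`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) abort("both samples must be non-empty")
  if (length(unique(c(x, y))) == 1)
    return(tibble::tibble(statistic = length(x) * length(y) / 2, p = 1,
                          method = "degenerate"))
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y)) <= 20 && !ties
  wt <- suppressWarnings(stats::wilcox.test(x, y, exact = exact, correct = TRUE))
  tibble::tibble(statistic = unname(wt$statistic), p = wt$p.value,
                 method = if (exact) "exact" else "normal_approx_tie_corrected")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in `[0, 1]`.
#' @return adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) abort("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Empirical age tertiles
#'
#' Rank-based tertiles with ties assigned to the lower tertile.
#'
#' @param age numeric vector.
#' @return integer tertile (1-3) per element.
#' @export
age_tertiles <- function(age) {
  n <- length(age)
  r <- rank(age, ties.method = "min")
  1L + (r > ceiling(n / 3)) + (r > ceiling(2 * n / 3))
}

#' Differential-abundance screen
#'
#' Prevalence-filters taxa (default: present in >= 10% of samples),
#' converts to relative abundances, and runs pairwise Wilcoxon rank-sum
#' tests between grouping levels within each stratum. BH correction is
#' applied within each (comparison, stratum) family. Continuous strata
#' named `"age"` are converted to empirical tertiles. Comparisons with
#' fewer than 3 samples per group are skipped with a reason.
#'
#' @param counts count tibble.
#' @param metadata sample metadata tibble.
#' @param grouping metadata column defining the groups.
#' @param strata optional metadata column to stratify by (`"age"` uses
#'   tertiles).
#' @param prevalence minimum presence fraction (default 0.10).
#' @return tibble with genus, stratum, level pair, statistic, p, p_adj
#'   and direction (log-fold of mean relative abundance).
#' @export
da_screen <- function(counts, metadata, grouping = "group", strata = NULL,
                      prevalence = 0.10) {
  counts <- counts[order(counts$sample_id), ]
  filt <- prevalence_filter(counts, prevalence)
  rel <- relative_abundance(filt)
  meta <- metadata[match(rel$sample_id, metadata$sample_id), ]
  grp <- as.character(meta[[grouping]])
  strat <- if (is.null(strata)) {
    rep("all", nrow(rel))
  } else if (strata == "age") {
    paste0("age_T", age_tertiles(meta$age))
  } else {
    as.character(meta[[strata]])
  }
  m <- count_matrix(rel)
  taxa <- sort(colnames(m))
  skipped <- list()
  rows <- list()
  for (s in sort(unique(strat))) {
    in_s <- strat == s
    lv <- sort(unique(grp[in_s]))
    if (length(lv) < 2) next
    for (pr in utils::combn(lv, 2, simplify = FALSE)) {
      i1 <- in_s & grp == pr[1]; i2 <- in_s & grp == pr[2]
      if (sum(i1) < 3 || sum(i2) < 3) {
        skipped[[length(skipped) + 1]] <-
          paste0(s, ":", pr[1], " vs ", pr[2], " (<3 samples per group)")
        next
      }
      res <- purrr::map(taxa, function(tx) {
        wt <- wilcoxon_rank_sum(m[i1, tx], m[i2, tx])
        eps <- 1e-8
        tibble::tibble(genus = tx, stratum = s, level1 = pr[1], level2 = pr[2],
                       statistic = wt$statistic, p = wt$p,
                       direction = log((mean(m[i1, tx]) + eps) /
                                         (mean(m[i2, tx]) + eps)))
      })
      fam <- dplyr::bind_rows(res)
      fam$p_adj <- bh_adjust(fam$p)
      rows[[length(rows) + 1]] <- fam
    }
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(genus = character(0), stratum = character(0),
                   level1 = character(0), level2 = character(0),
                   statistic = numeric(0), p = numeric(0),
                   direction = numeric(0), p_adj = numeric(0))
  attr(out, "skipped") <- unlist(skipped)
  out
}

#' Record externally computed differential-abundance results
#'
#' Hook for results produced by a bias-corrected external method (e.g.
#' ANCOM-BC2 run outside this package): validates the minimal column set
#' and tags the rows with their source so they can sit alongside
#' [da_screen()] output in reports.
#'
#' @param results data frame with at least `genus`, `level1`, `level2`,
#'   `p_adj`.
#' @param source label for the external tool.
#' @return tibble with a `source` column appended.
#' @export
attach_external_da <- function(results, source = "ANCOM-BC2") {
  need <- c("genus", "level1", "level2", "p_adj")
  if (!all(need %in% names(results)))
    abort(paste0("external results must contain: ", paste(need, collapse = ", ")))
  dplyr::mutate(tibble::as_tibble(results), source = source)
}

#' Basidiomycota/Ascomycota dysbiosis ratio
#'
#' Per-sample fungal phylum count ratio with a natural-log transform.
#' Samples with zero Ascomycota counts get a +0.5 continuity correction
#' on both phyla and are flagged; samples with zero counts in both phyla
#' are undefined (NA, flagged).
#'
#' @param counts fungal count tibble.
#' @param taxonomy taxonomy tibble with `phylum`.
#' @return tibble with per-sample counts, `ratio`, `log_ratio`, `flag`.
#' @export
ba_ratio <- function(counts, taxonomy) {
  phy <- aggregate_by_rank(counts, taxonomy, "phylum")
  get <- function(name) {
    if (name %in% taxa_names(phy)) phy[[name]] else rep(0, nrow(phy))
  }
  B <- get("Basidiomycota"); A <- get("Ascomycota")
  if (all(B == 0) && all(A == 0)) warn("neither fungal phylum present")
  flag <- dplyr::case_when(B == 0 & A == 0 ~ "undefined",
                           A == 0 ~ "continuity_corrected",
                           TRUE ~ "")
  ratio <- dplyr::case_when(B == 0 & A == 0 ~ NA_real_,
                            A == 0 ~ (B + 0.5) / 0.5,
                            TRUE ~ B / A)
  tibble::tibble(sample_id = phy$sample_id, basidiomycota = B, ascomycota = A,
                 ratio = ratio, log_ratio = log(ratio), flag = flag)
}
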