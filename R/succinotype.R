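# Succinotype classification: D-type / P-type / mixed / unclassified from
# the Dialister : Phascolarctobacterium read ratio, plus Fisher's-exact
# association testing against host categories.

#' Classify succinotype from succinate-utilizer read counts
#'
#' With `rD = nD / (nD + nP)`: unclassified if `nD + nP < min_reads`;
#' D-type if `rD > hi`; P-type if `rD < lo`; otherwise mixed. All
#' inequalities are strict, so `rD` exactly at a boundary is mixed.
#'
#' @param nD,nP non-negative integer read counts of Dialister and
#'   Phascolarctobacterium (vectorised).
#' @param hi,lo dominance thresholds (defaults 0.9 / 0.1).
#' @param min_reads minimum combined reads for classification (default 10).
#' @return character vector in `{"D","P","mixed","unclassified"}`.
#' @export
classify_succinotype <- function(nD, nP, hi = 0.9, lo = 0.1, min_reads = 10) {
  if (any(nD < 0) || any(nP < 0)) abort("read counts must be non-negative")
  total <- nD + nP
  rD <- ifelse(total > 0, nD / total, NA_real_)
  dplyr::case_when(
    total < min_reads ~ "unclassified",
    rD > hi ~ "D",
    rD < lo ~ "P",
    TRUE ~ "mixed")
}

#' Succinotype calls for a cohort
#'
#' Aggregates ASV counts per genus (exact genus-string matching with an
#' optional alias map), then classifies each sample. When a
#' `subject_map` (sample_id -> subject) is supplied, one call is retained
#' per subject, prioritising clear classifications (D or P) over mixed,
#' and mixed over unclassified.
#'
#' @param counts count tibble (ASV- or genus-level).
#' @param taxonomy taxonomy tibble with `taxon_id` and `genus`.
#' @param dialister_name,phasco_name genus strings to match.
#' @param aliases optional named character vector mapping variant genus
#'   spellings to canonical ones.
#' @param subject_map optional tibble with `sample_id` and `subject`.
#' @inheritParams classify_succinotype
#' @return tibble with `sample_id`, `nD`, `nP`, `rD`, `label`.
#' @export
classify_cohort <- function(counts, taxonomy,
                            dialister_name = "Dialister",
                            phasco_name = "Phascolarctobacterium",
                            aliases = NULL, subject_map = NULL,
                            hi = 0.9, lo = 0.1, min_reads = 10) {
  gen <- aggregate_by_rank(counts, taxonomy, "genus")
  nm <- taxa_names(gen)
  if (!is.null(aliases)) nm <- ifelse(nm %in% names(aliases), aliases[nm], nm)
  pick <- function(target) {
    hit <- which(nm == target)
    if (!length(hit)) rep(0, nrow(gen))
    else unname(rowSums(count_matrix(gen)[, hit, drop = FALSE]))
  }
  nD <- pick(dialister_name); nP <- pick(phasco_name)
  if (!any(nm %in% c(dialister_name, phasco_name)))
    warn("neither succinate-utilizer genus found; all samples unclassified")
  calls <- tibble::tibble(
    sample_id = gen$sample_id, nD = nD, nP = nP,
    rD = ifelse(nD + nP > 0, nD / (nD + nP), NA_real_),
    label = classify_succinotype(nD, nP, hi, lo, min_reads))
  if (!is.null(subject_map)) {
    pri <- c(D = 1, P = 1, mixed = 2, unclassified = 3)
    calls <- calls |>
      dplyr::left_join(subject_map, by = "sample_id") |>
      dplyr::group_by(.data$subject) |>
      dplyr::slice_min(pri[.data$label], n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  calls
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Two-sided p-value by summing, with margins fixed, the hypergeometric
#' probabilities of all tables no more probable than the observed one.
#' An empty margin returns p = 1 by convention.
#'
#' @param a,b,c,d non-negative integer cell counts (rows x columns:
#'   `[[a, b], [c, d]]`).
#' @return two-sided p-value.
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  if (any(c(a, b, c, d) < 0)) abort("cell counts must be non-negative")
  if ((a + b) == 0 || (c + d) == 0 || (a + c) == 0 || (b + d) == 0) return(1)
  m <- a + c; nn <- b + d; k <- a + b
  x <- max(0, k - nn):min(k, m)
  pr <- stats::dhyper(x, m, nn, k)
  p_obs <- stats::dhyper(a, m, nn, k)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}

#' Succinotype-metadata association tests
#'
#' For each metadata variable, tests every (succinotype label, variable
#' level) pair with a 2x2 Fisher's exact test (label vs rest x level vs
#' rest), BH-adjusting p-values across the whole family. Degenerate
#' tables (empty margins) are skipped with a reason.
#'
#' @param calls succinotype calls from [classify_cohort()].
#' @param metadata sample metadata tibble.
#' @param variables character vector of metadata columns to test.
#' @return tibble with variable, level, label, the 2x2 counts, `p`,
#'   `p_adj`, and `note`.
#' @export
association_tests <- function(calls, metadata, variables) {
  merged <- dplyr::inner_join(calls, metadata, by = "sample_id")
  rows <- list()
  for (v in variables) {
    vals <- as.character(merged[[v]])
    for (lev in sort(unique(vals[!is.na(vals)]))) {
      for (lab in sort(unique(merged$label))) {
        a <- sum(merged$label == lab & vals == lev, na.rm = TRUE)
        b <- sum(merged$label == lab & vals != lev, na.rm = TRUE)
        c_ <- sum(merged$label != lab & vals == lev, na.rm = TRUE)
        d <- sum(merged$label != lab & vals != lev, na.rm = TRUE)
        degenerate <- (a + b) == 0 || (c_ + d) == 0 || (a + c_) == 0 || (b + d) == 0
        rows[[length(rows) + 1]] <- tibble::tibble(
          variable = v, level = lev, label = lab,
          n11 = a, n12 = b, n21 = c_, n22 = d,
          p = if (degenerate) NA_real_ else fisher_exact_2x2(a, b, c_, d),
          note = if (degenerate) "degenerate margins" else "")
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out$p_adj <- NA_real_
  ok <- !is.na(out$p)
  out$p_adj[ok] <- stats::p.adjust(out$p[ok], method = "BH")
  out
}

#' Succinotype prevalence under both normalizations
#'
#' Reports label frequencies normalised within each group and as a
#' fraction of the whole cohort.
#'
#' @param calls succinotype calls.
#' @param metadata sample metadata with a `group` column.
#' @return tibble with group, label, n, `prop_within_group`, `prop_cohort`.
#' @export
succinotype_prevalence <- function(calls, metadata) {
  merged <- dplyr::inner_join(calls, metadata, by = "sample_id")
  n_total <- nrow(merged)
  merged |>
    dplyr::count(.data$group, .data$label) |>
    dplyr::group_by(.data$group) |>
    dplyr::mutate(prop_within_group = .data$n / sum(.data$n)) |>
    dplyr::ungroup() |>
    dplyr::mutate(prop_cohort = .data$n / n_total)
}
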