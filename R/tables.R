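# Count-table I/O, taxonomic aggregation, filtering, rarefaction and
# compositional transforms. Counts live in wide tibbles: one `sample_id`
# column plus one non-negative numeric column per taxon.

#' Read a count table from a tab-separated file
#'
#' Files store taxa as rows and samples as columns (the common deposit
#' layout); the returned tibble is transposed to samples x taxa.
#'
#' @param path file path.
#' @return count tibble (`sample_id` + taxa columns).
#' @export
read_count_table <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  taxa <- raw[[1]]
  if (anyDuplicated(taxa))
    abort(paste0("duplicate taxon id at line ",
                 which(duplicated(taxa))[1] + 1L, ": ", taxa[duplicated(taxa)][1]))
  if (anyDuplicated(names(raw)[-1]))
    abort(paste0("duplicate sample id: ", names(raw)[-1][duplicated(names(raw)[-1])][1]))
  m <- as.matrix(raw[-1])
  if (any(m != round(m)))
    abort(paste0("counts must be integers (offending line ",
                 which(rowSums(m != round(m)) > 0)[1] + 1L, ")"))
  if (min(m) < 0) abort("negative counts in file")
  out <- t(m)
  colnames(out) <- taxa
  rownames(out) <- names(raw)[-1]
  as_count_tbl(out)
}

#' Write a count table as tab-separated taxa x samples
#'
#' When the table carries filter provenance (`attr(, "dropped")` from
#' [rare_asv_filter()] or `attr(, "excluded")` from [rarefy_counts()]), a
#' sidecar JSON log `<path>.log.json` records those decisions.
#'
#' @param counts count tibble.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_count_table <- function(counts, path) {
  check_counts(counts)
  m <- t(count_matrix(counts))
  df <- data.frame(taxon_id = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log <- list()
  if (!is.null(attr(counts, "dropped"))) log$taxa_dropped <- attr(counts, "dropped")
  if (!is.null(attr(counts, "excluded"))) log$samples_excluded <- attr(counts, "excluded")
  if (length(log))
    jsonlite::write_json(log, paste0(path, ".log.json"), auto_unbox = FALSE)
  invisible(path)
}

#' Read a BIOM-format count table (optional)
#'
#' Thin wrapper over the `biomformat` package, returning the same
#' samples x taxa tibble as [read_count_table()].
#'
#' @param path path to a BIOM file.
#' @return count tibble.
#' @export
read_biom_table <- function(path) {
  if (!requireNamespace("biomformat", quietly = TRUE))
    abort("the biomformat package is required to read BIOM files")
  b <- biomformat::read_biom(path)
  m <- as(biomformat::biom_data(b), "matrix")   # taxa x samples
  as_count_tbl(t(m))
}

#' Read/write a taxonomy table (taxon_id + rank columns)
#' @param path file path.
#' @return tibble with `taxon_id` and rank columns.
#' @export
read_taxonomy_table <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
  if (anyDuplicated(tb$taxon_id))
    abort(paste0("duplicate taxon_id: ", tb$taxon_id[duplicated(tb$taxon_id)][1]))
  tb
}

#' @rdname read_taxonomy_table
#' @param taxonomy taxonomy tibble.
#' @export
write_taxonomy_table <- function(taxonomy, path) {
  utils::write.table(taxonomy, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read/write sample metadata (samples as rows)
#' @param path file path.
#' @return metadata tibble keyed by `sample_id`.
#' @export
read_sample_metadata <- function(path) {
  tb <- tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE))
  if (anyDuplicated(tb$sample_id))
    abort(paste0("duplicate sample_id: ", tb$sample_id[duplicated(tb$sample_id)][1]))
  tb
}

#' @rdname read_sample_metadata
#' @param metadata metadata tibble.
#' @export
write_sample_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Aggregate ASV counts to a taxonomic rank
#'
#' Sums member ASV counts per distinct rank value; per-sample totals are
#' conserved exactly. ASVs whose rank is missing/empty are pooled as
#' `unassigned_<nearest assigned parent>` rather than dropped.
#'
#' @param counts ASV-level count tibble.
#' @param taxonomy tibble with `taxon_id` plus rank columns
#'   (kingdom/phylum/class/order/family/genus).
#' @param rank rank to aggregate at (default "genus").
#' @return count tibble with one column per rank value.
#' @export
aggregate_by_rank <- function(counts, taxonomy, rank = "genus") {
  check_counts(counts)
  ranks <- c("kingdom", "phylum", "class", "order", "family", "genus")
  if (!rank %in% names(taxonomy)) abort(paste0("rank not in taxonomy: ", rank))
  tax <- taxonomy[match(taxa_names(counts), taxonomy$taxon_id), , drop = FALSE]
  lab <- as.character(tax[[rank]])
  blank <- is.na(tax$taxon_id) | is.na(lab) | lab == ""
  if (any(blank)) {
    above <- rev(ranks[seq_len(match(rank, ranks) - 1)])
    parent <- rep("root", sum(blank))
    sub <- tax[blank, , drop = FALSE]
    for (i in seq_len(nrow(sub))) {
      for (r in above) {
        v <- as.character(sub[[r]][i])
        if (!is.na(v) && v != "") { parent[i] <- v; break }
      }
    }
    lab[blank] <- paste0("unassigned_", parent)
  }
  m <- count_matrix(counts)
  agg <- t(rowsum(t(m), group = lab))
  as_count_tbl(agg[, order(colnames(agg)), drop = FALSE])
}

#' Remove singleton and rare taxa
#'
#' Drops taxa seen in exactly one sample with one read (singletons) and
#' taxa below a relative-abundance cutoff expressed against the mean
#' per-sample sequencing depth. Two interpretations of the cutoff are
#' offered: `"total"` (default) removes taxa whose *total* count across
#' samples is below `fraction` x mean depth; `"per_sample"` removes taxa
#' whose *mean relative abundance* is below `fraction`.
#'
#' @param counts count tibble.
#' @param fraction abundance cutoff (default 0.001, i.e. 0.1%).
#' @param mode `"total"` or `"per_sample"`.
#' @return filtered count tibble; dropped taxa in `attr(, "dropped")`.
#' @export
rare_asv_filter <- function(counts, fraction = 0.001, mode = c("total", "per_sample")) {
  mode <- match.arg(mode)
  stopifnot(fraction > 0, fraction < 1)
  check_counts(counts)
  m <- count_matrix(counts)
  tot <- colSums(m)
  singleton <- tot == 1
  if (mode == "total") {
    rare <- tot < fraction * mean(rowSums(m))
  } else {
    rel <- m / pmax(rowSums(m), 1)
    rare <- colMeans(rel) < fraction
  }
  drop <- singleton | rare
  out <- dplyr::select(counts, "sample_id", dplyr::all_of(taxa_names(counts)[!drop]))
  attr(out, "dropped") <- taxa_names(counts)[drop]
  out
}

#' Keep taxa present in at least a fraction of samples
#'
#' Removal uses the strict rule: a taxon is dropped when its prevalence is
#' *below* `min_prevalence` (exactly at the threshold is kept).
#'
#' @param counts count tibble.
#' @param min_prevalence fraction of samples in `[0, 1)`.
#' @return filtered count tibble.
#' @export
prevalence_filter <- function(counts, min_prevalence) {
  stopifnot(min_prevalence >= 0, min_prevalence < 1)
  check_counts(counts)
  m <- count_matrix(counts)
  prev <- colMeans(m > 0)
  keep <- prev >= min_prevalence
  if (!any(keep)) warn("prevalence filter removed every taxon")
  dplyr::select(counts, "sample_id", dplyr::all_of(taxa_names(counts)[keep]))
}

#' Rarefy samples to an even depth
#'
#' Subsamples reads without replacement to exactly `depth` per sample;
#' samples with fewer reads than `depth` are excluded and listed in
#' `attr(, "excluded")`.
#'
#' @param counts count tibble (integer counts).
#' @param depth target reads per sample.
#' @param seed RNG seed (rarefaction is stochastic).
#' @return rarefied count tibble.
#' @export
rarefy_counts <- function(counts, depth, seed) {
  if (depth <= 0) abort("rarefaction depth must be positive")
  check_counts(counts, integer_only = TRUE)
  m <- count_matrix(counts)
  keep <- rowSums(m) >= depth
  excluded <- rownames(m)[!keep]
  m <- m[keep, , drop = FALSE]
  out <- with_seed(seed, suppressWarnings(vegan::rrarefy(m, depth)))
  res <- as_count_tbl(out)
  attr(res, "excluded") <- excluded
  res
}

#' Per-sample relative abundances
#' @param counts count tibble; every sample total must be positive.
#' @return tibble of proportions (rows sum to 1).
#' @export
relative_abundance <- function(counts) {
  check_counts(counts)
  m <- count_matrix(counts)
  tot <- rowSums(m)
  if (any(tot == 0))
    abort(paste0("all-zero sample: ", rownames(m)[tot == 0][1]))
  as_count_tbl(m / tot)
}

#' Centred log-ratio transform
#'
#' `log(x + pseudocount)` centred by the per-sample mean log value; each
#' output row sums to zero.
#'
#' @param counts count tibble.
#' @param pseudocount added before the log (default 1); may be 0 if all
#'   counts are positive.
#' @return tibble of CLR values.
#' @export
clr_transform <- function(counts, pseudocount = 1) {
  m <- count_matrix(counts) + pseudocount
  if (min(m) <= 0) abort("pseudocount must make all values positive")
  lm_ <- log(m)
  as_count_tbl(lm_ - rowMeans(lm_))
}
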