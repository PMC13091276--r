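#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom tidyr pivot_longer pivot_wider
#' @importFrom purrr map map_dbl map2 imap
#' @useDynLib microstrat, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# A count table is a tibble whose first column is `sample_id` (unique
# character) and whose remaining columns are non-negative numeric taxa.

#' Convert a count tibble to a numeric matrix (samples x taxa)
#'
#' @param counts count tibble with a `sample_id` column.
#' @return numeric matrix with sample ids as rownames.
#' @export
count_matrix <- function(counts) {
  check_counts(counts, allow_negative = TRUE)
  m <- as.matrix(counts[setdiff(names(counts), "sample_id")])
  rownames(m) <- counts$sample_id
  storage.mode(m) <- "double"
  m
}

#' Convert a samples x taxa matrix to a count tibble
#'
#' @param m numeric matrix with sample ids as rownames.
#' @return tibble with `sample_id` first.
#' @export
as_count_tbl <- function(m) {
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("T", seq_len(ncol(m)))
  dplyr::bind_cols(tibble::tibble(sample_id = rownames(m)),
                   tibble::as_tibble(m, .name_repair = "minimal"))
}

check_counts <- function(counts, integer_only = FALSE, allow_negative = FALSE) {
  if (!is.data.frame(counts) || !"sample_id" %in% names(counts))
    abort("count table must be a data frame with a `sample_id` column")
  ids <- counts$sample_id
  if (anyDuplicated(ids))
    abort(paste0("duplicate sample_id: ", ids[duplicated(ids)][1]))
  num <- counts[setdiff(names(counts), "sample_id")]
  if (anyDuplicated(names(num)))
    abort(paste0("duplicate taxon id: ", names(num)[duplicated(names(num))][1]))
  if (!all(vapply(num, is.numeric, logical(1))))
    abort("all taxon columns must be numeric")
  m <- as.matrix(num)
  if (!allow_negative && length(m) && min(m, na.rm = TRUE) < 0)
    abort("negative counts are not allowed")
  if (integer_only && length(m) && any(m != round(m)))
    abort("counts must be integers")
  invisible(counts)
}

taxa_names <- function(counts) setdiff(names(counts), "sample_id")

# Deterministic stage seeds derived from a master seed: hash the stage name
# into a 31-bit offset so adding stages never shifts existing streams.
stage_seed <- function(master_seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)) * 131L)
  (as.integer(master_seed) + (h %% 100003L)) %% .Machine$integer.max
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}
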