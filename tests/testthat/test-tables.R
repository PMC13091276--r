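test_that("count tables round-trip through TSV", {
  tb <- toy_counts()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_count_table(tb, path)
  back <- read_count_table(path)
  expect_equal(as.data.frame(back), as.data.frame(tb))
})

test_that("malformed count files raise informative parse errors", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "a\t3\t4"), path)
  expect_error(read_count_table(path), "duplicate taxon id.*a")
  writeLines(c("taxon_id\ts1\ts2", "a\t1\t2", "b\t3.7\t4"), path)
  expect_error(read_count_table(path), "integers")
  expect_error(
    check_counts <- as_count_tbl(matrix(1, 1, 1)) |>
      dplyr::bind_rows(as_count_tbl(matrix(1, 1, 1))) |>
      alpha_diversity(),
    "duplicate sample_id")
})

test_that("rank aggregation sums member ASVs and conserves totals", {
  tb <- toy_counts()
  agg <- aggregate_by_rank(tb, toy_taxonomy(), "genus")
  expect_setequal(setdiff(names(agg), "sample_id"), c("GenA", "GenB", "GenC"))
  expect_equal(agg$GenA, tb$asv1 + tb$asv2)
  expect_equal(rowSums(count_matrix(agg)), rowSums(count_matrix(tb)))
  # many ASVs of two genera collapse to exactly two columns
  m <- matrix(rpois(26 * 4, 5), nrow = 4,
              dimnames = list(paste0("s", 1:4), paste0("asv", 1:26)))
  tax <- tibble::tibble(taxon_id = paste0("asv", 1:26), kingdom = "Bacteria",
                        phylum = "Bacillota", class = NA, order = NA, family = NA,
                        genus = rep(c("Dialister", "Phascolarctobacterium"), c(23, 3)))
  agg2 <- aggregate_by_rank(as_count_tbl(m), tax, "genus")
  expect_equal(sort(setdiff(names(agg2), "sample_id")),
               c("Dialister", "Phascolarctobacterium"))
})

test_that("unassigned genera pool under the nearest assigned parent", {
  tax <- toy_taxonomy()
  tax$genus[4] <- ""
  agg <- aggregate_by_rank(toy_counts(), tax, "genus")
  expect_true("unassigned_f2" %in% names(agg))
  expect_equal(rowSums(count_matrix(agg)), rowSums(count_matrix(toy_counts())))
})

test_that("rare-taxon filter drops singletons and low-total taxa", {
  m <- matrix(0L, 10, 3, dimnames = list(paste0("s", 1:10), c("abundant", "rare", "single")))
  m[, "abundant"] <- 1000L
  m[, "rare"] <- 1L          # total 10 < 0.001 * mean depth if depth large
  m[1, "single"] <- 1L
  m[1, "rare"] <- 0L
  tb <- as_count_tbl(m)
  out <- rare_asv_filter(tb, fraction = 0.02)  # mean depth ~1001 -> cutoff ~20
  expect_setequal(setdiff(names(out), "sample_id"), "abundant")
  expect_setequal(attr(out, "dropped"), c("rare", "single"))
  # all-abundant table unchanged, and the filter is idempotent
  ab <- as_count_tbl(matrix(100L, 4, 2, dimnames = list(paste0("s", 1:4), c("a", "b"))))
  expect_equal(as.data.frame(rare_asv_filter(ab)[names(ab)]), as.data.frame(ab),
               ignore_attr = TRUE)
  once <- rare_asv_filter(tb, fraction = 0.02)
  twice <- rare_asv_filter(once, fraction = 0.02)
  expect_equal(as.data.frame(twice), as.data.frame(once), ignore_attr = TRUE)
})

test_that("prevalence filter uses strict below-threshold removal", {
  m <- matrix(0L, 20, 3, dimnames = list(paste0("s", 1:20), c("one", "two", "all")))
  m[1, "one"] <- 5L
  m[1:2, "two"] <- 5L
  m[, "all"] <- 5L
  tb <- as_count_tbl(m)
  out <- prevalence_filter(tb, 0.10)
  expect_setequal(setdiff(names(out), "sample_id"), c("two", "all"))  # 2/20 = 10% kept
  expect_equal(names(prevalence_filter(tb, 0)), names(tb))
})

test_that("rarefaction hits exact depth, drops shallow samples, matches hypergeometric means", {
  m <- matrix(c(50L, 30L, 20L,
                5L, 3L, 1L), nrow = 2, byrow = TRUE,
              dimnames = list(c("deep", "shallow"), c("a", "b", "c")))
  tb <- as_count_tbl(m)
  out <- rarefy_counts(tb, 60, seed = 1)
  expect_equal(out$sample_id, "deep")
  expect_equal(attr(out, "excluded"), "shallow")
  expect_equal(rowSums(count_matrix(out)), c(deep = 60))
  expect_true(all(count_matrix(out) <= m["deep", , drop = FALSE]))
  # depth equal to the total returns the sample unchanged
  same <- rarefy_counts(tb, 9, seed = 1)
  expect_equal(unlist(same[same$sample_id == "shallow", c("a", "b", "c")]),
               c(a = 5, b = 3, c = 1))
  # marginal expectation: depth * count / total (hypergeometric mean)
  one <- as_count_tbl(matrix(c(40L, 40L, 20L), 1,
                             dimnames = list("s", c("a", "b", "c"))))
  draws <- sapply(1:500, function(s) unlist(rarefy_counts(one, 50, seed = s)[, c("a", "b", "c")]))
  expect_mu <- 50 * c(40, 40, 20) / 100
  se <- sqrt(diag(stats::var(t(draws))) / 500)
  expect_true(all(abs(rowMeans(draws) - expect_mu) < 3 * pmax(se, 1e-6)))
})

test_that("relative abundance and CLR satisfy their identities", {
  tb <- as_count_tbl(matrix(c(2, 2), 1, dimnames = list("s", c("a", "b"))))
  expect_equal(unlist(relative_abundance(tb)[, c("a", "b")]), c(a = 0.5, b = 0.5))
  expect_error(relative_abundance(as_count_tbl(matrix(0, 1, 2))), "all-zero")
  m <- matrix(rpois(60, 20), 6, 10)
  rel <- count_matrix(relative_abundance(as_count_tbl(m)))
  expect_equal(unname(rowSums(rel)), rep(1, 6), tolerance = 1e-12)
  clr <- count_matrix(clr_transform(as_count_tbl(m)))
  expect_equal(unname(rowSums(clr)), rep(0, 6), tolerance = 1e-9)
  # equal counts map to an all-zero row; scale invariance at pseudocount 0
  eq <- count_matrix(clr_transform(as_count_tbl(matrix(7, 1, 5))))
  expect_equal(as.numeric(eq), rep(0, 5))
  x <- matrix(c(2, 4, 8, 1, 3, 9), 2, byrow = TRUE)
  expect_equal(count_matrix(clr_transform(as_count_tbl(2 * x), pseudocount = 0)),
               count_matrix(clr_transform(as_count_tbl(x), pseudocount = 0)),
               ignore_attr = TRUE)
})
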