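test_that("succinotype rule applies strict boundaries and the read floor", {
  expect_equal(classify_succinotype(95, 5), "D")      # rD = 0.95
  expect_equal(classify_succinotype(90, 10), "mixed") # rD = 0.90, not > 0.9
  expect_equal(classify_succinotype(10, 90), "mixed") # rD = 0.10, not < 0.1
  expect_equal(classify_succinotype(5, 95), "P")
  expect_equal(classify_succinotype(9, 0), "unclassified")  # total 9 < 10
  expect_equal(classify_succinotype(10, 0), "D")
  expect_error(classify_succinotype(-1, 5), "non-negative")
})

test_that("classification agrees with a brute-force oracle on a broad grid", {
  # independent re-statement of the printed rule
  oracle <- function(nD, nP) {
    if (nD + nP < 10) return("unclassified")
    r <- nD / (nD + nP)
    if (r > 0.9) "D" else if (r < 0.1) "P" else "mixed"
  }
  grid <- expand.grid(nD = 0:60, nP = 0:60)
  got <- classify_succinotype(grid$nD, grid$nP)
  want <- mapply(oracle, grid$nD, grid$nP)
  expect_identical(got, unname(want))
})

test_that("scaling counts never changes a classifiable label", {
  grid <- expand.grid(nD = 0:25, nP = 0:25, c = c(2, 5, 13))
  base <- classify_succinotype(grid$nD, grid$nP)
  scaled <- classify_succinotype(grid$nD * grid$c, grid$nP * grid$c)
  classifiable <- base != "unclassified"
  expect_identical(scaled[classifiable], base[classifiable])
  moved <- base == "unclassified" & scaled != "unclassified"
  expect_true(all(scaled[base == "unclassified"][
    scaled[base == "unclassified"] != "unclassified"] %in% c("D", "P", "mixed")))
})

test_that("cohort classification aggregates ASVs and prioritizes clear subject calls", {
  m <- matrix(c(40L, 60L, 0L,
                5L, 5L, 40L,
                0L, 0L, 50L), nrow = 3, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"),
                              c("dial_asv1", "dial_asv2", "phasco_asv")))
  tax <- tibble::tibble(taxon_id = colnames(m)[c(1, 2, 3)], kingdom = "Bacteria",
                        phylum = "Bacillota", class = NA, order = NA, family = NA,
                        genus = c("Dialister", "Dialister", "Phascolarctobacterium"))
  calls <- classify_cohort(as_count_tbl(m), tax)
  expect_equal(calls$label, c("D", "mixed", "P"))
  expect_equal(calls$nD, c(100, 10, 0))
  # one mixed and one P sample for the same subject -> P retained
  subj <- tibble::tibble(sample_id = c("s1", "s2", "s3"),
                         subject = c("u1", "u2", "u2"))
  merged <- classify_cohort(as_count_tbl(m), tax, subject_map = subj)
  expect_equal(merged$label[merged$subject == "u2"], "P")
  # absent genera -> everything unclassified with a warning
  tax_none <- dplyr::mutate(tax, genus = "Other")
  expect_warning(calls0 <- classify_cohort(as_count_tbl(m), tax_none),
                 "unclassified")
  expect_true(all(calls0$label == "unclassified"))
})

test_that("Fisher two-sided p matches hypergeometric enumeration", {
  expect_equal(fisher_exact_2x2(5, 0, 0, 5), 2 / 252)
  expect_equal(fisher_exact_2x2(1, 1, 1, 1), 1)
  expect_equal(fisher_exact_2x2(0, 3, 0, 4), 1)      # empty margin convention
  # symmetry under row and column swaps, agreement with stats::fisher.test
  set.seed(1)
  for (i in 1:25) {
    tb <- matrix(rpois(4, 6), 2)
    p <- fisher_exact_2x2(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(p, fisher_exact_2x2(tb[2, 1], tb[2, 2], tb[1, 1], tb[1, 2]))
    expect_equal(p, fisher_exact_2x2(tb[1, 1], tb[2, 1], tb[1, 2], tb[2, 2]))
    expect_equal(p, stats::fisher.test(tb)$p.value, tolerance = 1e-9)
  }
})

test_that("association tests report counts, skip degenerate tables, and BH-adjust", {
  calls <- tibble::tibble(sample_id = paste0("s", 1:40),
                          nD = 50, nP = 0, rD = 1,
                          label = rep(c("D", "P"), 20))
  meta <- tibble::tibble(sample_id = paste0("s", 1:40),
                         group = rep(c("g1", "g2"), each = 20))
  res <- association_tests(calls, meta, "group")
  expect_true(all(abs(res$p - 1) < 1e-9))  # identical label distribution
  expect_true(all(res$p_adj >= res$p - 1e-12, na.rm = TRUE))
  # enriched label is detected
  calls2 <- calls
  calls2$label <- c(rep("D", 18), rep("P", 2), rep("P", 18), rep("D", 2))
  res2 <- association_tests(calls2, meta, "group")
  expect_lt(min(res2$p_adj, na.rm = TRUE), 0.05)
})

test_that("forced enrichment is detected with high power at n = 100", {
  # group g1 D-enriched (odds 5): power >= 0.8 at FDR 0.05
  set.seed(99)
  detect <- replicate(40, {
    n <- 100
    grp <- rep(c("g1", "g2"), each = n / 2)
    pD <- ifelse(grp == "g1", 5 / 6, 1 / 2)
    lab <- ifelse(stats::runif(n) < pD, "D", "P")
    calls <- tibble::tibble(sample_id = paste0("s", 1:n), nD = 50, nP = 0,
                            rD = 1, label = lab)
    meta <- tibble::tibble(sample_id = paste0("s", 1:n), group = grp)
    res <- association_tests(calls, meta, "group")
    any(res$p_adj < 0.05, na.rm = TRUE)
  })
  expect_gte(mean(detect), 0.8)
})

test_that("prevalence summaries report both normalizations", {
  calls <- tibble::tibble(sample_id = paste0("s", 1:10),
                          nD = 20, nP = 0, rD = 1,
                          label = c(rep("D", 6), rep("P", 4)))
  meta <- tibble::tibble(sample_id = paste0("s", 1:10),
                         group = rep(c("a", "b"), each = 5))
  pv <- succinotype_prevalence(calls, meta)
  expect_equal(sum(pv$prop_cohort), 1)
  sums <- pv |> dplyr::group_by(group) |>
    dplyr::summarise(s = sum(prop_within_group))
  expect_true(all(abs(sums$s - 1) < 1e-12))
})
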