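test_that("Dirichlet-multinomial log-likelihood matches closed forms", {
  expect_equal(dm_loglik(c(1, 0), c(1, 1)), log(0.5))
  expect_equal(dm_loglik(c(0, 0, 0), c(2, 3, 4)), 0)
  # Monte-Carlo oracle on a 3-taxon toy: average multinomial likelihood
  # over Dirichlet draws
  set.seed(42)
  alpha <- c(2, 1, 0.5); x <- c(4, 2, 1)
  n_mc <- 2e5
  g <- matrix(rgamma(3 * n_mc, shape = alpha), ncol = 3, byrow = TRUE)
  p <- g / rowSums(g)
  ll <- stats::dmultinom(x, prob = c(1, 1, 1) / 3, log = TRUE)  # placeholder shape
  lik <- apply(p, 1, function(pr) stats::dmultinom(x, prob = pr))
  mc <- mean(lik); se <- stats::sd(lik) / sqrt(n_mc)
  # dm_loglik excludes the multinomial coefficient; add it back
  coef_log <- lgamma(sum(x) + 1) - sum(lgamma(x + 1))
  expect_lt(abs(exp(dm_loglik(x, alpha) + coef_log) - mc), 2 * se)
})

test_that("single-component fit recovers a symmetric Dirichlet within 20%", {
  a <- rep(10, 5); names(a) <- paste0("t", 1:5)
  d <- sample_dmm_counts(list(a), 1, n = 200, depths = 1000, seed = 5)
  fit <- fit_dmm(d$counts, 1, seed = 1)
  expect_true(all(abs(fit$alpha[, 1] - 10) / 10 < 0.2))
  # independent oracle: plain (unweighted) fixed-point MLE to tight tolerance
  X <- count_matrix(d$counts)
  a_or <- rep(1, 5); N <- rowSums(X)
  for (it in 1:2000) {
    A <- sum(a_or)
    num <- colSums(digamma(sweep(X, 2, a_or, "+")) - rep(digamma(a_or), each = nrow(X)))
    den <- sum(digamma(N + A) - digamma(A))
    a_new <- a_or * num / den
    if (max(abs(a_new - a_or)) < 1e-10) { a_or <- a_new; break }
    a_or <- a_new
  }
  expect_equal(unname(fit$alpha[, 1]), unname(a_or), tolerance = 0.01)
})

test_that("EM log-likelihood is monotone and restarts pick the best fit", {
  set.seed(3)
  a1 <- c(20, 2, 2, 2, 2); a2 <- c(2, 2, 2, 2, 20)
  names(a1) <- names(a2) <- paste0("g", 1:5)
  d <- sample_dmm_counts(list(a1, a2), c(0.5, 0.5), n = 80, depths = 500, seed = 9)
  fit <- fit_dmm(d$counts, 2, seed = 4)
  expect_true(all(diff(fit$trace) > -1e-6 * (abs(fit$loglik) + 1)))
  expect_true(all(fit$weights > 0))
  expect_equal(rowSums(fit$resp), rep(1, 80), tolerance = 1e-9)
})

test_that("well-separated components are recovered with confident assignments", {
  G <- 20
  base <- rep(2, G)
  a2 <- base; a2[1:10] <- a2[1:10] * 10
  names(base) <- names(a2) <- paste0("g", 1:G)
  d <- sample_dmm_counts(list(base, a2), c(0.5, 0.5), n = 150, depths = 1500, seed = 21)
  fit <- fit_dmm(d$counts, 2, seed = 7)
  ass <- assign_enterotypes(fit)
  acc <- max(mean(ass$enterotype == d$labels), mean(ass$enterotype == 3 - d$labels))
  expect_gte(acc, 0.95)
  expect_gte(mean(ass$responsibility >= 0.99), 0.95)
})

test_that("model selection finds the generating K on synthetic cohorts", {
  G <- 15
  a1 <- rep(3, G); a2 <- a1; a2[1:7] <- 30
  names(a1) <- names(a2) <- paste0("g", 1:G)
  two <- sample_dmm_counts(list(a1, a2), c(0.5, 0.5), n = 120, depths = 1000, seed = 2)
  sel2 <- select_k(two$counts, k_range = 1:3, seed = 5)
  expect_equal(unname(sel2$best["bic"]), 2)
  expect_gte(unname(sel2$best["laplace"]), 2)
  one <- sample_dmm_counts(list(a1), 1, n = 120, depths = 1000, seed = 3)
  sel1 <- select_k(one$counts, k_range = 1:2, seed = 5)
  expect_equal(unname(sel1$best["bic"]), 1)
})

test_that("identical samples collapse the two-component fit", {
  m <- matrix(rep(c(30L, 20L, 10L), each = 40), nrow = 40)
  colnames(m) <- paste0("g", 1:3); rownames(m) <- paste0("s", 1:40)
  tb <- as_count_tbl(m)
  s <- select_k(tb, k_range = 1:2, seed = 1)
  expect_equal(unname(s$best["bic"]), 1)
  f2 <- s$fits[["k2"]]
  profiles <- apply(f2$alpha, 2, function(a) a / sum(a))
  collapsed <- min(f2$weights) < 0.05 ||
    max(abs(profiles[, 1] - profiles[, 2])) < 0.05
  expect_true(collapsed)
})

test_that("assignment breaks ties toward the lowest component and logs them", {
  fit <- structure(list(resp = rbind(c(0.9, 0.1), c(0.5, 0.5)),
                        sample_ids = c("s1", "s2"), k = 2),
                   class = "dmm_fit")
  ass <- assign_enterotypes(fit)
  expect_equal(ass$enterotype, c(1L, 1L))
  expect_equal(attr(ass, "ties"), "s2")
})

test_that("genus contributions are zero for identical profiles and flag the moved genus", {
  G <- 6
  a <- rep(5, G); names(a) <- paste0("g", 1:G)
  mkfit <- function(alpha_mat, k) {
    structure(list(k = k, alpha = alpha_mat, genera = paste0("g", 1:G)),
              class = "dmm_fit")
  }
  f1 <- mkfit(matrix(a, ncol = 1), 1)
  fk_same <- mkfit(cbind(a, a), 2)
  expect_true(all(genus_contributions(fk_same, f1)$score < 1e-12))
  moved <- a; moved["g3"] <- 50
  fk <- mkfit(cbind(a, moved), 2)
  contrib <- genus_contributions(fk, f1, space = "proportion")
  expect_equal(contrib$genus[1], "g3")
  expect_true(all(contrib$score >= 0))
  # CLR space is the default and also ranks the moved genus first
  expect_equal(genus_contributions(fk, f1)$genus[1], "g3")
  bad <- mkfit(matrix(a, ncol = 1), 1); bad$genera <- paste0("x", 1:G)
  expect_error(genus_contributions(fk, bad), "different genus sets")
})

test_that("tidiers expose scores and profiles", {
  a <- rep(4, 4); names(a) <- paste0("g", 1:4)
  d <- sample_dmm_counts(list(a), 1, n = 30, depths = 300, seed = 1)
  fit <- fit_dmm(d$counts, 1, seed = 1)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 4)
  gl <- generics::glance(fit)
  expect_equal(gl$k, 1)
  expect_true(is.finite(gl$laplace))
})
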