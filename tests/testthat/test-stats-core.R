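test_that("binomial upper tail matches the enumeration oracle and the
           published liver worked example", {
  # worked example: 30 liver-specific pairs among 162 tissue pairs, with a
  # background of 820 liver pair combinations out of 23005
  p_liver <- binomial_upper_tail(30, 162, 820 / 23005, strict_tail = TRUE)
  expect_equal(signif(p_liver, 2), 2.3e-14)

  # enumeration oracle on small cases, both tail conventions
  cases <- list(c(2, 3, 0.5), c(0, 7, 0.2), c(5, 12, 0.35), c(12, 12, 0.9))
  for (cs in cases) {
    for (strict in c(TRUE, FALSE)) {
      expect_equal(
        binomial_upper_tail(cs[1], cs[2], cs[3], strict_tail = strict),
        enum_binom_tail(cs[1], cs[2], cs[3], strict), tolerance = 1e-12)
    }
  }
  expect_equal(binomial_upper_tail(2, 3, 0.5, strict_tail = FALSE), 0.5)
  expect_equal(binomial_upper_tail(0, 50, 0.3, strict_tail = FALSE), 1.0)

  # strict + pmf(n_obs) = inclusive
  expect_equal(binomial_upper_tail(4, 20, 0.1, TRUE) + dbinom(4, 20, 0.1),
               binomial_upper_tail(4, 20, 0.1, FALSE), tolerance = 1e-12)

  expect_error(binomial_upper_tail(5, 3, 0.5), "n_obs")
  expect_error(binomial_upper_tail(1, 3, 1.5), "n_obs")
})

test_that("hypergeometric overlap probability equals exhaustive enumeration
           for universes up to 20", {
  expect_equal(hypergeom_overlap_pvalue(5, 10, 5, 5), 1 / 252)
  expect_equal(hypergeom_overlap_pvalue(0, 10, 4, 5), 1.0)
  for (cs in list(c(8, 20, 10, 10), c(3, 15, 6, 9), c(1, 8, 2, 3),
                  c(4, 12, 4, 10))) {
    expect_equal(hypergeom_overlap_pvalue(cs[1], cs[2], cs[3], cs[4]),
                 enum_hypergeom_tail(cs[1], cs[2], cs[3], cs[4]),
                 tolerance = 1e-12)
  }
  expect_error(hypergeom_overlap_pvalue(6, 10, 5, 5), "exceeds")
})

test_that("Fisher enrichment is the hypergeometric tail and matches
           fisher.test on 2x2 tables", {
  expect_equal(fisher_enrichment(2, 2, 2, 4), 1 / 6)
  expect_equal(fisher_enrichment(0, 5, 5, 20), 1.0)
  expect_equal(fisher_enrichment(1, 1, 1, 10), 0.1)
  # independent oracle: one-sided Fisher exact test on the 2x2 table
  k <- 4; n <- 9; K <- 7; N <- 30
  tab <- matrix(c(k, K - k, n - k, N - K - n + k), 2)
  expect_equal(fisher_enrichment(k, n, K, N),
               fisher.test(tab, alternative = "greater")$p.value,
               tolerance = 1e-12)
  expect_error(fisher_enrichment(5, 4, 10, 20), "margins")
})

test_that("pearson_r covers the closed-form examples and rejects
           degenerate profiles", {
  expect_equal(pearson_r(1:10, 1:10), 1.0)
  expect_equal(pearson_r(1:10, 10:1), -1.0)
  # hand-computed covariance / sd oracle
  x <- c(1, 2, 3, 5); y <- c(2, 2, 4, 5)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_r(x, y), r_hand)
  expect_error(pearson_r(rep(1, 5), 1:5), "constant")
  expect_error(pearson_r(1:2, 1:2), "length")
})

test_that("permutation test enumerates exhaustively for short profiles and
           is deterministic when sampling", {
  # all 3! = 6 permutations; r = 1 for identity only, ties counted >=
  res <- permutation_corr_pvalue(c(1, 2, 3), c(1, 2, 3))
  expect_equal(res$r, 1.0)
  perms <- matrix(c(1,2,3, 1,3,2, 2,1,3, 2,3,1, 3,1,2, 3,2,1),
                  ncol = 3, byrow = TRUE)
  r_all <- apply(perms, 1, function(ix) cor(c(1, 2, 3), c(1, 2, 3)[ix]))
  expect_equal(res$p, mean(r_all >= 1 - 1e-9))

  # sampling branch: determinism and the lower bound 1/(n_perm + 1)
  x <- c(3, 1, 4, 1, 5, 9, 2, 6, 5, 3)
  y <- c(2, 7, 1, 8, 2, 8, 1, 8, 2, 8)
  a <- permutation_corr_pvalue(x, y, n_perm = 999, seed = 7)
  b <- permutation_corr_pvalue(x, y, n_perm = 999, seed = 7)
  expect_identical(a, b)
  expect_gte(a$p, 1 / 1000)
  expect_lte(a$p, 1)

  # sampling converges to the exhaustive value (3 sigma of binomial error)
  x5 <- c(2, 4, 1, 5, 3); y5 <- c(1, 5, 2, 4, 3)
  exact <- permutation_corr_pvalue(x5, y5)$p
  sampled <- permutation_corr_pvalue(x5, y5, n_perm = 1e5, seed = 3,
                                     exact = FALSE)$p
  se <- sqrt(exact * (1 - exact) / 1e5)
  expect_lt(abs(sampled - exact), 3 * se + 2 / 1e5)

  expect_warning(
    permutation_corr_pvalue(x, y, n_perm = 50, seed = 1, exact = FALSE),
    "coarse")
})

test_that("BH q-values follow the step-up formula, preserve order and never
           decrease p", {
  expect_equal(bh_qvalues(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_qvalues(0.5), 0.5)
  expect_identical(bh_qvalues(numeric(0)), numeric(0))

  withr::with_seed(11, {
    for (i in 1:5) {
      p <- runif(20)
      q <- bh_qvalues(p)
      # independent step-up oracle
      o <- order(p)
      m <- length(p)
      q_oracle <- rev(cummin(rev(m * p[o] / seq_len(m))))
      q_oracle <- pmin(q_oracle, 1)[order(o)]
      expect_equal(q, q_oracle, tolerance = 1e-12)
      expect_true(all(q >= p))
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
  # idempotence holds on flat adjusted batches (equal q-values)
  q <- bh_qvalues(c(0.01, 0.02, 0.03, 0.04))
  expect_equal(bh_qvalues(q), q)
  expect_error(bh_qvalues(c(0.5, 1.2)), "0, 1")
})
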