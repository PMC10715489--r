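test_that("exhaustive permutation p-values equal the enumeration oracle", {
  cfg <- permutation_config(n_permutations = 1000L, seed = 2L)
  # frozen worked example: pooled {1,2,100,101}, 6 arrangements, two of
  # which (the observed split and its mirror) reach |mean diff| = 99
  res <- permutation_test(c(1, 2), c(100, 101), cfg)
  expect_equal(res$method, "exhaustive")
  expect_equal(res$p_value, 2 / 6)
  expect_equal(res$p_value, perm_oracle(c(1, 2), c(100, 101)))

  # identical groups: observed 0 is never exceeded strictly, p = 1
  same <- permutation_test(c(3, 1, 4), c(3, 1, 4), cfg)
  expect_equal(same$observed, 0)
  expect_equal(same$p_value, 1)

  # randomized small fixtures against the independent oracle
  set.seed(8)
  for (k in 1:10) {
    a <- round(runif(sample(3:5, 1)), 2)
    b <- round(runif(sample(3:5, 1)), 2)
    expect_equal(permutation_test(a, b, cfg)$p_value, perm_oracle(a, b))
  }
})

test_that("sampled permutation p-values are reproducible and never zero", {
  a <- rnorm(30, 0, 1)
  b <- rnorm(30, 3, 1)
  cfg <- permutation_config(n_permutations = 500L, seed = 11L)
  r1 <- permutation_test(a, b, cfg)
  r2 <- permutation_test(a, b, cfg)
  expect_equal(r1$method, "sampled")
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0) # add-one estimator floor: 1 / (B + 1)
  expect_equal(r1$p_value, 1 / 501)
  # independent of input ordering
  r3 <- permutation_test(sample(a), sample(b), cfg)
  expect_identical(r1$p_value, r3$p_value)
})

test_that("median statistic and degenerate inputs behave", {
  cfg <- permutation_config(statistic = "median_difference",
                            n_permutations = 1000L, seed = 3L)
  res <- permutation_test(c(1, 2, 3), c(10, 11, 12), cfg)
  expect_equal(res$observed, -9)
  expect_error(permutation_test(numeric(0), 1:3, cfg), "group")
})

test_that("pairwise tests Bonferroni-adjust over all unordered pairs", {
  set.seed(4)
  samples <- list(a = rnorm(8), b = rnorm(8), c = rnorm(8) + 5, d = rnorm(8))
  cfg <- permutation_config(n_permutations = 400L, seed = 6L)
  out <- pairwise_tests(samples, cfg)
  expect_equal(nrow(out), 6L)
  expect_equal(out$p_adjusted, pmin(1, out$p_value * 6))
  # agrees with the stock Bonferroni correction
  expect_equal(out$p_adjusted, p.adjust(out$p_value, "bonferroni"))
  expect_true(all(out$p_adjusted >= out$p_value))
  expect_true(all(out$p_adjusted <= 1))
  # hand arithmetic on the cap and on a small p
  expect_equal(min(1, 0.3 * 6), 1)
  expect_equal(min(1, 0.004 * 6), 0.024)
})

test_that("shared-expression test reports rank-sum headline plus Welch", {
  # no difference: identical scores per peptide
  nes <- c(1, 2, 3, 4, 5)
  expect_warning(tied <- shared_expression_test(rep(1, 5), rep(1, 5)),
                 "tied")
  expect_equal(tied$headline_p, 1)
  expect_true(tied$degenerate)

  same <- shared_expression_test(nes, nes)
  expect_gt(same$wilcoxon_p, 0.99)

  # tiny worked set: exact rank-sum p by enumeration over all 20
  # assignments of ranks {1..6} to group sizes 3/3
  a <- c(1, 2, 3); b <- c(4, 5, 6)
  idx <- combn(6, 3)
  w_obs <- sum(rank(c(b, a))[1:3]) # rank sum of the comparison group
  w_null <- apply(idx, 2, function(i) sum(i))
  exact_p <- mean(abs(w_null - mean(w_null)) >= abs(w_obs - mean(w_null)))
  res <- shared_expression_test(a, b)
  expect_equal(res$wilcoxon_p, exact_p)
  expect_false(res$degenerate)
})

test_that("a planted location shift is detected reliably", {
  set.seed(21)
  hits <- vapply(1:50, function(k) {
    a <- rnorm(50)
    b <- rnorm(50, mean = 2) # 2-sigma shift
    shared_expression_test(a, b)$significant
  }, logical(1))
  expect_gte(mean(hits), 0.99)
})
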