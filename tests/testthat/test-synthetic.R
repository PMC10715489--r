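test_that("generators are pure functions of configuration and seed", {
  cfg <- synthetic_config(seed = 77L, n_ref = 60L, n_cmp = 80L,
                          n_shared = 20L, n_up = 5L, n_down = 2L)
  p1 <- generate_repertoire_pair(cfg)
  p2 <- generate_repertoire_pair(cfg)
  expect_identical(p1, p2)
  r1 <- generate_rank_table(p1$rep_cmp, cfg, seed = 78L)
  r2 <- generate_rank_table(p2$rep_cmp, cfg, seed = 78L)
  expect_identical(r1, r2)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- generate_variant_fixture(cfg, dir = d1)
  f2 <- generate_variant_fixture(cfg, dir = d2)
  expect_identical(readLines(f1$vcf), readLines(f2$vcf))
  expect_identical(readLines(f1$gtf), readLines(f2$gtf))
  expect_identical(f1$truth, f2$truth)
})

test_that("the repertoire pair honours sizes, sharing and planted truth", {
  cfg <- synthetic_config(seed = 9L)
  pair <- generate_repertoire_pair(cfg, "wt", "ko")
  expect_equal(n_peptide(pair$rep_ref), 144L)
  expect_equal(n_peptide(pair$rep_cmp), 613L)
  part <- partition_repertoires(pair$rep_ref, pair$rep_cmp)
  expect_length(part$shared, 82L)
  expect_length(part$unique_a, 62L)
  expect_length(part$unique_b, 531L)
  expect_setequal(part$shared,
                  pair$truth$peptide[pair$truth$set == "shared"])
  expect_equal(sum(pair$truth$planted_log2fc > 0, na.rm = TRUE), 58L)
  expect_equal(sum(pair$truth$planted_log2fc < 0, na.rm = TRUE), 6L)

  none <- generate_repertoire_pair(
    synthetic_config(seed = 9L, n_ref = 20L, n_cmp = 20L, n_shared = 0L,
                     n_up = 0L, n_down = 0L)
  )
  expect_length(partition_repertoires(none$rep_ref, none$rep_cmp)$shared, 0L)
  expect_error(synthetic_config(seed = 1L, n_ref = 10L, n_cmp = 10L,
                                n_shared = 11L))
})

test_that("rank tables honour the configured binder fractions", {
  cfg <- synthetic_config(seed = 14L, n_ref = 50L, n_cmp = 50L,
                          n_shared = 10L, n_up = 2L, n_down = 1L)
  pair <- generate_repertoire_pair(cfg)
  rt0 <- generate_rank_table(pair$rep_cmp, cfg, strong_fraction = 0,
                             weak_fraction = 0, seed = 15L)
  expect_true(all(rt0$table$percent_rank > 2))
  expect_true(all(rt0$truth$true_class == "non"))

  rt <- generate_rank_table(pair$rep_cmp, cfg, seed = 16L)
  best <- best_class_per_peptide(rt$table)
  expect_identical(best$binder_class[match(rt$truth$peptide, best$peptide)],
                   rt$truth$true_class)
  expect_equal(nrow(rt$table), 6L * n_peptide(pair$rep_cmp))
})

test_that("generated marginals track the configured laws", {
  cfg <- synthetic_config(seed = 25L, n_cmp = 2000L)
  pair <- generate_repertoire_pair(cfg)
  ld <- length_distribution(pair$rep_cmp)
  expect_lt(abs(ld$fraction[ld$length == 8] - 0.535), 0.04)
  cp <- cterm_profile(pair$rep_cmp)
  expect_lt(abs(cp$freq$fraction[cp$freq$residue == "L"] - 0.533), 0.04)
  # spectral counts: every peptide has at least one spectrum; off the
  # planted shared set the mean tracks the configured law (1 + count_mean)
  sc <- pair$rep_cmp$table$spectra
  expect_true(all(sc >= 1L))
  unplanted <- pair$truth$peptide[pair$truth$set == "cmp_only"]
  sc_un <- sc[match(unplanted, pair$rep_cmp$table$peptide)]
  expect_lt(abs(mean(sc_un) - (1 + cfg$count_mean)), 1.5)
})
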