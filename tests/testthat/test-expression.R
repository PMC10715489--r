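test_that("NES formulas scale spectral counts as specified", {
  expect_equal(nes_comparison_sample(10, 1000), 10)
  expect_equal(nes_comparison_sample(0, 613), 0)
  expect_equal(nes_comparison_sample(5, 613), 5 * 1000 / 613)
  expect_error(nes_comparison_sample(1, 0), "positive")

  expect_equal(nes_reference_sample(10, 100, 50, 100), 50)
  # correction collapses when s1 = s2
  expect_equal(nes_reference_sample(7, 200, 300, 300),
               nes_comparison_sample(7, 200))
  # with n_peptide = s1 both samples effectively share denominator s2
  expect_equal(nes_reference_sample(9, 144, 144, 613), 9 * 1000 / 613)
})

test_that("fold-change classes use inclusive 1.5x / 0.5x cut-offs", {
  params <- nes_params(s1 = 100, s2 = 100)
  expect_equal(round(params$up_cutoff_log2, 2), 0.58)
  expect_equal(params$down_cutoff_log2, -1)
  expect_equal(classify_fold_change(0, params), "unchanged")
  expect_equal(classify_fold_change(1, params), "up")
  expect_equal(classify_fold_change(-1.5, params), "down")
  expect_equal(classify_fold_change(log2(1.5), params), "up")
  expect_equal(classify_fold_change(-1, params), "down")
  expect_warning(cls <- classify_fold_change(c(0, Inf), params),
                 "non-finite")
  expect_equal(cls[2], "comparison-only")
})

test_that("shared expression table recovers planted inflation exactly", {
  # 100 shared peptides; 30 carry a planted 2x spectral-count inflation in
  # the comparison sample, the rest identical counts
  set.seed(12)
  peps <- sample_peptides_for_test(100)
  sc <- sample(5:40, 100, replace = TRUE)
  inflated <- seq_len(30)
  sc_cmp <- sc
  sc_cmp[inflated] <- sc[inflated] * 2L
  ref <- mini_rep(peps, spectra = sc, id = "ref")
  cmp <- mini_rep(peps, spectra = sc_cmp, id = "cmp")
  tab <- shared_expression_table(ref, cmp)

  # brute-force re-derivation: equal totals, so log2 fc = log2(sc ratio)
  expect_equal(tab$log2_fc,
               log2(tab$sc_cmp / tab$sc_ref))
  up_expected <- sort(peps[inflated])
  expect_setequal(tab$peptide[tab$reg_class == "up"], up_expected)
  expect_true(all(tab$reg_class[!tab$peptide %in% up_expected] ==
                    "unchanged"))
  tally <- tally_classes(tab$reg_class)
  expect_equal(sum(tally), nrow(tab))
})

test_that("single shared peptide with balanced counts is unchanged", {
  ref <- mini_rep(c("AAAAL", "CCCCV"), spectra = c(4L, 9L), id = "ref")
  cmp <- mini_rep(c("AAAAL", "DDDDK"), spectra = c(4L, 2L), id = "cmp")
  tab <- shared_expression_table(ref, cmp)
  expect_equal(nrow(tab), 1L)
  expect_equal(tab$log2_fc, 0)
  expect_equal(tab$reg_class, "unchanged")
  expect_error(
    shared_expression_table(ref, mini_rep("EEEEE", id = "cmp")),
    "no peptides shared"
  )
})

test_that("NES is linear in SC: doubling all counts preserves fold changes", {
  set.seed(13)
  peps <- sample_peptides_for_test(40)
  sc_r <- sample(2:30, 40, replace = TRUE)
  sc_c <- sample(2:60, 40, replace = TRUE)
  t1 <- shared_expression_table(mini_rep(peps, spectra = sc_r, id = "r"),
                                mini_rep(peps, spectra = sc_c, id = "c"))
  t2 <- shared_expression_table(mini_rep(peps, spectra = 2L * sc_r, id = "r"),
                                mini_rep(peps, spectra = 2L * sc_c, id = "c"))
  expect_equal(t2$nes_ref, 2 * t1$nes_ref)
  expect_equal(t2$log2_fc, t1$log2_fc)
  expect_identical(t2$reg_class, t1$reg_class)
})

test_that("protein grouping sums member-peptide spectra and reclassifies", {
  params <- nes_params(s1 = 10, s2 = 10)
  records <- tibble::tibble(
    peptide = c("AAAAL", "CCCCV", "DDDDK"),
    proteins = list("X", "X", "Y"),
    sc_ref = c(3, 2, 5), sc_cmp = c(6, 4, 5),
    nes_ref = NA_real_, nes_cmp = NA_real_,
    log2_fc = NA_real_, reg_class = NA_character_
  )
  out <- group_by_protein(records, params, n_ref = 10, n_cmp = 10)
  expect_equal(out$sc_ref[out$protein == "X"], 5)
  expect_equal(out$sc_cmp[out$protein == "X"], 10)
  expect_equal(out$reg_class[out$protein == "X"], "up")
  expect_equal(out$reg_class[out$protein == "Y"], "unchanged")

  # one peptide per protein: protein classes equal peptide classes
  ref <- mini_rep(c("AAAAL", "CCCCV"), spectra = c(2L, 8L),
                  proteins = list("P1", "P2"), id = "r")
  cmp <- mini_rep(c("AAAAL", "CCCCV"), spectra = c(8L, 2L),
                  proteins = list("P1", "P2"), id = "c")
  tab <- shared_expression_table(ref, cmp)
  p <- nes_params(s1 = n_peptide(ref), s2 = n_peptide(cmp))
  prot <- group_by_protein(tab, p, n_ref = 2, n_cmp = 2)
  expect_equal(prot$reg_class[match(c("P1", "P2"), prot$protein)],
               tab$reg_class[match(c("AAAAL", "CCCCV"), tab$peptide)])
})

test_that("multi-mapped and unassigned peptides are handled as documented", {
  params <- nes_params(s1 = 10, s2 = 10)
  records <- tibble::tibble(
    peptide = c("AAAAL", "CCCCV"),
    proteins = list(c("X", "Y"), character(0)),
    sc_ref = c(4, 2), sc_cmp = c(4, 2),
    nes_ref = NA_real_, nes_cmp = NA_real_,
    log2_fc = NA_real_, reg_class = NA_character_
  )
  expect_warning(full <- group_by_protein(records, params, 10, 10),
                 "unassigned")
  # full counts to every mapped protein
  expect_equal(full$sc_ref[full$protein %in% c("X", "Y")], c(4, 4))
  expect_true("unassigned" %in% full$protein)
  split <- suppressWarnings(
    group_by_protein(records, params, 10, 10, multimap = "split")
  )
  expect_equal(split$sc_ref[split$protein %in% c("X", "Y")], c(2, 2))
})
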