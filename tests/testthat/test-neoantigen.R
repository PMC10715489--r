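test_that("an SNV substitutes one residue with its position recorded", {
  # CDS ATG GCT GAA (MAE); codon 2 GCT -> GTT gives MVE, altered {2}
  model <- hand_model("ATGGCTGAA")
  snv <- tibble::tibble(chrom = "chr1", pos = 1005L, ref = "C", alt = "T",
                        type = "SNV")
  res <- build_mutated_proteome(snv, list(model))
  expect_equal(res$proteins$protein, "MVE")
  expect_equal(res$proteins$altered_positions[[1]], 2L)
  expect_equal(res$proteins$flag, "ok")
})

test_that("minus-strand variants are applied in transcript orientation", {
  # same CDS on the minus strand: genomic slice is the reverse complement,
  # so CDS position 5 (C) sits at genomic end - 5 + 1 with allele G>A
  model <- hand_model("ATGGCTGAA", strand = "-")
  snv <- tibble::tibble(chrom = "chr1", pos = 1005L, ref = "G", alt = "A",
                        type = "SNV")
  res <- build_mutated_proteome(snv, list(model))
  expect_equal(res$proteins$protein, "MVE")
  expect_equal(res$proteins$altered_positions[[1]], 2L)
})

test_that("stop-gains truncate with lost residues recorded as absent", {
  # ATG GAA GCT AAA TAA translates MEAK; G>T at CDS pos 4 makes codon 2 TAA
  model <- hand_model("ATGGAAGCTAAATAA")
  snv <- tibble::tibble(chrom = "chr1", pos = 1004L, ref = "G", alt = "T",
                        type = "SNV")
  res <- build_mutated_proteome(snv, list(model))
  expect_equal(res$proteins$protein, "M")
  expect_equal(res$proteins$flag, "truncation")
  expect_equal(res$proteins$altered_positions[[1]], integer(0))
  expect_equal(res$proteins$absent_positions[[1]], 2:4)
})

test_that("ref mismatches, non-coding and synonymous variants are dropped", {
  model <- hand_model("ATGGCTGAA")
  mism <- tibble::tibble(chrom = "chr1", pos = 1005L, ref = "A", alt = "T",
                         type = "SNV")
  expect_warning(res <- build_mutated_proteome(mism, list(model)),
                 "REF mismatch")
  expect_equal(nrow(res$proteins), 0L)
  expect_equal(res$n_ref_mismatch, 1L)

  outside <- tibble::tibble(chrom = "chr1", pos = 5000L, ref = "A",
                            alt = "T", type = "SNV")
  res2 <- build_mutated_proteome(outside, list(model))
  expect_equal(res2$n_noncoding, 1L)

  # GAA -> GAG is synonymous (E): no mutant protein emitted
  syn <- tibble::tibble(chrom = "chr1", pos = 1009L, ref = "A", alt = "G",
                        type = "SNV")
  expect_equal(nrow(build_mutated_proteome(syn, list(model))$proteins), 0L)

  expect_equal(nrow(build_mutated_proteome(empty_variants(),
                                           list(model))$proteins), 0L)
})

test_that("applying then reverting an SNV restores the reference", {
  model <- hand_model("ATGGCTGAAAAACCC" , id = "T1")
  fwd <- tibble::tibble(chrom = "chr1", pos = 1005L, ref = "C", alt = "T",
                        type = "SNV")
  mut <- build_mutated_proteome(fwd, list(model))
  mutated_model <- hand_model(sub("ATGGC", "ATGGT", model$cds), id = "T1")
  back <- tibble::tibble(chrom = "chr1", pos = 1005L, ref = "T", alt = "C",
                         type = "SNV")
  reverted <- build_mutated_proteome(back, list(mutated_model))
  # reverting reproduces the original reference translation
  expect_equal(reverted$proteins$protein, mut$proteins$ref_protein)
})

test_that("decoy construction reverses every target once", {
  db <- append_decoys(c(p1 = "MAE", p2 = "KLV"))
  expect_length(db, 4L)
  expect_equal(db[["rev_p1"]], "EAM")
  expect_equal(db[["rev_p2"]], "VLK")
  expect_message(append_decoys(c(pal = "ABA")), "palindromic")
  expect_error(append_decoys(c(a = "MA", a = "ML")), "duplicate")
})

test_that("hits require verbatim occurrence covering an altered residue", {
  mutants <- tibble::tibble(
    transcript_id = "TX",
    protein = "MVEKLRSTANDF",
    ref_protein = "MAEKLRSTANDF",
    altered_positions = list(2L),
    absent_positions = list(integer(0)),
    variants = list("chr1:1 A>T"), flag = "ok"
  )
  rep <- mini_rep(c("MVEKL", "LRSTANDF", "VEKLR"))
  hits <- find_mutant_peptides(rep, mutants,
                               exclude_reference_matches = FALSE)
  # LRSTANDF matches positions 5-12 only: no altered coverage, no hit
  expect_setequal(hits$peptide, c("MVEKL", "VEKLR"))
  for (k in seq_len(nrow(hits))) {
    expect_equal(substr(mutants$protein, hits$start[k], hits$end[k]),
                 hits$peptide[k])
  }
  # default reference exclusion also removes reference-matching peptides
  hits2 <- find_mutant_peptides(rep, mutants)
  expect_false("LRSTANDF" %in% hits2$peptide)

  # reference-only input: no mutants, no hits
  expect_equal(nrow(find_mutant_peptides(rep, tibble::tibble(
    transcript_id = character(0), protein = character(0),
    ref_protein = character(0), altered_positions = list(),
    absent_positions = list(), variants = list(), flag = character(0)
  ))), 0L)
})

test_that("spiked variant fixtures are fully recovered with no false hits", {
  for (s in c(31L, 32L)) {
    cfg <- synthetic_config(seed = s)
    fix <- generate_variant_fixture(cfg, dir = tempfile())
    models <- read_gene_models(fix$gtf, fix$cds_fasta)
    mut <- build_mutated_proteome(read_variants(fix$vcf), models)
    expect_equal(mut$n_ref_mismatch, 0L)
    hits <- find_mutant_peptides(fix$repertoire, mut)
    spiked <- fix$truth$peptide[fix$truth$is_mutant]
    expect_true(all(spiked %in% hits$peptide))
    expect_true(all(hits$peptide %in% spiked))
    # brute-force all-substring scan agrees on the hit set
    prot <- mut$proteins[!is.na(mut$proteins$protein), ]
    bf <- character(0)
    for (i in seq_len(nrow(prot))) {
      for (p in peptides(fix$repertoire)) {
        m <- gregexpr(p, prot$protein[i], fixed = TRUE)[[1]]
        if (m[1] == -1) next
        alt <- prot$altered_positions[[i]]
        covers <- any(vapply(m, function(s0) {
          any(alt >= s0 & alt <= s0 + nchar(p) - 1L)
        }, logical(1)))
        in_ref <- any(vapply(unique(prot$ref_protein), function(r) {
          grepl(p, r, fixed = TRUE)
        }, logical(1)))
        if (covers && !in_ref) bf <- c(bf, p)
      }
    }
    expect_setequal(unique(hits$peptide), unique(bf))
  }
})
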