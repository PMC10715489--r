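#' Run the full immunopeptidome characterisation
#'
#' Orchestrates ingest, pairwise set comparison, binder classification
#' with scaled binding scores, length and C-terminal hydrophobicity
#' profiles with pairwise permutation tests (Bonferroni-adjusted),
#' shared-peptide expression analysis between a designated
#' reference/comparison pair, protein-level grouping, and — when variant
#' inputs are supplied — the neoantigen search. All tables are written to
#' `out_dir` as TSV with a JSON run manifest.
#'
#' @param samples Named list of `peptide_repertoire` objects (or of paths
#'   to peptide tables readable with [read_peptide_table()] defaults).
#' @param ranks Named list (same names) of rank-table tibbles or paths
#'   readable with [read_rank_table()] defaults.
#' @param reference,comparison Sample names of the expression pair.
#' @param out_dir Output directory.
#' @param thresholds A [binding_thresholds()].
#' @param alpha Significance level for the permutation tests.
#' @param n_permutations Permutation budget per test.
#' @param seed Seed funnelling all randomness (permutation sampling).
#' @param neoantigen Optional list with `vcf`, `gtf`, `cds_fasta` paths
#'   to run the variant-to-mutated-proteome search on the comparison
#'   repertoire.
#' @return A list with every result table (`venn`, `binding`,
#'   `length_profiles`, `cterm_profiles`, `length_tests`, `cterm_tests`,
#'   `expression`, `expression_test`, `proteins`, `neoantigen_hits`,
#'   `manifest`), invisibly also written under `out_dir`.
#' @export
run_full_characterization <- function(samples, ranks = NULL,
                                      reference, comparison,
                                      out_dir,
                                      thresholds = binding_thresholds(),
                                      alpha = 0.05,
                                      n_permutations = 10000L,
                                      seed = 1L,
                                      neoantigen = NULL) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            !is.null(names(samples)),
            all(c(reference, comparison) %in% names(samples)))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  reps <- lapply(names(samples), function(id) {
    s <- samples[[id]]
    if (inherits(s, "peptide_repertoire")) s else
      read_peptide_table(s, sample_id = id, count_col = "spectra",
                         protein_col = "protein")$repertoire
  })
  names(reps) <- names(samples)

  venn <- multiway_summary(unname(reps)) |>
    dplyr::select(-"partition")
  readr::write_tsv(venn, file.path(out_dir, "venn.tsv"), progress = FALSE)

  binding <- NULL
  if (!is.null(ranks)) {
    binding <- dplyr::bind_rows(lapply(names(reps), function(id) {
      rt <- ranks[[id]]
      if (is.character(rt)) rt <- read_rank_table(rt)
      bs <- binding_summary(reps[[id]], rt, thresholds)
      tibble::tibble(
        sample_id = id, n_strong = bs$n_strong, n_weak = bs$n_weak,
        n_non = bs$n_non, sample_total = bs$sample_total,
        scaled_score = bs$scaled_score
      )
    }))
    readr::write_tsv(binding, file.path(out_dir, "binding_summary.tsv"),
                     progress = FALSE)
  }

  length_profiles <- dplyr::bind_rows(lapply(reps, length_distribution))
  readr::write_tsv(length_profiles,
                   file.path(out_dir, "length_profiles.tsv"),
                   progress = FALSE)

  ct <- lapply(reps, cterm_profile)
  cterm_profiles <- dplyr::bind_rows(lapply(ct, function(p) {
    dplyr::mutate(p$freq, sample_id = p$sample_id,
                  hydrophobic_fraction = p$hydrophobic_fraction,
                  weighted_avg_hydrophobicity =
                    p$weighted_avg_hydrophobicity,
                  .before = 1L)
  }))
  readr::write_tsv(cterm_profiles,
                   file.path(out_dir, "cterm_profiles.tsv"),
                   progress = FALSE)

  cfg <- permutation_config(n_permutations = n_permutations, alpha = alpha,
                            seed = seed)
  length_values <- lapply(reps, function(r) nchar(peptides(r)))
  cterm_values <- lapply(reps, function(r) {
    kd_score(substring(peptides(r), nchar(peptides(r))))
  })
  length_tests <- dplyr::mutate(pairwise_tests(length_values, cfg),
                                metric = "length", .before = 1L)
  cterm_tests <- dplyr::mutate(pairwise_tests(cterm_values, cfg),
                               metric = "cterm_hydrophobicity", .before = 1L)
  readr::write_tsv(dplyr::bind_rows(length_tests, cterm_tests),
                   file.path(out_dir, "permutation_tests.tsv"),
                   progress = FALSE)

  rep_ref <- reps[[reference]]
  rep_cmp <- reps[[comparison]]
  params <- nes_params(s1 = n_peptide(rep_ref), s2 = n_peptide(rep_cmp))
  expression <- shared_expression_table(rep_ref, rep_cmp, params = params)
  expr_out <- dplyr::mutate(expression, proteins = vapply(
    .data$proteins, paste, character(1), collapse = ";"
  ))
  readr::write_tsv(expr_out, file.path(out_dir, "shared_expression.tsv"),
                   progress = FALSE)
  expression_test <- shared_expression_test(expression$nes_ref,
                                            expression$nes_cmp, alpha)
  proteins <- group_by_protein(expression, params,
                               n_ref = n_peptide(rep_ref),
                               n_cmp = n_peptide(rep_cmp))
  readr::write_tsv(proteins, file.path(out_dir, "protein_expression.tsv"),
                   progress = FALSE)

  neo_hits <- NULL
  if (!is.null(neoantigen)) {
    models <- read_gene_models(neoantigen$gtf, neoantigen$cds_fasta)
    variants <- read_variants(neoantigen$vcf)
    mutants <- build_mutated_proteome(variants, models)
    neo_hits <- find_mutant_peptides(rep_cmp, mutants)
    readr::write_tsv(neo_hits, file.path(out_dir, "neoantigen_hits.tsv"),
                     progress = FALSE)
  }

  manifest <- list(
    samples = lapply(reps, function(r) {
      list(sample_id = r$sample_id, n_peptide = n_peptide(r),
           total_spectra = sum(r$table$spectra))
    }),
    reference = reference,
    comparison = comparison,
    parameters = list(
      strong_cutoff = thresholds$strong_cutoff,
      weak_cutoff = thresholds$weak_cutoff,
      up_cutoff_log2 = params$up_cutoff_log2,
      down_cutoff_log2 = params$down_cutoff_log2,
      nes_scaling = params$scaling,
      s1 = params$s1, s2 = params$s2,
      alpha = alpha, n_permutations = n_permutations, seed = seed
    ),
    class_tally = as.list(tally_classes(expression$reg_class)),
    protein_tally = as.list(tally_classes(proteins$reg_class)),
    expression_test = as.list(expression_test),
    package_version = as.character(utils::packageVersion("pepscape"))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(
    repertoires = reps, venn = venn, binding = binding,
    length_profiles = length_profiles, cterm_profiles = cterm_profiles,
    length_tests = length_tests, cterm_tests = cterm_tests,
    expression = expression, expression_test = expression_test,
    proteins = proteins, neoantigen_hits = neo_hits, manifest = manifest
  ))
}
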