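# Fixture generator. Defaults emulate the study conditions of the
# four-line immunopeptidome comparison this pipeline characterises: a
# reference (wild-type-like) repertoire of 144 peptides and a comparison
# (knockout-like) repertoire of 613 peptides sharing 82; the comparison
# sample is 8-mer-rich (53.5%) with a dominant C-terminal leucine (53.3%)
# and a 40% strong-binder fraction, the reference sample longer-tailed
# (37.5% 8-mers) with under 10% strong binders.

default_length_weights_ref <- c(`8` = 0.375, `9` = 0.153, `10` = 0.20,
                                `11` = 0.12, `12` = 0.08, `13` = 0.047,
                                `14` = 0.025)
default_length_weights_cmp <- c(`8` = 0.535, `9` = 0.225, `10` = 0.10,
                                `11` = 0.07, `12` = 0.04, `13` = 0.02,
                                `14` = 0.01)

default_cterm_weights <- function(L, V, M, A) {
  rest <- setdiff(names(KYTE_DOOLITTLE), c("L", "V", "M", "A"))
  w <- setNames(rep((1 - L - V - M - A) / length(rest), length(rest)), rest)
  c(c(L = L, V = V, M = M, A = A), w)
}

#' Synthetic-fixture configuration
#'
#' All knobs of the fixture generators, with defaults emulating the study
#' conditions (sample sizes 144 and 613 sharing 82 peptides; length and
#' C-terminal-residue composition per sample; a gamma-Poisson
#' (negative-binomial-like) spectral-count law shared between samples so
#' shared-peptide counts are correlated; planted log2 fold changes on the
#' shared set; strong/weak binder fractions; a toy genome).
#'
#' @param seed Integer seed (mandatory; every generator is a pure
#'   function of the configuration and this seed).
#' @param n_ref,n_cmp,n_shared Repertoire sizes and shared-set size.
#' @param length_weights_ref,length_weights_cmp Named weights over
#'   lengths 8-14.
#' @param cterm_weights_ref,cterm_weights_cmp Named weights over the 20
#'   residues for the C-terminal position.
#' @param internal_weights Named weights for non-terminal positions
#'   (default uniform).
#' @param count_mean,count_size Mean and dispersion (gamma shape) of the
#'   spectral-count law; counts are `1 + Poisson(gamma base)` so every
#'   identified peptide has at least one spectrum.
#' @param n_up,n_down Numbers of shared peptides planted up/down.
#' @param effect_log2 Magnitude of planted log2 fold changes (default 2).
#' @param strong_fraction,weak_fraction Fractions of peptides drawn as
#'   strong (best rank <= 0.5) and weak (0.5 < rank <= 2) binders.
#' @param n_proteins_shared Number of proteins the shared peptides map to.
#' @param n_transcripts,cds_codons,n_snvs,n_indels Toy-genome spec for the
#'   variant fixture.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(seed,
                             n_ref = 144L, n_cmp = 613L, n_shared = 82L,
                             length_weights_ref = default_length_weights_ref,
                             length_weights_cmp = default_length_weights_cmp,
                             cterm_weights_ref =
                               default_cterm_weights(0.40, 0.05, 0.09, 0.08),
                             cterm_weights_cmp =
                               default_cterm_weights(0.533, 0.103, 0.04, 0.04),
                             internal_weights =
                               setNames(rep(1 / 20, 20),
                                        names(KYTE_DOOLITTLE)),
                             count_mean = 20, count_size = 10,
                             n_up = 58L, n_down = 6L, effect_log2 = 2,
                             strong_fraction = 0.40, weak_fraction = 0.20,
                             n_proteins_shared = 61L,
                             n_transcripts = 4L, cds_codons = c(30L, 60L),
                             n_snvs = 3L, n_indels = 1L) {
  if (missing(seed)) stop("seed is mandatory", call. = FALSE)
  stopifnot(n_shared <= min(n_ref, n_cmp),
            n_up + n_down <= n_shared,
            strong_fraction >= 0, weak_fraction >= 0,
            strong_fraction + weak_fraction <= 1,
            all(length_weights_ref >= 0), all(length_weights_cmp >= 0),
            all(cterm_weights_ref >= 0), all(cterm_weights_cmp >= 0))
  structure(
    list(seed = as.integer(seed), n_ref = n_ref, n_cmp = n_cmp,
         n_shared = n_shared,
         length_weights_ref = length_weights_ref / sum(length_weights_ref),
         length_weights_cmp = length_weights_cmp / sum(length_weights_cmp),
         cterm_weights_ref = cterm_weights_ref / sum(cterm_weights_ref),
         cterm_weights_cmp = cterm_weights_cmp / sum(cterm_weights_cmp),
         internal_weights = internal_weights / sum(internal_weights),
         count_mean = count_mean, count_size = count_size,
         n_up = n_up, n_down = n_down, effect_log2 = effect_log2,
         strong_fraction = strong_fraction, weak_fraction = weak_fraction,
         n_proteins_shared = n_proteins_shared,
         n_transcripts = n_transcripts, cds_codons = cds_codons,
         n_snvs = n_snvs, n_indels = n_indels),
    class = "synthetic_config"
  )
}

sample_peptides <- function(n, length_weights, cterm_weights,
                            internal_weights, exclude = character(0)) {
  out <- character(0)
  lengths_avail <- as.integer(names(length_weights))
  while (length(out) < n) {
    k <- n - length(out)
    lens <- sample(lengths_avail, k, replace = TRUE, prob = length_weights)
    peps <- vapply(lens, function(L) {
      body <- sample(names(internal_weights), L - 1L, replace = TRUE,
                     prob = internal_weights)
      ct <- sample(names(cterm_weights), 1L, prob = cterm_weights)
      paste0(paste(body, collapse = ""), ct)
    }, character(1))
    out <- unique(c(out, setdiff(peps, exclude)))
  }
  out[seq_len(n)]
}

# gamma-Poisson spectral counts: a shared gamma base makes the two
# samples' counts for one peptide correlated; the fold effect scales the
# base of the comparison sample.
nb_counts <- function(base) 1L + stats::rpois(length(base), base)

#' Generate a correlated repertoire pair with planted fold changes
#'
#' @param cfg A [synthetic_config()].
#' @param sample_ref,sample_cmp Sample ids.
#' @return A list: `rep_ref`, `rep_cmp` (`peptide_repertoire`s) and
#'   `truth`, a tibble with one row per generated peptide: `peptide`,
#'   `set` (`"ref_only"`, `"shared"`, `"cmp_only"`), `planted_log2fc`
#'   (`NA` off the shared set), `protein`.
#' @export
generate_repertoire_pair <- function(cfg, sample_ref = "REF",
                                     sample_cmp = "CMP") {
  stopifnot(inherits(cfg, "synthetic_config"))
  set.seed(cfg$seed)

  shared <- sample_peptides(cfg$n_shared, cfg$length_weights_cmp,
                            cfg$cterm_weights_cmp, cfg$internal_weights)
  ref_only <- sample_peptides(cfg$n_ref - cfg$n_shared,
                              cfg$length_weights_ref,
                              cfg$cterm_weights_ref, cfg$internal_weights,
                              exclude = shared)
  cmp_only <- sample_peptides(cfg$n_cmp - cfg$n_shared,
                              cfg$length_weights_cmp,
                              cfg$cterm_weights_cmp, cfg$internal_weights,
                              exclude = c(shared, ref_only))

  fc <- rep(0, cfg$n_shared)
  if (cfg$n_up > 0L) fc[seq_len(cfg$n_up)] <- cfg$effect_log2
  if (cfg$n_down > 0L) {
    fc[cfg$n_up + seq_len(cfg$n_down)] <- -cfg$effect_log2
  }

  base_shared <- stats::rgamma(cfg$n_shared, shape = cfg$count_size,
                               rate = cfg$count_size / cfg$count_mean)
  sc_ref_shared <- nb_counts(base_shared)
  sc_cmp_shared <- nb_counts(base_shared * 2^fc)
  sc_ref_only <- nb_counts(stats::rgamma(length(ref_only),
                                         shape = cfg$count_size,
                                         rate = cfg$count_size / cfg$count_mean))
  sc_cmp_only <- nb_counts(stats::rgamma(length(cmp_only),
                                         shape = cfg$count_size,
                                         rate = cfg$count_size / cfg$count_mean))

  label <- function(prefix, idx) {
    if (length(idx) == 0L) character(0) else
      paste0(prefix, sprintf("%04d", idx))
  }
  prot_shared <- label("PROT", rep_len(seq_len(cfg$n_proteins_shared),
                                       cfg$n_shared))
  prot_ref <- label("PREF", seq_along(ref_only))
  prot_cmp <- label("PCMP", seq_along(cmp_only))

  rep_ref <- peptide_repertoire(
    sample_ref,
    peptides = c(shared, ref_only),
    spectra = c(sc_ref_shared, sc_ref_only),
    proteins = as.list(c(prot_shared, prot_ref))
  )
  rep_cmp <- peptide_repertoire(
    sample_cmp,
    peptides = c(shared, cmp_only),
    spectra = c(sc_cmp_shared, sc_cmp_only),
    proteins = as.list(c(prot_shared, prot_cmp))
  )
  truth <- tibble::tibble(
    peptide = c(shared, ref_only, cmp_only),
    set = c(rep("shared", length(shared)),
            rep("ref_only", length(ref_only)),
            rep("cmp_only", length(cmp_only))),
    planted_log2fc = c(fc, rep(NA_real_, length(ref_only) + length(cmp_only))),
    protein = c(prot_shared, prot_ref, prot_cmp)
  )
  list(rep_ref = rep_ref, rep_cmp = rep_cmp, truth = truth)
}

#' Generate a synthetic binding-rank table for a repertoire
#'
#' Draws a percentile rank per (peptide, allele) so that a configured
#' fraction of peptides falls at or below 0.5 on its best allele (strong),
#' a further fraction in (0.5, 2] (weak), and the rest above 2 on every
#' allele. A crude monotone rank-to-nM map fills the affinity column.
#'
#' @param rep A `peptide_repertoire`.
#' @param cfg A [synthetic_config()].
#' @param strong_fraction,weak_fraction Overrides of the config fractions.
#' @param seed Override of `cfg$seed` (use distinct seeds for distinct
#'   samples).
#' @return A list: `table` (tibble `peptide`, `allele`, `percent_rank`,
#'   `affinity_nm`) and `truth` (tibble `peptide`, `true_class`).
#' @export
generate_rank_table <- function(rep, cfg, strong_fraction = NULL,
                                weak_fraction = NULL, seed = NULL) {
  stopifnot(inherits(rep, "peptide_repertoire"),
            inherits(cfg, "synthetic_config"))
  if (is.null(strong_fraction)) strong_fraction <- cfg$strong_fraction
  if (is.null(weak_fraction)) weak_fraction <- cfg$weak_fraction
  set.seed(if (is.null(seed)) cfg$seed else as.integer(seed))

  peps <- peptides(rep)
  n <- length(peps)
  cls <- sample(c("strong", "weak", "non"), n, replace = TRUE,
                prob = c(strong_fraction, weak_fraction,
                         1 - strong_fraction - weak_fraction))
  ranks <- matrix(runif(n * 6L, min = 2.001, max = 50),
                  nrow = n, ncol = 6L,
                  dimnames = list(NULL, MOUSE_MHC_ALLELES))
  best_allele <- sample(MOUSE_MHC_ALLELES, n, replace = TRUE)
  best_rank <- ifelse(cls == "strong", runif(n, 0.001, 0.5),
                      ifelse(cls == "weak", runif(n, 0.501, 2), NA))
  for (i in which(cls != "non")) {
    ranks[i, best_allele[i]] <- best_rank[i]
  }
  tab <- tibble::tibble(
    peptide = rep(peps, each = 6L),
    allele = rep(MOUSE_MHC_ALLELES, times = n),
    percent_rank = as.vector(t(ranks))
  )
  tab$affinity_nm <- round(5 + 500 * tab$percent_rank, 2)
  list(table = tab, truth = tibble::tibble(peptide = peps, true_class = cls))
}

## ---- toy genome / variant fixture ------------------------------------

CODONS_NO_STOP <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

random_cds <- function(n_codons) {
  paste0("ATG",
         paste(sample(CODONS_NO_STOP, n_codons - 2L, replace = TRUE),
               collapse = ""),
         "TAA")
}

cds_to_genomic <- function(iv, strand, p) {
  widths <- iv$end - iv$start + 1L
  if (strand == "+") {
    cum <- cumsum(widths)
    k <- which(p <= cum)[1]
    off <- p - (if (k > 1L) cum[k - 1L] else 0L)
    iv$start[k] + off - 1L
  } else {
    ordd <- order(iv$start, decreasing = TRUE)
    widths_d <- widths[ordd]
    cum <- cumsum(widths_d)
    k <- which(p <= cum)[1]
    off <- p - (if (k > 1L) cum[k - 1L] else 0L)
    iv$end[ordd[k]] - off + 1L
  }
}

complement1 <- function(x) chartr("ACGT", "TGCA", x)

#' Generate a toy genome, variants and spiked peptides for the
#' neoantigen stage
#'
#' Writes a GTF of CDS features, a CDS FASTA (transcript orientation) and
#' a sites-only VCF into `dir`. Transcripts alternate strand and one is
#' split across two exons. SNVs are planted at known codons with
#' non-synonymous alternates; in-frame single-codon deletions are planted
#' on a plus-strand single-exon transcript. For every variant a spiked
#' peptide covering the altered residue is derived by construction from
#' the known mutated translation, and negative-control peptides are drawn
#' from a variant-free transcript's reference translation.
#'
#' @param cfg A [synthetic_config()].
#' @param dir Output directory (created if needed).
#' @return A list: `gtf`, `cds_fasta`, `vcf` (paths), `repertoire`
#'   (a `peptide_repertoire` of spiked + negative peptides) and `truth`
#'   (tibble `peptide`, `transcript_id`, `is_mutant`).
#' @export
generate_variant_fixture <- function(cfg, dir = tempfile("varfix")) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(cfg$seed)

  n_tx <- max(cfg$n_transcripts, 3L)
  tx <- vector("list", n_tx)
  for (t in seq_len(n_tx)) {
    n_codons <- sample(seq(cfg$cds_codons[1], cfg$cds_codons[2]), 1L)
    cds <- random_cds(n_codons)
    len <- nchar(cds)
    strand <- if (t == 2L) "-" else "+"
    g0 <- 1001L
    if (t == 3L) { # two-exon plus-strand transcript
      k <- (len %/% 2L) + 1L
      iv <- tibble::tibble(start = c(g0, g0 + k + 100L),
                           end = c(g0 + k - 1L, g0 + len + 99L))
    } else {
      iv <- tibble::tibble(start = g0, end = g0 + len - 1L)
    }
    tx[[t]] <- list(transcript_id = sprintf("TX%03d", t),
                    chrom = paste0("chr", t), strand = strand,
                    intervals = iv, cds = cds)
  }

  # plant SNVs on transcripts 1..3 (round-robin), deletions on TX001
  variants <- list()
  spiked <- list()
  mutant_codon <- list()
  snv_targets <- rep_len(c(1L, 2L, 3L), cfg$n_snvs)
  for (s in seq_len(cfg$n_snvs)) {
    t <- snv_targets[s]
    model <- tx[[t]]
    n_codons <- nchar(model$cds) %/% 3L
    # planted codons on one transcript stay >= 10 apart so each spiked
    # peptide window is unaffected by the other variants
    tries <- 0L
    repeat {
      cdn <- sample(2:(n_codons - 1L), 1L)
      prev <- mutant_codon[[model$transcript_id]]
      if (is.null(prev) || all(abs(cdn - prev) >= 10L)) break
      tries <- tries + 1L
      if (tries > 200L) stop("cannot place variant; CDS too short for ",
                             "the requested variant count", call. = FALSE)
    }
    mutant_codon[[model$transcript_id]] <-
      c(mutant_codon[[model$transcript_id]], cdn)
    old_codon <- substr(model$cds, 3L * cdn - 2L, 3L * cdn)
    old_aa <- translate_cds(paste0(old_codon, "TAA"))
    # pick a base change making a different, non-stop amino acid
    found <- FALSE
    for (o in sample(1:3)) {
      p <- 3L * (cdn - 1L) + o
      ref_b <- substr(model$cds, p, p)
      for (alt_b in sample(setdiff(c("A", "C", "G", "T"), ref_b))) {
        new_codon <- old_codon
        substr(new_codon, o, o) <- alt_b
        new_aa <- if (new_codon %in% c("TAA", "TAG", "TGA")) "*" else
          translate_cds(paste0(new_codon, "TAA"))
        if (new_aa != old_aa && new_aa != "*" && nzchar(new_aa)) {
          found <- TRUE
          break
        }
      }
      if (found) break
    }
    stopifnot(found)
    gpos <- cds_to_genomic(model$intervals, model$strand, p)
    if (model$strand == "+") {
      g_ref <- ref_b; g_alt <- alt_b
    } else {
      g_ref <- complement1(ref_b); g_alt <- complement1(alt_b)
    }
    variants[[length(variants) + 1L]] <- tibble::tibble(
      chrom = model$chrom, pos = gpos, ref = g_ref, alt = g_alt
    )
    # construction truth: residue cdn of the translation changes to new_aa
    ref_prot <- translate_cds(model$cds)
    mut_prot <- ref_prot
    substr(mut_prot, cdn, cdn) <- new_aa
    st <- max(1L, min(cdn - 4L, nchar(mut_prot) - 8L))
    spiked[[length(spiked) + 1L]] <- tibble::tibble(
      peptide = substr(mut_prot, st, st + 8L),
      transcript_id = model$transcript_id, is_mutant = TRUE
    )
  }

  for (d in seq_len(cfg$n_indels)) { # in-frame codon deletions on TX001
    model <- tx[[1L]]
    n_codons <- nchar(model$cds) %/% 3L
    tries <- 0L
    repeat {
      cdn <- sample(10:(n_codons - 2L), 1L)
      prev <- mutant_codon[["TX001"]]
      if (is.null(prev) || all(abs(cdn - prev) >= 10L)) break
      tries <- tries + 1L
      if (tries > 200L) stop("cannot place indel; CDS too short for ",
                             "the requested variant count", call. = FALSE)
    }
    mutant_codon[["TX001"]] <- c(mutant_codon[["TX001"]], cdn)
    a <- 3L * (cdn - 1L) # last base of the previous codon = VCF anchor
    ref_seq <- substr(model$cds, a, a + 3L)
    alt_seq <- substr(model$cds, a, a)
    gpos <- cds_to_genomic(model$intervals, model$strand, a)
    variants[[length(variants) + 1L]] <- tibble::tibble(
      chrom = model$chrom, pos = gpos, ref = ref_seq, alt = alt_seq
    )
    ref_prot <- translate_cds(model$cds)
    mut_prot <- paste0(substr(ref_prot, 1L, cdn - 1L),
                       substr(ref_prot, cdn + 1L, nchar(ref_prot)))
    st <- max(1L, min(cdn - 4L, nchar(mut_prot) - 8L))
    spiked[[length(spiked) + 1L]] <- tibble::tibble(
      peptide = substr(mut_prot, st, st + 8L),
      transcript_id = model$transcript_id, is_mutant = TRUE
    )
  }

  # negatives: windows of the last (variant-free) transcript's translation
  neg_model <- tx[[n_tx]]
  neg_prot <- translate_cds(neg_model$cds)
  n_neg <- 5L
  neg_starts <- seq(1L, max(1L, nchar(neg_prot) - 9L),
                    length.out = n_neg) |> round()
  negatives <- tibble::tibble(
    peptide = unique(substr(rep(neg_prot, n_neg), neg_starts,
                            neg_starts + 8L)),
    transcript_id = neg_model$transcript_id, is_mutant = FALSE
  )

  truth <- dplyr::bind_rows(c(spiked, list(negatives))) |>
    dplyr::distinct(.data$peptide, .keep_all = TRUE)

  # emit files
  gtf_path <- file.path(dir, "toy.gtf")
  fasta_path <- file.path(dir, "toy_cds.fa")
  vcf_path <- file.path(dir, "toy.vcf")

  gtf_lines <- unlist(lapply(tx, function(m) {
    sprintf(
      "%s\tpepscape\tCDS\t%d\t%d\t.\t%s\t0\tgene_id \"g_%s\"; transcript_id \"%s\";",
      m$chrom, m$intervals$start, m$intervals$end, m$strand,
      m$transcript_id, m$transcript_id
    )
  }))
  writeLines(gtf_lines, gtf_path)

  cds_records <- setNames(
    vapply(tx, function(m) m$cds, character(1)),
    vapply(tx, function(m) m$transcript_id, character(1))
  )
  write_fasta(cds_records, fasta_path)

  var_tab <- dplyr::bind_rows(variants)
  vcf_lines <- c(
    "##fileformat=VCFv4.2",
    paste0("##contig=<ID=chr", seq_len(n_tx), ">"),
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.",
            var_tab$chrom, var_tab$pos, var_tab$ref, var_tab$alt)
  )
  writeLines(vcf_lines, vcf_path)

  spike_rep <- peptide_repertoire("SPIKE", peptides = truth$peptide)
  list(gtf = gtf_path, cds_fasta = fasta_path, vcf = vcf_path,
       repertoire = spike_rep, truth = truth)
}
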