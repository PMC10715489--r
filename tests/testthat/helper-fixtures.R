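# Small builders used across the suite.

mini_rep <- function(peps, spectra = NULL, proteins = NULL, id = "S") {
  peptide_repertoire(id, peptides = peps, spectra = spectra,
                     proteins = proteins)
}

write_psm_tsv <- function(rows, path = tempfile(fileext = ".tsv"),
                          cols = c("peptide", "protein")) {
  readr::write_tsv(rows, path, progress = FALSE)
  path
}

# Independent exhaustive permutation oracle: enumerate every assignment of
# na pooled values to group A and report the exact two-sided p for the
# absolute mean difference.
perm_oracle <- function(a, b) {
  pool <- c(a, b)
  obs <- abs(mean(a) - mean(b))
  idx <- combn(length(pool), length(a))
  stats <- apply(idx, 2, function(i) {
    abs(mean(pool[i]) - mean(pool[-i]))
  })
  mean(stats >= obs - 1e-12)
}

sample_peptides_for_test <- function(n, len = 9L) {
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, replicate(n, paste(
      sample(c("A", "C", "D", "E", "F", "G", "L", "V"), len,
             replace = TRUE), collapse = ""
    ))))
  }
  out[seq_len(n)]
}

# Hand-built single-exon transcript model (plus or minus strand).
hand_model <- function(cds, strand = "+", chrom = "chr1", g0 = 1001L,
                       id = "TXH") {
  list(transcript_id = id, chrom = chrom, strand = strand,
       intervals = tibble::tibble(start = g0, end = g0 + nchar(cds) - 1L),
       cds = cds, partial = nchar(cds) %% 3L != 0L)
}

empty_variants <- function() {
  tibble::tibble(chrom = character(0), pos = integer(0),
                 ref = character(0), alt = character(0),
                 type = character(0))
}
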