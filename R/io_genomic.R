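#' Read transcript gene models from GTF + CDS FASTA
#'
#' Builds one transcript model per GTF transcript with CDS features: the
#' ordered genomic CDS intervals (1-based, inclusive, per GTF convention),
#' the strand, and the CDS nucleotide sequence taken from the companion
#' FASTA (ENSEMBL `cds.all`-style, already in transcript orientation, i.e.
#' minus-strand CDS reverse-complemented relative to the genome).
#' Transcripts in the GTF with no sequence in the FASTA are skipped with a
#' warning; models whose CDS length is not divisible by 3 are flagged
#' partial.
#'
#' @param gtf_path Path to a GTF file with `CDS` features carrying
#'   `transcript_id` attributes.
#' @param cds_fasta_path Path to a FASTA of CDS sequences named by
#'   transcript id (first whitespace-separated token of the header).
#' @return A named list of transcript models; each model is a list with
#'   `transcript_id`, `chrom`, `strand`, `intervals` (tibble `start`,
#'   `end`, sorted by genomic start), `cds` (character sequence) and
#'   `partial` (logical).
#' @export
read_gene_models <- function(gtf_path, cds_fasta_path) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  gr <- gr[gr$type == "CDS"]
  if (length(gr) == 0L) stop("no CDS features in ", gtf_path, call. = FALSE)
  seqs <- Biostrings::readDNAStringSet(cds_fasta_path)
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)

  models <- list()
  for (tx in unique(gr$transcript_id)) {
    sub <- gr[gr$transcript_id == tx]
    if (!tx %in% names(seqs)) {
      warning("no CDS sequence for transcript ", tx, "; skipped",
              call. = FALSE)
      next
    }
    ord <- order(GenomicRanges::start(sub))
    cds <- as.character(seqs[[tx]])
    iv <- tibble::tibble(
      start = GenomicRanges::start(sub)[ord],
      end = GenomicRanges::end(sub)[ord]
    )
    if (any(iv$start[-1] <= iv$end[-nrow(iv)])) {
      stop("overlapping CDS intervals for transcript ", tx, call. = FALSE)
    }
    if (sum(iv$end - iv$start + 1) != nchar(cds)) {
      warning("CDS length mismatch between GTF and FASTA for ", tx,
              "; skipped", call. = FALSE)
      next
    }
    models[[tx]] <- list(
      transcript_id = tx,
      chrom = as.character(GenomicRanges::seqnames(sub))[1],
      strand = as.character(GenomicRanges::strand(sub))[1],
      intervals = iv,
      cds = cds,
      partial = nchar(cds) %% 3L != 0L
    )
  }
  if (length(models) == 0L) {
    stop("no usable transcript models (GTF/FASTA mismatch?)", call. = FALSE)
  }
  models
}

#' Read variants from a VCF
#'
#' Consumes CHROM/POS/REF/ALT (1-based positions, VCF v4.x); multi-allelic
#' rows are split into one record per alternate allele. Only sequence
#' alleles are kept (symbolic ALTs such as `<DEL>` are dropped with a
#' warning).
#'
#' @param vcf_path Path to a VCF file.
#' @param include_filtered Keep rows whose FILTER is neither PASS nor `.`
#'   (default `TRUE`).
#' @return Tibble with columns `chrom`, `pos`, `ref`, `alt`, `type`
#'   (`"SNV"`, `"insertion"`, `"deletion"`, `"complex"`).
#' @export
read_variants <- function(vcf_path, include_filtered = TRUE) {
  vcf <- suppressMessages(vcfR::read.vcfR(vcf_path, verbose = FALSE))
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  if (nrow(fix) == 0L) {
    return(tibble::tibble(chrom = character(0), pos = integer(0),
                          ref = character(0), alt = character(0),
                          type = character(0)))
  }
  if (!include_filtered) {
    keep <- is.na(fix$FILTER) | fix$FILTER %in% c("PASS", ".")
    fix <- fix[keep, , drop = FALSE]
  }
  out <- tibble::tibble(
    chrom = fix$CHROM,
    pos = as.integer(fix$POS),
    ref = toupper(fix$REF),
    alt = toupper(fix$ALT)
  ) |>
    tidyr::separate_longer_delim("alt", delim = ",")

  symbolic <- grepl("[^ACGTN]", out$alt) | grepl("[^ACGTN]", out$ref)
  if (any(symbolic)) {
    warning(sum(symbolic), " symbolic/non-sequence allele(s) dropped",
            call. = FALSE)
    out <- out[!symbolic, ]
  }
  out <- out[out$ref != out$alt & out$pos >= 1L, ]
  dplyr::mutate(out, type = dplyr::case_when(
    nchar(.data$ref) == 1L & nchar(.data$alt) == 1L ~ "SNV",
    nchar(.data$alt) > nchar(.data$ref) ~ "insertion",
    nchar(.data$alt) < nchar(.data$ref) ~ "deletion",
    TRUE ~ "complex"
  ))
}

#' Write sequences to FASTA, wrapped at 60 columns
#'
#' @param records Named character vector of sequences (amino acid or
#'   nucleotide); names become FASTA headers and must be unique.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.character(records), !is.null(names(records)),
            all(nzchar(names(records))))
  if (anyDuplicated(names(records))) {
    stop("duplicate FASTA headers", call. = FALSE)
  }
  set <- Biostrings::BStringSet(records)
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a FASTA into a named character vector
#'
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  out <- as.character(set)
  names(out) <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  out
}
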