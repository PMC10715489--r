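# Variant-to-mutated-proteome construction and mutant-peptide search.
#
# Coordinate conventions: VCF and GTF are both 1-based inclusive; CDS
# positions are 1-based along the spliced CDS in transcript orientation;
# protein positions are 1-based residues. All variants of a transcript are
# applied to a single haplotype (bulk, unphased variant files carry no
# phase), in 5'->3' transcript order.

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

translate_cds <- function(cds) {
  usable <- (nchar(cds) %/% 3L) * 3L
  if (usable < 3L) return("")
  # no.init.codon: translate codons literally (CTG/TTG are L, not an
  # alternative initiator M); start-codon integrity is checked separately
  aa <- suppressWarnings(as.character(
    Biostrings::translate(Biostrings::DNAString(substr(cds, 1L, usable)),
                          no.init.codon = TRUE, if.fuzzy.codon = "X")
  ))
  sub("\\*.*$", "", aa)
}

# Map a genomic position to its 1-based CDS coordinate for a transcript
# model; NA when the position falls outside the CDS intervals.
genomic_to_cds <- function(model, gpos) {
  iv <- model$intervals
  widths <- iv$end - iv$start + 1L
  hit <- which(gpos >= iv$start & gpos <= iv$end)
  if (length(hit) == 0L) return(NA_integer_)
  if (model$strand == "+") {
    before <- if (hit > 1L) sum(widths[seq_len(hit - 1L)]) else 0L
    before + (gpos - iv$start[hit] + 1L)
  } else {
    # minus strand: 5' end of the transcript is the highest-coordinate exon
    after <- if (hit < nrow(iv)) sum(widths[seq(hit + 1L, nrow(iv))]) else 0L
    after + (iv$end[hit] - gpos + 1L)
  }
}

#' Build a mutated proteome from variants and transcript models
#'
#' Applies each transcript's coding variants to its CDS on one haplotype
#' in 5'->3' transcript order, translates with the standard codon table
#' (truncating at the first stop), and reports the altered residue
#' positions relative to the reference translation. SNVs substitute a
#' base; in-frame indels insert or delete codons; frameshifts translate
#' the shifted frame to its first stop, with every residue from the shift
#' onward counted as altered. Variants whose reference allele does not
#' match the CDS at the mapped position are skipped and counted, as are
#' non-coding variants and variants overlapping an already-applied one.
#' Mutated proteins identical to the reference translation (synonymous
#' changes) are dropped.
#'
#' @param variants Tibble from [read_variants()].
#' @param models Transcript model list from [read_gene_models()].
#' @return A list with `proteins` — tibble `transcript_id`, `protein`,
#'   `ref_protein`, `altered_positions` (list of integer vectors, 1-based
#'   in the mutant protein), `absent_positions` (list; reference residues
#'   lost to truncation), `variants` (list of `chrom:pos ref>alt` labels),
#'   `flag` (`"ok"`, `"start-lost"`, `"truncation"`) — and counts
#'   `n_noncoding`, `n_ref_mismatch`, `n_conflict`.
#' @export
build_mutated_proteome <- function(variants, models) {
  n_noncoding <- 0L
  n_ref_mismatch <- 0L
  n_conflict <- 0L
  rows <- list()

  for (model in models) {
    on_chrom <- variants[variants$chrom == model$chrom, , drop = FALSE]
    if (nrow(on_chrom) == 0L) next
    cds <- toupper(model$cds)

    # map each variant into CDS space; multi-base REFs must sit in one exon
    mapped <- list()
    for (k in seq_len(nrow(on_chrom))) {
      v <- on_chrom[k, ]
      ref_len <- nchar(v$ref)
      p1 <- genomic_to_cds(model, v$pos)
      p2 <- genomic_to_cds(model, v$pos + ref_len - 1L)
      if (is.na(p1) || is.na(p2) || abs(p2 - p1) != ref_len - 1L) {
        n_noncoding <- n_noncoding + 1L
        next
      }
      if (model$strand == "+") {
        cds_start <- p1
        ref_cds <- toupper(v$ref)
        alt_cds <- toupper(v$alt)
      } else {
        cds_start <- p2
        ref_cds <- revcomp(v$ref)
        alt_cds <- revcomp(v$alt)
      }
      if (substr(cds, cds_start, cds_start + ref_len - 1L) != ref_cds) {
        warning("REF mismatch for ", v$chrom, ":", v$pos, " ", v$ref, ">",
                v$alt, " on ", model$transcript_id, "; variant skipped",
                call. = FALSE)
        n_ref_mismatch <- n_ref_mismatch + 1L
        next
      }
      mapped[[length(mapped) + 1L]] <- list(
        cds_start = cds_start, cds_end = cds_start + ref_len - 1L,
        ref = ref_cds, alt = alt_cds,
        label = paste0(v$chrom, ":", v$pos, " ", v$ref, ">", v$alt)
      )
    }
    if (length(mapped) == 0L) next

    # apply 5'->3' with a running offset; overlaps with an applied variant
    # are conflicts and the later variant is skipped
    ord <- order(vapply(mapped, function(m) m$cds_start, integer(1)))
    mapped <- mapped[ord]
    mut <- cds
    offset <- 0L
    last_end <- 0L
    applied <- character(0)
    for (m in mapped) {
      if (m$cds_start <= last_end) {
        warning("conflicting variant ", m$label, " on ",
                model$transcript_id, "; skipped", call. = FALSE)
        n_conflict <- n_conflict + 1L
        next
      }
      s <- m$cds_start + offset
      e <- m$cds_end + offset
      mut <- paste0(substr(mut, 1L, s - 1L), m$alt,
                    substr(mut, e + 1L, nchar(mut)))
      offset <- offset + nchar(m$alt) - nchar(m$ref)
      last_end <- m$cds_end
      applied <- c(applied, m$label)
    }
    if (length(applied) == 0L) next

    ref_prot <- translate_cds(cds)
    mut_prot <- translate_cds(mut)
    if (identical(mut_prot, ref_prot)) next # synonymous only

    if (!nzchar(mut_prot) || substr(mut_prot, 1L, 1L) != "M") {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        transcript_id = model$transcript_id,
        protein = NA_character_, ref_protein = ref_prot,
        altered_positions = list(integer(0)),
        absent_positions = list(seq_len(nchar(ref_prot))),
        variants = list(applied), flag = "start-lost"
      )
      next
    }

    ra <- strsplit(ref_prot, "")[[1]]
    ma <- strsplit(mut_prot, "")[[1]]
    nmin <- min(length(ra), length(ma))
    if (length(ra) == length(ma)) {
      altered <- which(ra != ma)
      absent <- integer(0)
    } else {
      diffs <- which(ra[seq_len(nmin)] != ma[seq_len(nmin)])
      first <- if (length(diffs)) diffs[1L] else nmin + 1L
      altered <- if (first <= length(ma)) seq(first, length(ma)) else integer(0)
      absent <- if (first <= length(ra)) seq(first, length(ra)) else integer(0)
    }
    flag <- if (length(ma) < length(ra) && length(altered) == 0L) {
      "truncation"
    } else {
      "ok"
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      transcript_id = model$transcript_id,
      protein = mut_prot, ref_protein = ref_prot,
      altered_positions = list(altered),
      absent_positions = list(absent),
      variants = list(applied), flag = flag
    )
  }

  proteins <- if (length(rows)) {
    dplyr::bind_rows(rows)
  } else {
    tibble::tibble(
      transcript_id = character(0), protein = character(0),
      ref_protein = character(0), altered_positions = list(),
      absent_positions = list(), variants = list(), flag = character(0)
    )
  }
  list(proteins = proteins, n_noncoding = n_noncoding,
       n_ref_mismatch = n_ref_mismatch, n_conflict = n_conflict)
}

#' Append reversed decoys to a target database
#'
#' For every target sequence one decoy is added whose sequence is the
#' exact reversal and whose id carries the `rev_` prefix — the standard
#' target-decoy construction for FDR estimation in spectral searches.
#'
#' @param targets Named character vector of target sequences (optionally
#'   already including contaminant entries).
#' @param decoy_prefix Id prefix for decoys (default `"rev_"`).
#' @return Named character vector of length `2 * length(targets)`:
#'   targets followed by decoys.
#' @export
append_decoys <- function(targets, decoy_prefix = "rev_") {
  stopifnot(is.character(targets), !is.null(names(targets)))
  if (anyDuplicated(names(targets))) stop("duplicate target ids",
                                          call. = FALSE)
  decoys <- vapply(strsplit(targets, ""), function(s) {
    paste(rev(s), collapse = "")
  }, character(1))
  names(decoys) <- paste0(decoy_prefix, names(targets))
  if (anyDuplicated(c(names(targets), names(decoys)))) {
    stop("id collision after decoy prefixing", call. = FALSE)
  }
  pal <- decoys == targets
  if (any(pal)) {
    message(sum(pal), " palindromic sequence(s): decoy equals target")
  }
  c(targets, decoys)
}

#' Find identified peptides that span mutated residues
#'
#' A hit is a peptide that occurs verbatim in a mutated protein at an
#' interval covering at least one altered residue position; peptides
#' matching only unaltered stretches are not evidence of a mutation and
#' are not hits. All occurrences are reported. By default peptides that
#' also occur in any reference translation are excluded (a
#' reference-matching peptide cannot evidence a mutant).
#'
#' @param rep A `peptide_repertoire`.
#' @param mutants Result of [build_mutated_proteome()] (or its `proteins`
#'   tibble).
#' @param exclude_reference_matches Drop peptides found in a reference
#'   translation (default `TRUE`).
#' @return Tibble of hits: `peptide`, `transcript_id`, `start`, `end`
#'   (1-based residue interval in the mutant protein),
#'   `n_altered_covered`.
#' @export
find_mutant_peptides <- function(rep, mutants,
                                 exclude_reference_matches = TRUE) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  prot <- if (is.data.frame(mutants)) mutants else mutants$proteins
  empty <- tibble::tibble(
    peptide = character(0), transcript_id = character(0),
    start = integer(0), end = integer(0), n_altered_covered = integer(0)
  )
  prot <- prot[!is.na(prot$protein) & lengths(prot$altered_positions) > 0L, ]
  if (nrow(prot) == 0L || n_peptide(rep) == 0L) return(empty)

  peps <- peptides(rep)
  if (exclude_reference_matches) {
    refs <- unique(prot$ref_protein)
    in_ref <- vapply(peps, function(p) {
      any(vapply(refs, function(r) grepl(p, r, fixed = TRUE), logical(1)))
    }, logical(1))
    peps <- peps[!in_ref]
  }
  if (length(peps) == 0L) return(empty)

  rows <- list()
  for (i in seq_len(nrow(prot))) {
    seq_i <- prot$protein[i]
    alt_i <- prot$altered_positions[[i]]
    for (p in peps) {
      starts <- gregexpr(p, seq_i, fixed = TRUE)[[1]]
      if (starts[1] == -1L) next
      for (s in starts) {
        e <- s + nchar(p) - 1L
        covered <- sum(alt_i >= s & alt_i <= e)
        if (covered > 0L) {
          rows[[length(rows) + 1L]] <- tibble::tibble(
            peptide = p, transcript_id = prot$transcript_id[i],
            start = as.integer(s), end = as.integer(e),
            n_altered_covered = as.integer(covered)
          )
        }
      }
    }
  }
  if (length(rows)) dplyr::bind_rows(rows) else empty
}
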