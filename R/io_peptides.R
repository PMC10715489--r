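#' Read a delimited peptide/PSM table into a repertoire
#'
#' Ingests a validated peptide-spectrum-match or peptide table. Rows are
#' aggregated by peptide sequence: spectral counts are summed across rows
#' of the same (case-folded) peptide, so a one-row-per-spectrum PSM table
#' yields spectral counts equal to the number of rows per peptide. Rows
#' whose sequence contains a non-standard residue (B, J, O, U, X, Z, or any
#' other character outside the 20-letter alphabet) are dropped and counted
#' in the returned rejection report rather than imputed.
#'
#' @param path Path to a delimited text file.
#' @param sample_id Sample name to stamp on the repertoire.
#' @param peptide_col Name of the peptide-sequence column (default
#'   `"peptide"`).
#' @param count_col Optional name of an explicit spectral-count column;
#'   when `NULL` (default) every row counts as one spectrum.
#' @param protein_col Optional name of a protein-accession column.
#' @param delim Field delimiter (default tab).
#'
#' @return A list with elements `repertoire` (a [peptide_repertoire()]),
#'   `n_rows` (input rows), `n_rejected` (rows dropped for non-standard
#'   residues or short sequences) and `rejected` (tibble of the offending
#'   rows).
#' @export
read_peptide_table <- function(path, sample_id,
                               peptide_col = "peptide",
                               count_col = NULL,
                               protein_col = NULL,
                               delim = "\t") {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    stop("peptide table is empty: ", path, call. = FALSE)
  }
  if (!peptide_col %in% names(raw)) {
    stop("peptide column '", peptide_col, "' not found in ", path,
         " (columns: ", paste(names(raw), collapse = ", "), ")",
         call. = FALSE)
  }
  if (!is.null(count_col) && !count_col %in% names(raw)) {
    stop("count column '", count_col, "' not found in ", path, call. = FALSE)
  }

  tab <- tibble::tibble(
    peptide = toupper(as.character(raw[[peptide_col]])),
    spectra = if (is.null(count_col)) 1L else as.integer(raw[[count_col]]),
    protein = if (is.null(protein_col) || !protein_col %in% names(raw)) {
      NA_character_
    } else {
      as.character(raw[[protein_col]])
    }
  )

  ok <- grepl(PEPTIDE_REGEX, tab$peptide) & nchar(tab$peptide) >= 5L
  rejected <- tab[!ok, ]
  tab <- tab[ok, ]
  if (nrow(tab) == 0L) {
    stop("all ", nrow(raw), " rows rejected; wrong column mapping?",
         call. = FALSE)
  }
  if (nrow(rejected) / nrow(raw) > 0.5) {
    stop("more than 50% of rows rejected (", nrow(rejected), "/", nrow(raw),
         "); wrong column mapping?", call. = FALSE)
  }

  agg <- tab |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      spectra = sum(.data$spectra),
      proteins = list(as.character(sort(unique(unlist(strsplit(
        .data$protein[!is.na(.data$protein) & nzchar(.data$protein)], ";",
        fixed = TRUE
      )))))),
      .groups = "drop"
    )

  list(
    repertoire = peptide_repertoire(
      sample_id = sample_id,
      peptides = agg$peptide,
      spectra = agg$spectra,
      proteins = agg$proteins
    ),
    n_rows = nrow(raw),
    n_rejected = nrow(rejected),
    rejected = rejected
  )
}

#' Read a binding-prediction rank table
#'
#' Consumes a simple delimited dialect of per-(peptide, allele) predictor
#' output: peptide sequence, allele name, percentile rank and optionally a
#' predicted affinity in nM. Lower percentile ranks mean stronger predicted
#' binding.
#'
#' @param path Path to a delimited file.
#' @param peptide_col,allele_col,rank_col,affinity_col Column names
#'   (affinity optional; set `affinity_col = NULL` if absent).
#' @param delim Field delimiter (default tab).
#' @param known_alleles Character vector of expected allele names; rows with
#'   other alleles are kept with a warning.
#'
#' @return A tibble with columns `peptide`, `allele`, `percent_rank` and
#'   `affinity_nm` (NA when not supplied). Empty input yields an empty
#'   tibble with a warning.
#' @export
read_rank_table <- function(path,
                            peptide_col = "peptide",
                            allele_col = "allele",
                            rank_col = "percent_rank",
                            affinity_col = "affinity_nm",
                            delim = "\t",
                            known_alleles = MOUSE_MHC_ALLELES) {
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (nrow(raw) == 0L) {
    warning("rank table is empty: ", path, call. = FALSE)
    return(tibble::tibble(peptide = character(0), allele = character(0),
                          percent_rank = numeric(0), affinity_nm = numeric(0)))
  }
  for (col in c(peptide_col, allele_col, rank_col)) {
    if (!col %in% names(raw)) {
      stop("column '", col, "' not found in rank table ", path, call. = FALSE)
    }
  }
  out <- tibble::tibble(
    peptide = toupper(as.character(raw[[peptide_col]])),
    allele = as.character(raw[[allele_col]]),
    percent_rank = as.numeric(raw[[rank_col]]),
    affinity_nm = if (!is.null(affinity_col) && affinity_col %in% names(raw)) {
      as.numeric(raw[[affinity_col]])
    } else {
      NA_real_
    }
  )
  if (any(!is.finite(out$percent_rank)) || any(out$percent_rank < 0)) {
    stop("negative or non-finite percentile rank in ", path, call. = FALSE)
  }
  unknown <- setdiff(unique(out$allele), known_alleles)
  if (length(unknown) > 0L) {
    warning("unknown allele(s) in rank table: ",
            paste(unknown, collapse = ", "), call. = FALSE)
  }
  out
}

#' Write a repertoire to a delimited file
#'
#' One row per distinct peptide with its spectral count and
#' semicolon-joined protein accessions; the format [read_peptide_table()]
#' reads back with `count_col = "spectra"`, `protein_col = "protein"`.
#'
#' @param rep A `peptide_repertoire`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(rep, path) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  out <- tibble::tibble(
    peptide = rep$table$peptide,
    spectra = rep$table$spectra,
    protein = vapply(rep$table$proteins, paste, character(1), collapse = ";")
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
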