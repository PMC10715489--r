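#' Construct a peptide repertoire
#'
#' A peptide repertoire is one sample's deduplicated set of identified
#' peptide sequences, each with its spectral count (number of spectra
#' mapping onto the peptide, the label-free abundance proxy) and the set of
#' protein accessions it maps to.
#'
#' @param sample_id Single string naming the sample.
#' @param peptides Character vector of peptide sequences (will be
#'   uppercased; must be unique after uppercasing).
#' @param spectra Integer vector of spectral counts, one per peptide
#'   (default all 1).
#' @param proteins List of character vectors of protein accessions, one
#'   element per peptide (default empty sets).
#'
#' @return An object of class `peptide_repertoire`: a list with elements
#'   `sample_id` and `table` (a tibble with columns `peptide`, `spectra`,
#'   `proteins`).
#' @export
peptide_repertoire <- function(sample_id, peptides, spectra = NULL,
                               proteins = NULL) {
  stopifnot(is.character(sample_id), length(sample_id) == 1L, nzchar(sample_id))
  peptides <- toupper(as.character(peptides))
  if (anyDuplicated(peptides)) {
    stop("peptides must be unique within a repertoire", call. = FALSE)
  }
  bad <- !grepl(PEPTIDE_REGEX, peptides)
  if (any(bad)) {
    stop("non-standard residues in peptides: ",
         paste(head(peptides[bad], 3L), collapse = ", "), call. = FALSE)
  }
  if (any(nchar(peptides) < 5L)) {
    stop("peptides shorter than 5 residues are not valid identifications",
         call. = FALSE)
  }
  if (is.null(spectra)) spectra <- rep(1L, length(peptides))
  spectra <- as.integer(spectra)
  if (length(spectra) != length(peptides) || any(spectra < 1L)) {
    stop("spectra must be positive integers, one per peptide", call. = FALSE)
  }
  if (is.null(proteins)) proteins <- rep(list(character(0)), length(peptides))
  stopifnot(is.list(proteins), length(proteins) == length(peptides))

  tab <- tibble::tibble(
    peptide = peptides,
    spectra = spectra,
    proteins = proteins
  )
  tab <- dplyr::arrange(tab, .data$peptide)
  structure(
    list(sample_id = sample_id, table = tab),
    class = "peptide_repertoire"
  )
}

#' Number of distinct peptides in a repertoire
#'
#' @param rep A `peptide_repertoire`.
#' @return Integer count of distinct peptide sequences (the sample total
#'   used as the normalisation denominator throughout the pipeline).
#' @export
n_peptide <- function(rep) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  nrow(rep$table)
}

#' @export
print.peptide_repertoire <- function(x, ...) {
  cat("<peptide_repertoire> sample:", x$sample_id,
      "| peptides:", nrow(x$table),
      "| total spectra:", sum(x$table$spectra), "\n")
  invisible(x)
}

#' Merge two repertoires of the same sample
#'
#' Represents consolidation of identifications of one sample coming from
#' two search pipelines: the peptide sets are unioned, spectral counts are
#' summed per peptide and protein sets are unioned.
#'
#' @param rep_a,rep_b `peptide_repertoire` objects with identical
#'   `sample_id`.
#' @return A merged `peptide_repertoire`.
#' @export
merge_repertoires <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "peptide_repertoire"),
            inherits(rep_b, "peptide_repertoire"))
  if (!identical(rep_a$sample_id, rep_b$sample_id)) {
    stop("cannot merge repertoires of different samples: '",
         rep_a$sample_id, "' vs '", rep_b$sample_id, "'", call. = FALSE)
  }
  combined <- dplyr::bind_rows(rep_a$table, rep_b$table)
  merged <- combined |>
    dplyr::group_by(.data$peptide) |>
    dplyr::summarise(
      spectra = sum(.data$spectra),
      proteins = list(sort(unique(unlist(.data$proteins)))),
      .groups = "drop"
    )
  peptide_repertoire(
    sample_id = rep_a$sample_id,
    peptides = merged$peptide,
    spectra = merged$spectra,
    proteins = merged$proteins
  )
}

#' Peptide sequences of a repertoire
#' @param rep A `peptide_repertoire`.
#' @return Character vector of distinct peptide sequences, sorted.
#' @export
peptides <- function(rep) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  rep$table$peptide
}
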