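#' Kyte-Doolittle hydropathy scale
#'
#' The canonical residue hydropathy index; positive values are
#' hydrophobic. C-terminal hydrophobicity is a key MHC class-I anchor
#' property: immunoproteasome (chymotryptic) cleavage preferentially
#' yields hydrophobic C-termini.
#'
#' @format Named numeric vector over the 20 standard residues.
#' @export
KYTE_DOOLITTLE <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5,
  Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I = 4.5,
  L = 3.8, K = -3.9, M = 1.9, F = 2.8, P = -1.6,
  S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V = 4.2
)

#' Kyte-Doolittle score of a residue
#'
#' @param residue Character vector of single-letter residue codes.
#' @return Numeric vector of hydropathy scores.
#' @export
kd_score <- function(residue) {
  residue <- toupper(residue)
  bad <- !residue %in% names(KYTE_DOOLITTLE)
  if (any(bad)) {
    stop("non-standard residue(s): ",
         paste(unique(residue[bad]), collapse = ", "), call. = FALSE)
  }
  unname(KYTE_DOOLITTLE[residue])
}

#' Hydrophobic residues (Kyte-Doolittle score > 0)
#' @export
HYDROPHOBIC_AA <- names(KYTE_DOOLITTLE)[KYTE_DOOLITTLE > 0]

#' Length distribution of a repertoire
#'
#' Counts and fractions of peptide lengths over distinct peptide sequences
#' (not spectra-weighted): repertoire composition statements are phrased as
#' percentages of all identified peptides.
#'
#' @param rep A `peptide_repertoire`.
#' @return Tibble with columns `sample_id`, `length`, `count`, `fraction`.
#' @export
length_distribution <- function(rep) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  if (n_peptide(rep) == 0L) stop("empty repertoire", call. = FALSE)
  lens <- nchar(peptides(rep))
  tab <- table(lens)
  tibble::tibble(
    sample_id = rep$sample_id,
    length = as.integer(names(tab)),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(lens)
  )
}

#' C-terminal residue profile of a repertoire
#'
#' Frequency of each residue at the last (C-terminal) position over
#' distinct peptides; the fraction of peptides with a hydrophobic C-terminus
#' (Kyte-Doolittle score > 0); and a weighted average hydrophobicity score.
#' The default weighted average is the mean C-terminal Kyte-Doolittle score
#' over peptides whose C-terminus is hydrophobic (`NA` when no peptide
#' qualifies); `hydro_mean = "all"` averages over every peptide instead.
#'
#' @param rep A `peptide_repertoire`.
#' @param hydro_mean `"hydrophobic-only"` (default) or `"all"`.
#' @return A list: `sample_id`, `freq` (tibble residue/count/fraction,
#'   fractions summing to 1), `hydrophobic_fraction`,
#'   `weighted_avg_hydrophobicity`.
#' @export
cterm_profile <- function(rep, hydro_mean = c("hydrophobic-only", "all")) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  hydro_mean <- match.arg(hydro_mean)
  if (n_peptide(rep) == 0L) stop("empty repertoire", call. = FALSE)
  ct <- substring(peptides(rep), nchar(peptides(rep)))
  scores <- kd_score(ct)
  tab <- table(factor(ct, levels = names(KYTE_DOOLITTLE)))
  freq <- tibble::tibble(
    residue = names(tab),
    count = as.integer(tab),
    fraction = as.integer(tab) / length(ct)
  )
  hydro <- scores > 0
  wavg <- if (hydro_mean == "all") {
    mean(scores)
  } else if (any(hydro)) {
    mean(scores[hydro])
  } else {
    NA_real_
  }
  list(
    sample_id = rep$sample_id,
    freq = freq,
    hydrophobic_fraction = mean(hydro),
    weighted_avg_hydrophobicity = wavg
  )
}
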