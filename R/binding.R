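#' @title Binder classification from percentile ranks
#' @description Peptides are classed against predictor percentile ranks:
#'   lower rank means stronger predicted binding. The conventional cut-offs
#'   are 0.5 (strong) and 2 (weak); both boundaries are inclusive.
#' @name binding
NULL

#' The six classical mouse MHC class-I alleles
#'
#' Fixed allele order used for deterministic tie-breaking when two alleles
#' give a peptide the same minimum rank.
#' @export
MOUSE_MHC_ALLELES <- c("H2-Db", "H2-Dd", "H2-Kb", "H2-Kd", "H2-Kk", "H2-Ld")

#' Binder-classification thresholds
#'
#' @param strong_cutoff Percentile rank at or below which a peptide is a
#'   strong binder (default 0.5).
#' @param weak_cutoff Percentile rank at or below which a peptide is at
#'   least a weak binder (default 2).
#' @return A `binding_thresholds` list.
#' @export
binding_thresholds <- function(strong_cutoff = 0.5, weak_cutoff = 2.0) {
  stopifnot(strong_cutoff > 0, strong_cutoff < weak_cutoff)
  structure(list(strong_cutoff = strong_cutoff, weak_cutoff = weak_cutoff),
            class = "binding_thresholds")
}

#' Classify a percentile rank as strong/weak/non-binder
#'
#' @param percent_rank Numeric vector of percentile ranks (>= 0).
#' @param thresholds A [binding_thresholds()] object.
#' @return Character vector in `c("strong", "weak", "non")`.
#' @export
classify_binder <- function(percent_rank, thresholds = binding_thresholds()) {
  if (any(!is.finite(percent_rank)) || any(percent_rank < 0)) {
    stop("percentile ranks must be finite and non-negative", call. = FALSE)
  }
  dplyr::case_when(
    percent_rank <= thresholds$strong_cutoff ~ "strong",
    percent_rank <= thresholds$weak_cutoff ~ "weak",
    TRUE ~ "non"
  )
}

#' Best binder class per peptide across alleles
#'
#' For each peptide the minimum percentile rank over all supplied alleles
#' determines its class (standard ligandomics practice: a peptide binds if
#' any allele binds it). Rank ties between alleles are broken by the fixed
#' allele order of [MOUSE_MHC_ALLELES], then lexicographically.
#'
#' @param preds Tibble as returned by [read_rank_table()]: columns
#'   `peptide`, `allele`, `percent_rank`.
#' @param thresholds A [binding_thresholds()] object.
#' @param alleles Optional character vector restricting which alleles are
#'   considered (e.g. `"H2-Kb"` alone).
#' @return Tibble with one row per peptide: `peptide`, `best_allele`,
#'   `min_rank`, `binder_class`.
#' @export
best_class_per_peptide <- function(preds, thresholds = binding_thresholds(),
                                   alleles = NULL) {
  stopifnot(all(c("peptide", "allele", "percent_rank") %in% names(preds)))
  if (!is.null(alleles)) {
    preds <- dplyr::filter(preds, .data$allele %in% alleles)
  }
  if (nrow(preds) == 0L) {
    return(tibble::tibble(peptide = character(0), best_allele = character(0),
                          min_rank = numeric(0), binder_class = character(0)))
  }
  allele_rank <- match(preds$allele, MOUSE_MHC_ALLELES)
  # unknown alleles sort after the six canonical ones, alphabetically
  ord <- order(preds$peptide, preds$percent_rank,
               is.na(allele_rank), allele_rank, preds$allele)
  best <- preds[ord, ][!duplicated(preds$peptide[ord]), ]
  tibble::tibble(
    peptide = best$peptide,
    best_allele = best$allele,
    min_rank = best$percent_rank,
    binder_class = classify_binder(best$percent_rank, thresholds)
  )
}

#' Scaled binding score
#'
#' The number of strong binders expressed as a percentage of the sample's
#' total peptide number: `n_strong * 100 / sample_total`. Scaling by the
#' sample size makes strong-binder burdens comparable between repertoires
#' of very different depth.
#'
#' @param n_strong Number of strong binders in the sample.
#' @param sample_total Total number of distinct peptides in the sample.
#' @return The score in percent, in `[0, 100]`.
#' @export
scaled_binding_score <- function(n_strong, sample_total) {
  if (sample_total <= 0) stop("sample_total must be positive", call. = FALSE)
  stopifnot(n_strong >= 0, n_strong <= sample_total)
  n_strong * 100 / sample_total
}

#' Per-sample binding summary
#'
#' Classifies every peptide of a repertoire from a rank table and derives
#' the scaled binding score. Peptides absent from the rank table are, by
#' default, counted as non-binders and listed in `missing_predictions`
#' (they still contribute to the denominator).
#'
#' @param rep A `peptide_repertoire`.
#' @param preds Rank table tibble ([read_rank_table()]).
#' @param thresholds A [binding_thresholds()] object.
#' @param alleles Optional allele restriction passed to
#'   [best_class_per_peptide()].
#' @param drop_missing If `TRUE`, peptides without predictions are removed
#'   from the denominator instead of being counted as non-binders.
#' @return A list: `sample_id`, `n_strong`, `n_weak`, `n_non`,
#'   `sample_total`, `scaled_score`, `per_peptide` (classification tibble),
#'   `missing_predictions` (character vector).
#' @export
binding_summary <- function(rep, preds, thresholds = binding_thresholds(),
                            alleles = NULL, drop_missing = FALSE) {
  stopifnot(inherits(rep, "peptide_repertoire"))
  cls <- best_class_per_peptide(preds, thresholds, alleles)
  cls <- cls[cls$peptide %in% peptides(rep), ]
  missing <- setdiff(peptides(rep), cls$peptide)
  if (!drop_missing && length(missing) > 0L) {
    cls <- dplyr::bind_rows(cls, tibble::tibble(
      peptide = missing, best_allele = NA_character_,
      min_rank = NA_real_, binder_class = "non"
    ))
  }
  total <- if (drop_missing) nrow(cls) else n_peptide(rep)
  n_strong <- sum(cls$binder_class == "strong")
  list(
    sample_id = rep$sample_id,
    n_strong = n_strong,
    n_weak = sum(cls$binder_class == "weak"),
    n_non = sum(cls$binder_class == "non"),
    sample_total = total,
    scaled_score = scaled_binding_score(n_strong, total),
    per_peptide = dplyr::arrange(cls, .data$peptide),
    missing_predictions = sort(missing)
  )
}
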