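#' Normalised Expression Score parameters
#'
#' NES rescales a peptide's raw spectral count by the sample's total
#' peptide number, times a fixed scaling factor of 1000 so scores read at
#' two decimal places. The reference (larger-denominator) sample
#' additionally carries the correction factor `s1/s2` (reference total /
#' comparison total), which corrects for overestimation of the smaller
#' sample's scores due to its smaller denominator. Fold changes are
#' classified as up at or above 1.5-fold (log2 fold change 0.58) and down
#' at or below 0.5-fold (log2 fold change -1).
#'
#' @param s1 Total peptide number of the reference sample.
#' @param s2 Total peptide number of the comparison sample.
#' @param up_cutoff_log2 Upregulation cut-off (default `log2(1.5)`,
#'   reported as 0.58).
#' @param down_cutoff_log2 Downregulation cut-off (default -1).
#' @param scaling Scaling factor (default 1000).
#' @return An `nes_params` list.
#' @export
nes_params <- function(s1, s2, up_cutoff_log2 = log2(1.5),
                       down_cutoff_log2 = -1, scaling = 1000) {
  stopifnot(s1 > 0, s2 > 0, up_cutoff_log2 > 0, down_cutoff_log2 < 0)
  structure(
    list(s1 = s1, s2 = s2, up_cutoff_log2 = up_cutoff_log2,
         down_cutoff_log2 = down_cutoff_log2, scaling = scaling),
    class = "nes_params"
  )
}

#' NES of the comparison sample
#'
#' `SC * 1000 / n_peptide` — the spectral count scaled by the sample's own
#' total peptide number.
#'
#' @param sc Raw spectral count(s).
#' @param n_peptide Total distinct peptides in the sample.
#' @param scaling Scaling factor (default 1000).
#' @return Numeric NES value(s).
#' @export
nes_comparison_sample <- function(sc, n_peptide, scaling = 1000) {
  if (n_peptide <= 0) stop("n_peptide must be positive", call. = FALSE)
  stopifnot(all(sc >= 0))
  sc * scaling / n_peptide
}

#' NES of the reference sample
#'
#' `SC * 1000 / n_peptide * (s1 / s2)`. With `s1` equal to the reference
#' sample's own total, this reduces to `SC * 1000 / s2`, i.e. both samples
#' effectively share the comparison sample's denominator.
#'
#' @param sc Raw spectral count(s).
#' @param n_peptide Total distinct peptides in the reference sample.
#' @param s1,s2 Totals of the reference and comparison samples.
#' @param scaling Scaling factor (default 1000).
#' @return Numeric NES value(s).
#' @export
nes_reference_sample <- function(sc, n_peptide, s1, s2, scaling = 1000) {
  if (n_peptide <= 0 || s1 <= 0 || s2 <= 0) {
    stop("n_peptide, s1 and s2 must be positive", call. = FALSE)
  }
  stopifnot(all(sc >= 0))
  sc * scaling / n_peptide * (s1 / s2)
}

#' Classify a log2 fold change
#'
#' Up at or above the 1.5-fold cut-off (log2 = 0.58), down at or below the
#' 0.5-fold cut-off (log2 = -1), otherwise unchanged; both boundaries
#' inclusive. Non-finite fold changes (zero reference NES) are classed
#' `"comparison-only"` and excluded from the three-way tally.
#'
#' @param log2_fc Numeric vector of log2 fold changes.
#' @param params An [nes_params()] object (only the cut-offs are used).
#' @return Character vector in
#'   `c("up", "down", "unchanged", "comparison-only")`.
#' @export
classify_fold_change <- function(log2_fc, params) {
  stopifnot(inherits(params, "nes_params"))
  out <- dplyr::case_when(
    !is.finite(log2_fc) ~ "comparison-only",
    log2_fc >= params$up_cutoff_log2 ~ "up",
    log2_fc <= params$down_cutoff_log2 ~ "down",
    TRUE ~ "unchanged"
  )
  if (any(out == "comparison-only")) {
    warning(sum(out == "comparison-only"),
            " non-finite fold change(s) excluded from the up/down/unchanged",
            " tally", call. = FALSE)
  }
  out
}

#' Shared-peptide expression table
#'
#' For every peptide shared between a reference and a comparison
#' repertoire: raw spectral counts, NES in each sample (reference NES
#' carries the `s1/s2` correction with `s1`/`s2` the two samples' total
#' peptide numbers), the log2 fold change `log2(NES_cmp / NES_ref)` and
#' its regulation class.
#'
#' @param rep_ref,rep_cmp Reference and comparison
#'   `peptide_repertoire` objects.
#' @param partition Optional precomputed
#'   [partition_repertoires()] of the same two repertoires.
#' @param params Optional [nes_params()]; defaults to the cut-offs above
#'   with `s1`/`s2` taken from the repertoires.
#' @return Tibble with one row per shared peptide: `peptide`, `proteins`
#'   (list), `sc_ref`, `sc_cmp`, `nes_ref`, `nes_cmp`, `log2_fc`,
#'   `reg_class`.
#' @export
shared_expression_table <- function(rep_ref, rep_cmp, partition = NULL,
                                    params = NULL) {
  stopifnot(inherits(rep_ref, "peptide_repertoire"),
            inherits(rep_cmp, "peptide_repertoire"))
  if (is.null(partition)) {
    partition <- partition_repertoires(rep_ref, rep_cmp)
  }
  shared <- partition$shared
  if (length(shared) == 0L) {
    stop("no peptides shared between '", rep_ref$sample_id, "' and '",
         rep_cmp$sample_id, "'", call. = FALSE)
  }
  if (is.null(params)) {
    params <- nes_params(s1 = n_peptide(rep_ref), s2 = n_peptide(rep_cmp))
  }
  ref_tab <- rep_ref$table[match(shared, rep_ref$table$peptide), ]
  cmp_tab <- rep_cmp$table[match(shared, rep_cmp$table$peptide), ]
  prot <- purrr::map2(ref_tab$proteins, cmp_tab$proteins,
                      function(a, b) sort(unique(c(a, b))))
  nes_ref <- nes_reference_sample(ref_tab$spectra, n_peptide(rep_ref),
                                  params$s1, params$s2, params$scaling)
  nes_cmp <- nes_comparison_sample(cmp_tab$spectra, n_peptide(rep_cmp),
                                   params$scaling)
  log2_fc <- log2(nes_cmp / nes_ref)
  tibble::tibble(
    peptide = shared,
    proteins = prot,
    sc_ref = ref_tab$spectra,
    sc_cmp = cmp_tab$spectra,
    nes_ref = nes_ref,
    nes_cmp = nes_cmp,
    log2_fc = log2_fc,
    reg_class = classify_fold_change(log2_fc, params)
  )
}

#' Group a shared-peptide expression table by protein of origin
#'
#' Spectral counts of all peptides mapping to a protein are summed per
#' sample as a total measure of that protein's expression; NES and the
#' fold-change class are recomputed on the summed counts with the same
#' parameters. A peptide mapping to several proteins contributes its full
#' counts to each of them by default (`multimap = "full"`);
#' `multimap = "split"` divides its counts evenly instead. Records with no
#' protein accession are routed to an `"unassigned"` bin with a warning.
#'
#' @param records Tibble from [shared_expression_table()].
#' @param params The [nes_params()] used for the peptide table (required:
#'   protein NES needs the same denominators).
#' @param n_ref,n_cmp Total peptide numbers of the two repertoires (NES
#'   denominators).
#' @param multimap `"full"` (default) or `"split"`.
#' @return Tibble with one row per protein: `protein`, `n_peptides`,
#'   `sc_ref`, `sc_cmp`, `nes_ref`, `nes_cmp`, `log2_fc`, `reg_class`.
#' @export
group_by_protein <- function(records, params, n_ref, n_cmp,
                             multimap = c("full", "split")) {
  multimap <- match.arg(multimap)
  stopifnot(inherits(params, "nes_params"))
  empty <- lengths(records$proteins) == 0L
  if (any(empty)) {
    warning(sum(empty), " peptide(s) without protein accession routed to",
            " 'unassigned'", call. = FALSE)
  }
  long <- records |>
    dplyr::mutate(proteins = purrr::map(.data$proteins, function(p) {
      if (length(p) == 0L) "unassigned" else p
    })) |>
    tidyr::unnest_longer("proteins", values_to = "protein") |>
    dplyr::group_by(.data$peptide) |>
    dplyr::mutate(weight = if (multimap == "split") 1 / dplyr::n() else 1) |>
    dplyr::ungroup()

  out <- long |>
    dplyr::group_by(.data$protein) |>
    dplyr::summarise(
      n_peptides = dplyr::n_distinct(.data$peptide),
      sc_ref = sum(.data$sc_ref * .data$weight),
      sc_cmp = sum(.data$sc_cmp * .data$weight),
      .groups = "drop"
    )
  nes_ref <- nes_reference_sample(out$sc_ref, n_ref, params$s1, params$s2,
                                  params$scaling)
  nes_cmp <- nes_comparison_sample(out$sc_cmp, n_cmp, params$scaling)
  log2_fc <- log2(nes_cmp / nes_ref)
  dplyr::mutate(out,
    nes_ref = nes_ref, nes_cmp = nes_cmp, log2_fc = log2_fc,
    reg_class = classify_fold_change(log2_fc, params)
  )
}

#' Tally regulation classes
#'
#' @param reg_class Character vector of classes.
#' @return Named integer vector over up/down/unchanged/comparison-only.
#' @export
tally_classes <- function(reg_class) {
  lv <- c("up", "down", "unchanged", "comparison-only")
  tab <- table(factor(reg_class, levels = lv))
  setNames(as.integer(tab), lv)
}
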