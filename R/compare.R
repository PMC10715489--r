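#' Partition two repertoires into unique and shared peptide sets
#'
#' Presence/absence set comparison of two samples' peptide repertoires —
#' the Venn partition underlying between-condition ligandome comparisons.
#' Spectral counts play no role here; downstream expression analysis
#' consumes the shared set.
#'
#' @param rep_a,rep_b `peptide_repertoire` objects.
#' @return An object of class `repertoire_partition`: list with
#'   `sample_a`, `sample_b`, and sorted character vectors `unique_a`,
#'   `shared`, `unique_b`.
#' @export
partition_repertoires <- function(rep_a, rep_b) {
  stopifnot(inherits(rep_a, "peptide_repertoire"),
            inherits(rep_b, "peptide_repertoire"))
  pa <- peptides(rep_a)
  pb <- peptides(rep_b)
  structure(
    list(
      sample_a = rep_a$sample_id,
      sample_b = rep_b$sample_id,
      unique_a = sort(setdiff(pa, pb)),
      shared = sort(intersect(pa, pb)),
      unique_b = sort(setdiff(pb, pa))
    ),
    class = "repertoire_partition"
  )
}

#' @export
print.repertoire_partition <- function(x, ...) {
  cat("<repertoire_partition>", x$sample_a, "vs", x$sample_b, "\n",
      " unique to", paste0(x$sample_a, ":"), length(x$unique_a), "\n",
      " shared:", length(x$shared), "\n",
      " unique to", paste0(x$sample_b, ":"), length(x$unique_b), "\n")
  invisible(x)
}

#' Pairwise partition summary across many repertoires
#'
#' One set partition per unordered pair of samples, summarised as counts.
#'
#' @param reps List of `peptide_repertoire` objects with distinct
#'   `sample_id`s.
#' @return A tibble with one row per unordered pair: `sample_a`,
#'   `sample_b`, `n_unique_a`, `n_shared`, `n_unique_b`, plus the
#'   partitions themselves in a list column `partition`.
#' @export
multiway_summary <- function(reps) {
  stopifnot(is.list(reps), length(reps) >= 2L)
  ids <- vapply(reps, function(r) r$sample_id, character(1))
  if (anyDuplicated(ids)) {
    stop("duplicate sample_id among repertoires: ",
         paste(ids[duplicated(ids)], collapse = ", "), call. = FALSE)
  }
  pairs <- combn(seq_along(reps), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    part <- partition_repertoires(reps[[i]], reps[[j]])
    tibble::tibble(
      sample_a = part$sample_a,
      sample_b = part$sample_b,
      n_unique_a = length(part$unique_a),
      n_shared = length(part$shared),
      n_unique_b = length(part$unique_b),
      partition = list(part)
    )
  })
  dplyr::bind_rows(rows)
}

#' Write a partition's peptide lists and counts
#'
#' @param part A `repertoire_partition`.
#' @param path Output TSV path for the count row; per-set peptide list
#'   files are written next to it with suffixes `.unique_a.txt`,
#'   `.shared.txt`, `.unique_b.txt`.
#' @return `path`, invisibly.
#' @export
write_partition <- function(part, path) {
  stopifnot(inherits(part, "repertoire_partition"))
  counts <- tibble::tibble(
    pair = paste(part$sample_a, part$sample_b, sep = "_vs_"),
    unique_a = length(part$unique_a),
    shared = length(part$shared),
    unique_b = length(part$unique_b)
  )
  readr::write_tsv(counts, path, progress = FALSE)
  writeLines(part$unique_a, paste0(path, ".unique_a.txt"))
  writeLines(part$shared, paste0(path, ".shared.txt"))
  writeLines(part$unique_b, paste0(path, ".unique_b.txt"))
  invisible(path)
}
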