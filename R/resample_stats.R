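#' Permutation-test configuration
#'
#' @param n_permutations Number of sampled relabelings (default 10000).
#'   When the number of distinct group-A index sets is at most this, the
#'   test enumerates all of them exactly instead of sampling.
#' @param statistic `"mean_difference"` (default) or `"median_difference"`.
#' @param alpha Significance level (default 0.05, i.e. 95% confidence).
#' @param seed Integer seed for the sampled mode.
#' @return A `permutation_config` list.
#' @export
permutation_config <- function(n_permutations = 10000L,
                               statistic = c("mean_difference",
                                             "median_difference"),
                               alpha = 0.05, seed = 1L) {
  statistic <- match.arg(statistic)
  stopifnot(n_permutations >= 100L, alpha > 0, alpha < 1)
  structure(
    list(n_permutations = as.integer(n_permutations), statistic = statistic,
         alpha = alpha, seed = as.integer(seed)),
    class = "permutation_config"
  )
}

stat_fun <- function(statistic) {
  switch(statistic,
    mean_difference = function(a, b) mean(a) - mean(b),
    median_difference = function(a, b) median(a) - median(b)
  )
}

#' Two-sample permutation test
#'
#' Two-sided test of a location difference between two samples by
#' relabeling the pooled values. When all distinct assignments of group
#' labels can be enumerated within the permutation budget, the exact
#' permutation p-value is returned (the fraction of arrangements whose
#' absolute statistic reaches the observed one — the identity arrangement
#' included, so p is never 0). Otherwise `n_permutations` random
#' relabelings are drawn and the add-one estimator
#' `(1 + #{|null| >= |obs|}) / (B + 1)` is used.
#'
#' @param values_a,values_b Numeric vectors (each non-empty, at least 2
#'   values pooled).
#' @param cfg A [permutation_config()].
#' @return A tibble row: `observed`, `p_value`, `n_permutations`, `method`
#'   (`"exhaustive"` or `"sampled"`), `statistic`.
#' @export
permutation_test <- function(values_a, values_b, cfg = permutation_config()) {
  stopifnot(inherits(cfg, "permutation_config"))
  if (length(values_a) < 1L || length(values_b) < 1L ||
      length(values_a) + length(values_b) < 2L) {
    stop("each group needs values and the pool at least 2", call. = FALSE)
  }
  f <- stat_fun(cfg$statistic)
  obs <- f(values_a, values_b)
  pool <- c(values_a, values_b)
  n <- length(pool)
  na <- length(values_a)
  n_arr <- choose(n, na)

  if (n_arr <= cfg$n_permutations) {
    idx <- combn(n, na)
    null_stats <- apply(idx, 2L, function(i) f(pool[i], pool[-i]))
    p <- mean(abs(null_stats) >= abs(obs) - 1e-12)
    method <- "exhaustive"
    used <- ncol(idx)
  } else {
    old_seed <- if (exists(".Random.seed", envir = globalenv())) {
      get(".Random.seed", envir = globalenv())
    }
    set.seed(cfg$seed)
    on.exit(if (!is.null(old_seed)) {
      assign(".Random.seed", old_seed, envir = globalenv())
    })
    null_stats <- vapply(seq_len(cfg$n_permutations), function(k) {
      i <- sample.int(n, na)
      f(pool[i], pool[-i])
    }, numeric(1))
    p <- (1 + sum(abs(null_stats) >= abs(obs) - 1e-12)) /
      (cfg$n_permutations + 1)
    method <- "sampled"
    used <- cfg$n_permutations
  }
  tibble::tibble(
    observed = obs, p_value = p, n_permutations = used,
    method = method, statistic = cfg$statistic
  )
}

#' Pairwise permutation tests with Bonferroni correction
#'
#' One two-sample permutation test per unordered pair of samples; raw
#' p-values are Bonferroni-adjusted over the number of pairs
#' (`min(1, p * n_pairs)`).
#'
#' @param samples Named list of numeric vectors, one per sample.
#' @param cfg A [permutation_config()].
#' @return Tibble with one row per pair: `sample_a`, `sample_b`,
#'   `observed`, `p_value`, `p_adjusted`, `significant` (at `cfg$alpha`),
#'   `n_permutations`, `method`.
#' @export
pairwise_tests <- function(samples, cfg = permutation_config()) {
  stopifnot(is.list(samples), length(samples) >= 2L,
            !is.null(names(samples)), all(nzchar(names(samples))))
  ids <- names(samples)
  pairs <- combn(length(samples), 2L)
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    res <- permutation_test(samples[[i]], samples[[j]], cfg)
    dplyr::mutate(res, sample_a = ids[i], sample_b = ids[j],
                  .before = "observed")
  })
  out <- dplyr::bind_rows(rows)
  out$p_adjusted <- pmin(1, out$p_value * ncol(pairs))
  out$significant <- out$p_adjusted < cfg$alpha
  dplyr::relocate(out, "p_adjusted", "significant", .after = "p_value")
}

#' Expression test on the shared-peptide set
#'
#' Compares the normalised expression scores of the peptides shared
#' between two samples. Both a Wilcoxon rank-sum test and a Welch
#' unequal-variance t-test are computed; the rank-sum result is the
#' headline (it makes no normality assumption on spectral-count-derived
#' scores), the Welch test is reported alongside.
#'
#' @param nes_ref,nes_cmp Numeric vectors of per-peptide scores in the
#'   reference and comparison sample (same shared peptides, same order).
#' @param alpha Significance level (default 0.05).
#' @return A tibble row: `n_shared`, `wilcoxon_p`, `welch_p`, `headline_p`
#'   (= Wilcoxon), `significant`, `degenerate` (all values tied).
#' @export
shared_expression_test <- function(nes_ref, nes_cmp, alpha = 0.05) {
  stopifnot(length(nes_ref) == length(nes_cmp))
  if (length(nes_ref) < 3L) {
    stop("need at least 3 shared peptides for an expression test",
         call. = FALSE)
  }
  degenerate <- length(unique(c(nes_ref, nes_cmp))) == 1L
  if (degenerate) {
    warning("all scores tied; rank-sum p reported as 1", call. = FALSE)
    wp <- 1
    tp <- 1
  } else {
    wp <- suppressWarnings(
      wilcox.test(nes_cmp, nes_ref, alternative = "two.sided")$p.value
    )
    tp <- t.test(nes_cmp, nes_ref, var.equal = FALSE)$p.value
  }
  tibble::tibble(
    n_shared = length(nes_ref),
    wilcoxon_p = wp, welch_p = tp, headline_p = wp,
    significant = wp < alpha, degenerate = degenerate
  )
}
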