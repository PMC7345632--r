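#' Upper binomial tail probability
#'
#' P(X >= k) for X ~ Binomial(n, p): the probability of seeing at least the
#' observed number of alternate reads if every alternate base were a
#' sequencing error with per-read probability `p`.
#'
#' @param k observed count (0 <= k <= n).
#' @param n number of trials (coverage).
#' @param p per-trial success probability, in (0, 1).
#' @return P(X >= k); 1 when `k = 0`.
#' @examples
#' binomial_tail(3, 10, 0.01)
#' @export
binomial_tail <- function(k, n, p) {
  if (any(p <= 0 | p >= 1)) stopf("p must be in (0,1)")
  if (any(k < 0 | n < 0 | k > n)) stopf("need 0 <= k <= n")
  stats::pbinom(k - 1, n, p, lower.tail = FALSE)
}

#' Per-substitution binomial tests for one or more pileup sites
#'
#' For each alternate base with at least one supporting read, tests the
#' observed count against the sequencing-error null. The per-substitution
#' error probability is the site's mean per-base error probability divided
#' by 3, apportioning the total error rate equally over the three possible
#' erroneous bases.
#'
#' @param pileup a [build_pileup()] table (one or more rows).
#' @return data.frame with one row per (site, alternate base) with k >= 1:
#'   `premirna_id`, `position`, `ref_base`, `alt_base`, `k`, `n`,
#'   `editing_level`, `err_prob`, `p_raw`.
#' @export
site_substitution_tests <- function(pileup) {
  empty <- data.frame(premirna_id = character(), position = integer(),
                      ref_base = character(), alt_base = character(),
                      k = numeric(), n = numeric(), editing_level = numeric(),
                      err_prob = numeric(), p_raw = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(pileup)) return(empty)
  rows <- list()
  for (b in DNA_BASES) {
    sel <- pileup$ref_base != b & pileup[[b]] > 0
    if (!any(sel)) next
    p <- pileup[sel, , drop = FALSE]
    rows[[b]] <- data.frame(
      premirna_id = p$premirna_id, position = p$position,
      ref_base = p$ref_base, alt_base = b, k = p[[b]], n = p$coverage,
      editing_level = p[[b]] / p$coverage, err_prob = p$err_prob,
      stringsAsFactors = FALSE)
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$premirna_id, out$position, out$alt_base), ]
  rownames(out) <- NULL
  out$p_raw <- binomial_tail(out$k, out$n, out$err_prob / 3)
  out
}

#' Call significant editing sites
#'
#' Bonferroni-corrects the per-substitution binomial tests (the family is
#' all test records entering the call, i.e. every (site, alternate) pair
#' with at least one supporting read in the sample) and applies coverage and
#' editing-level gates.
#'
#' @param tests output of [site_substitution_tests()] for one sample.
#' @param alpha family-wise significance level.
#' @param min_cov minimum site coverage for a significant call.
#' @param min_level minimum editing level (k/n) for a significant call.
#' @param sample_id optional sample label stored in the calls.
#' @param keep_all keep non-significant test records (flagged) instead of
#'   returning significant calls only.
#' @return data.frame of editing calls: the test columns plus `p_adj`,
#'   `significant`, and `sample_id`.
#' @export
call_events <- function(tests, alpha = 0.05, min_cov = 10, min_level = 0.01,
                        sample_id = NA_character_, keep_all = FALSE) {
  if (alpha <= 0 || alpha >= 1) stopf("alpha must be in (0,1)")
  m <- nrow(tests)
  out <- tests
  out$p_adj <- pmin(1, out$p_raw * m)
  out$significant <- out$p_adj < alpha & out$n >= min_cov &
    out$editing_level >= min_level
  out$sample_id <- rep(sample_id, m)
  if (!keep_all) {
    out <- out[out$significant, , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Detect editing sites in one sample's reads
#'
#' Convenience wrapper running the per-sample detection chain: adapter
#' trimming, quality filtering, unique-best alignment, pileup construction,
#' per-substitution binomial tests and Bonferroni-gated calling.
#'
#' @param reads reads data.frame for one sample.
#' @param refs a [premirna_set()].
#' @param sample_id sample label.
#' @param adapter 3' adapter to trim (`""` skips trimming).
#' @param min_overlap adapter trimming overlap (see [trim_adapter()]).
#' @param min_len,min_mean_q,drop_n read filters (see [quality_filter()]).
#' @param alpha,min_cov,min_level calling thresholds (see [call_events()]).
#' @param index optional prebuilt [build_align_index()].
#' @return list with `calls`, `tests`, `pileup`, and `stats` (weighted read
#'   tallies through the stages).
#' @export
detect_editing <- function(reads, refs, sample_id = NA_character_,
                           adapter = "", min_overlap = 5,
                           min_len = 16, min_mean_q = 20, drop_n = TRUE,
                           alpha = 0.05, min_cov = 10, min_level = 0.01,
                           index = NULL) {
  u <- collapse_reads(reads)
  n_in <- sum(u$weight)
  if (nzchar(adapter)) {
    u <- collapse_reads(trim_adapter(u, adapter, min_overlap = min_overlap))
  }
  u <- quality_filter(u, min_len = min_len, min_mean_q = min_mean_q,
                      drop_n = drop_n)
  aln <- align_reads(u, refs, index = index, min_len = min_len)
  pile <- build_pileup(aln, refs)
  tests <- site_substitution_tests(pile)
  calls <- call_events(tests, alpha = alpha, min_cov = min_cov,
                       min_level = min_level, sample_id = sample_id)
  list(calls = calls, tests = tests, pileup = pile,
       stats = c(input = n_in, dropped = attr(u, "n_dropped"),
                 attr(aln, "counts")))
}
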