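#' Fetch the one-base flanking context of an edited site
#'
#' Returns the hairpin bases at (pos-1, pos, pos+1). Context is always taken
#' from the hairpin, not the mature, so a mature-terminal site still has
#' flanks when the mature is internal to the hairpin. Sites at the first or
#' last hairpin base have no complete context and return `NA` (terminus).
#'
#' @param premirna_id,position vectors of hairpin id and 1-based hairpin
#'   position.
#' @param refs a [premirna_set()].
#' @return character vector of triplets (DNA alphabet), `NA` at termini.
#' @export
extract_context <- function(premirna_id, position, refs) {
  seqs <- refs$seq[premirna_id]
  if (anyNA(names(seqs))) stopf("unknown hairpin id")
  len <- nchar(seqs)
  out <- rep(NA_character_, length(position))
  ok <- position > 1L & position < len
  out[ok] <- substr(seqs[ok], position[ok] - 1L, position[ok] + 1L)
  out
}

#' Flanking-base probability profile with proportion tests
#'
#' From the triplet contexts of a set of edited sites, computes the base
#' probabilities one base upstream (position -1) and downstream (position
#' +1) of the edited base, plus the (fixed) position-0 composition for a
#' logo-style layout, and a two-tailed proportion test of each flanking base
#' against a null composition.
#'
#' @param contexts character vector of 3-base contexts (NAs — terminus
#'   sites — are dropped and counted).
#' @param background named numeric of null base probabilities (A, C, G, T).
#'   Defaults to uniform 0.25; [mature_base_freqs()] supplies a
#'   compositional null.
#' @param test `"z"` (normal-approximation test of proportion, default) or
#'   `"exact"` (two-sided exact binomial).
#' @return object of class `context_profile`: list with `n_events`,
#'   `n_terminus`, `counts` and `probs` (4 x 3 matrices, columns `-1`, `0`,
#'   `+1`), `pvals` (4 x 2 matrix, columns `-1`, `+1`), `background`.
#' @export
position_probabilities <- function(contexts,
                                   background = c(A = 0.25, C = 0.25,
                                                  G = 0.25, T = 0.25),
                                   test = c("z", "exact")) {
  test <- match.arg(test)
  n_term <- sum(is.na(contexts))
  contexts <- contexts[!is.na(contexts)]
  if (!length(contexts)) stopf("no usable contexts (all NA or empty input)")
  if (any(nchar(contexts) != 3L)) stopf("contexts must be 3 bases long")
  background <- background[DNA_BASES] / sum(background[DNA_BASES])
  n <- length(contexts)
  cols <- c("-1", "0", "+1")
  counts <- sapply(1:3, function(i) {
    b <- factor(substr(contexts, i, i), levels = DNA_BASES)
    as.integer(table(b))
  })
  dimnames(counts) <- list(DNA_BASES, cols)
  probs <- counts / n
  pvals <- matrix(NA_real_, 4, 2, dimnames = list(DNA_BASES, c("-1", "+1")))
  for (b in DNA_BASES) {
    for (j in c("-1", "+1")) {
      pvals[b, j] <- proportion_test(counts[b, j], n, background[[b]],
                                     method = test)
    }
  }
  structure(list(n_events = n, n_terminus = n_term, counts = counts,
                 probs = probs, pvals = pvals, background = background),
            class = "context_profile")
}

#' @export
print.context_profile <- function(x, ...) {
  cat(sprintf("context_profile over %d events (%d terminus sites excluded)\n",
              x$n_events, x$n_terminus))
  cat("base probabilities:\n")
  print(round(x$probs, 3))
  cat("two-tailed p-values vs background:\n")
  print(signif(x$pvals, 3))
  invisible(x)
}

#' Two-tailed test for a proportion
#'
#' Default is the normal-approximation z-test,
#' z = (k/n - p0) / sqrt(p0 (1 - p0) / n), p = 2 (1 - Phi(|z|));
#' `method = "exact"` uses the two-sided exact binomial test instead.
#'
#' @param k successes (0 <= k <= n).
#' @param n trials (>= 1).
#' @param p0 null proportion, in (0, 1) strictly.
#' @param method `"z"` or `"exact"`.
#' @return two-tailed p-value.
#' @export
proportion_test <- function(k, n, p0, method = c("z", "exact")) {
  method <- match.arg(method)
  if (p0 <= 0 || p0 >= 1) stopf("p0 must be strictly inside (0,1)")
  if (n < 1 || k < 0 || k > n) stopf("need n >= 1 and 0 <= k <= n")
  if (method == "exact") {
    return(stats::binom.test(k, n, p0)$p.value)
  }
  z <- (k / n - p0) / sqrt(p0 * (1 - p0) / n)
  2 * stats::pnorm(abs(z), lower.tail = FALSE)
}

#' Trinucleotide sliding-window spectrum
#'
#' Counts every overlapping 3-base window across the hairpins and returns
#' the 64 triplet frequencies: the background against which edited-site
#' context triplets are compared.
#'
#' @param refs a [premirna_set()], or a character vector / DNAStringSet of
#'   sequences (each of length >= 3).
#' @return object of class `triplet_spectrum`: named numeric of 64 triplet
#'   frequencies summing to 1; attributes `counts` and `total_windows`.
#' @export
triplet_spectrum <- function(refs) {
  seqs <- if (inherits(refs, "premirna_set")) refs$seq else as.character(refs)
  if (!length(seqs)) stopf("no sequences")
  if (any(nchar(seqs) < 3)) stopf("all sequences must be >= 3 bases")
  counts <- colSums(Biostrings::oligonucleotideFrequency(
    Biostrings::DNAStringSet(seqs), width = 3))
  total <- as.integer(sum(nchar(seqs) - 2))
  structure(counts / sum(counts), counts = counts, total_windows = total,
            class = "triplet_spectrum")
}

#' Triplet enrichment of edited-site contexts over a background spectrum
#'
#' @param contexts character vector of 3-base contexts of edited sites (NAs
#'   dropped).
#' @param spectrum a [triplet_spectrum()] background.
#' @return data.frame, one row per triplet observed among the contexts,
#'   sorted by `edited_fraction`: `triplet` (RNA convention label alongside
#'   the DNA key), `n`, `edited_fraction`, `background_fraction`, `ratio`
#'   (`Inf`, flagged in `ratio_undefined`, when the background is 0).
#' @export
triplet_enrichment <- function(contexts, spectrum) {
  contexts <- contexts[!is.na(contexts)]
  if (!length(contexts)) stopf("no usable contexts")
  n <- length(contexts)
  tab <- table(contexts)
  bg <- unclass(spectrum)[names(tab)]
  bg[is.na(bg)] <- 0
  out <- data.frame(triplet = names(tab),
                    triplet_rna = chartr("T", "U", names(tab)),
                    n = as.integer(tab),
                    edited_fraction = as.integer(tab) / n,
                    background_fraction = as.numeric(bg),
                    stringsAsFactors = FALSE)
  out$ratio <- out$edited_fraction / out$background_fraction
  out$ratio_undefined <- out$background_fraction == 0
  out$ratio[out$ratio_undefined] <- Inf
  out <- out[order(-out$edited_fraction, out$triplet), ]
  rownames(out) <- NULL
  out
}
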