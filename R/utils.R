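#' Round half away from zero
#'
#' Percentages in report tables are rounded half-up (0.005 -> 0.01), unlike
#' [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Evaluate code under a temporary RNG seed
#'
#' Restores (or removes) the caller's `.Random.seed` afterwards so library
#' functions do not perturb user-level random streams.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

#' Phred helpers
#'
#' `phred_char()` encodes an error probability as a single Phred+33 quality
#' character; `qual_to_errprob()` decodes a quality string into per-base error
#' probabilities; `mean_phred()` returns the mean Phred score of a quality
#' string.
#'
#' @param error_rate per-base error probability in (0, 1).
#' @return `phred_char()`: a single character; `qual_to_errprob()`: numeric
#'   vector of probabilities; `mean_phred()`: a number.
#' @export
phred_char <- function(error_rate) {
  stopifnot(error_rate > 0, error_rate < 1)
  intToUtf8(round(-10 * log10(error_rate)) + 33L)
}

#' @rdname phred_char
#' @param qual Phred+33 quality string.
#' @export
qual_to_errprob <- function(qual) 10^(-(utf8ToInt(qual) - 33) / 10)

#' @rdname phred_char
#' @export
mean_phred <- function(qual) mean(utf8ToInt(qual) - 33)

DNA_BASES <- c("A", "C", "G", "T")

comp_base <- function(b) chartr("ACGTN", "TGCAN", b)

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

#' Substitution label with the RNA reporting convention
#'
#' Sequences are held internally in the DNA alphabet; report-facing labels use
#' U for T (a G>T call is labelled "G-to-U").
#'
#' @param ref,alt reference and alternate bases (DNA alphabet).
#' @return character vector of labels such as `"C-to-A"`.
#' @export
subst_label <- function(ref, alt) {
  paste0(chartr("T", "U", ref), "-to-", chartr("T", "U", alt))
}
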