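#' Remove calls at known DNA-variant positions
#'
#' Calls explainable by DNA-level variation (dbSNP-style catalogues, exome
#' variants) are removed rather than reported as editing. In `"position"`
#' mode (default; matching positional overlap with a variant catalogue) any
#' call at a known-variant hairpin position is dropped; in `"allele"` mode a
#' call is dropped only when ref and alt also match the variant record.
#'
#' @param calls editing-call data.frame (columns `premirna_id`, `position`,
#'   `ref_base`, `alt_base`, ...).
#' @param variants data.frame `premirna_id`, `pos`, `ref`, `alt` in hairpin
#'   coordinates (see [read_variants()], [lift_variants()]); variants on
#'   unknown hairpins are skipped with a warning when `refs` is supplied.
#' @param mode `"position"` or `"allele"`.
#' @param refs optional [premirna_set()] used to warn about variants on
#'   unknown hairpins.
#' @param flag_only flag matching calls in a `known_variant` column instead
#'   of removing them (genome-encoded variants can still be present in the
#'   transcript).
#' @return filtered (or flagged) calls; attribute `n_removed` holds the
#'   number of calls removed.
#' @export
filter_known_variants <- function(calls, variants,
                                  mode = c("position", "allele"),
                                  refs = NULL, flag_only = FALSE) {
  mode <- match.arg(mode)
  if (is.null(variants) || !nrow(variants)) {
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  if (!is.null(refs)) {
    unknown <- !(variants$premirna_id %in% names(refs$seq))
    if (any(unknown)) {
      warnf("%d known variant(s) reference unknown hairpins and were skipped",
            sum(unknown))
      variants <- variants[!unknown, , drop = FALSE]
    }
  }
  if (mode == "position") {
    vk <- paste(variants$premirna_id, variants$pos)
    ck <- paste(calls$premirna_id, calls$position)
  } else {
    vk <- paste(variants$premirna_id, variants$pos, variants$ref,
                variants$alt)
    ck <- paste(calls$premirna_id, calls$position, calls$ref_base,
                calls$alt_base)
  }
  hit <- ck %in% vk
  if (flag_only) {
    calls$known_variant <- hit
    attr(calls, "n_removed") <- 0L
    return(calls)
  }
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Exclude a substitution class
#'
#' Removes every call of a given (ref, alt) class on the mature-sense
#' strand. The default removes A-to-C calls, a class dominated by a known
#' Illumina sequencer bias.
#'
#' @param calls editing-call data.frame.
#' @param ref_base,alt_base the substitution class to remove.
#' @return filtered calls; attribute `n_removed` holds the count removed.
#' @export
exclude_substitution_class <- function(calls, ref_base = "A",
                                       alt_base = "C") {
  hit <- calls$ref_base == ref_base & calls$alt_base == alt_base
  out <- calls[!hit, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_removed") <- sum(hit)
  out
}

#' Lift variants from a parent coordinate system onto hairpins
#'
#' Converts variant records expressed on a parent sequence (for example a
#' chromosome) into hairpin coordinates using an explicit mapping of each
#' hairpin to its parent interval. For minus-strand hairpins the position is
#' reflected and the alleles are complemented so that they read on the
#' hairpin (mature-sense) strand.
#'
#' @param variants data.frame `chrom`, `pos`, `ref`, `alt` (parent
#'   coordinates).
#' @param mapping data.frame `premirna_id`, `chrom`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`): the parent interval each hairpin occupies.
#' @return data.frame `premirna_id`, `pos`, `ref`, `alt` in hairpin
#'   coordinates; variants outside every mapped interval are dropped.
#' @export
lift_variants <- function(variants, mapping) {
  out <- list()
  for (i in seq_len(nrow(mapping))) {
    m <- mapping[i, ]
    sel <- variants$chrom == m$chrom & variants$pos >= m$start &
      variants$pos <= m$end
    if (!any(sel)) next
    v <- variants[sel, , drop = FALSE]
    if (m$strand == "-") {
      pos <- m$end - v$pos + 1L
      ref <- comp_base(v$ref)
      alt <- comp_base(v$alt)
    } else {
      pos <- v$pos - m$start + 1L
      ref <- v$ref
      alt <- v$alt
    }
    out[[length(out) + 1L]] <- data.frame(
      premirna_id = m$premirna_id, pos = as.integer(pos), ref = ref,
      alt = alt, stringsAsFactors = FALSE)
  }
  if (!length(out)) {
    return(data.frame(premirna_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
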