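#' Toy seed-match target predictor
#'
#' A 3'-UTR is called a target when it contains the reverse complement of
#' the mature miRNA's seed (bases 2-8 from the 5' end; `"7mer-m8"` exact
#' match, default) or additionally requires a 3' A opposite position 1
#' (`"8mer"`). This deliberately minimal predictor exists so that
#' seed-editing target redirection can be demonstrated end to end; it is not
#' a substitute for thermodynamic or conservation-aware tools.
#'
#' @param mature_seq mature miRNA sequence (>= 8 bases; DNA or RNA
#'   alphabet).
#' @param utrs named character vector (or DNAStringSet) of 3'-UTR
#'   sequences.
#' @param site `"7mer-m8"` or `"8mer"`.
#' @return character vector of UTR ids matched.
#' @export
seed_match_targets <- function(mature_seq, utrs, site = c("7mer-m8", "8mer")) {
  site <- match.arg(site)
  mature_seq <- toupper(chartr("Uu", "Tt", mature_seq))
  if (nchar(mature_seq) < 8) stopf("mature sequence must be >= 8 bases")
  nm <- names(utrs)
  utrs <- toupper(chartr("Uu", "Tt", as.character(utrs)))
  names(utrs) <- if (is.null(nm)) sprintf("utr%04d", seq_along(utrs)) else nm
  if (!length(utrs)) return(character(0))
  seed <- substr(mature_seq, 2, 8)
  pattern <- revcomp(seed)
  if (site == "8mer") pattern <- paste0(pattern, "A")
  names(utrs)[grepl(pattern, utrs, fixed = TRUE)]
}

#' Before/after-editing target-overlap statistic
#'
#' Quantifies target redirection: the percentage of the unedited miRNA's
#' targets retained by the edited miRNA, computed as
#' 100 * overlap / targets-before-editing, rounded half-up to 2 decimals.
#' Inputs may be target id sets or bare counts.
#'
#' @param before targets of the unedited miRNA: character vector of ids, or
#'   a single count.
#' @param after targets of the edited miRNA: ids or a count (may be `NA`
#'   when only `overlap` is known).
#' @param overlap overlap count; required when `before`/`after` are counts,
#'   ignored (recomputed by set intersection) when both are id sets.
#' @param mirna optional miRNA label.
#' @return one-row data.frame: `mirna`, `n_before`, `n_after`, `n_overlap`,
#'   `overlap_percent`.
#' @examples
#' overlap_stat(502, 111, overlap = 9)        # 1.79
#' overlap_stat(c("a", "b", "c"), c("b", "c", "d"))  # 66.67
#' @export
overlap_stat <- function(before, after = NULL, overlap = NULL,
                         mirna = NA_character_) {
  sets <- is.character(before) && is.character(after)
  if (sets) {
    n_before <- length(unique(before))
    n_after <- length(unique(after))
    n_overlap <- length(intersect(before, after))
  } else {
    n_before <- as.numeric(before)[1]
    n_after <- if (is.null(after)) NA_real_ else as.numeric(after)[1]
    if (is.null(overlap)) stopf("overlap count required with count inputs")
    n_overlap <- as.numeric(overlap)[1]
  }
  if (is.na(n_before) || n_before < 1) {
    stopf("overlap percentage undefined: no targets before editing")
  }
  if (!is.na(n_after) && n_overlap > min(n_before, n_after)) {
    stopf("overlap exceeds one of the target-set sizes")
  }
  data.frame(mirna = mirna, n_before = n_before, n_after = n_after,
             n_overlap = n_overlap,
             overlap_percent = round_half_up(100 * n_overlap / n_before, 2),
             stringsAsFactors = FALSE)
}

#' Target comparison for an edited miRNA over a UTR set
#'
#' Applies [seed_match_targets()] to the unedited and edited mature
#' sequences and returns the [overlap_stat()] row.
#'
#' @param mature_seq unedited mature sequence.
#' @param mature_position 1-based position of the edit on the mature.
#' @param alt_base edited base (DNA alphabet).
#' @param utrs UTR set.
#' @param mirna optional label.
#' @param site seed-match variant (see [seed_match_targets()]).
#' @return one-row data.frame as in [overlap_stat()].
#' @export
compare_targets <- function(mature_seq, mature_position, alt_base, utrs,
                            mirna = NA_character_, site = "7mer-m8") {
  mature_seq <- toupper(chartr("Uu", "Tt", mature_seq))
  edited <- mature_seq
  substr(edited, mature_position, mature_position) <- alt_base
  before <- seed_match_targets(mature_seq, utrs, site = site)
  after <- seed_match_targets(edited, utrs, site = site)
  if (!length(before)) {
    return(data.frame(mirna = mirna, n_before = 0L, n_after = length(after),
                      n_overlap = NA_integer_, overlap_percent = NA_real_,
                      stringsAsFactors = FALSE))
  }
  overlap_stat(before, after, mirna = mirna)
}
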