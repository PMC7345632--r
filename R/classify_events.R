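#' Classify a substitution as canonical or non-canonical
#'
#' A-to-G is reported as A-to-I (inosine is read as guanosine by the
#' sequencer) and C-to-T as C-to-U; both are enzyme-mediated canonical
#' editing. Every other substitution is non-canonical. A-to-C input is an
#' internal-consistency error: that class must be excluded upstream with
#' [exclude_substitution_class()].
#'
#' @param ref_base,alt_base character vectors of bases (DNA alphabet,
#'   `ref != alt`).
#' @return data.frame with `label` (RNA convention, e.g. `"G-to-U"`) and
#'   `category` (`"canonical"` / `"non-canonical"`).
#' @examples
#' classify_type("A", "G")  # A-to-I, canonical
#' classify_type("C", "A")  # C-to-A, non-canonical
#' @export
classify_type <- function(ref_base, alt_base) {
  if (any(!ref_base %in% DNA_BASES) || any(!alt_base %in% DNA_BASES)) {
    stopf("bases must be in {A,C,G,T}")
  }
  if (any(ref_base == alt_base)) stopf("ref and alt must differ")
  if (any(ref_base == "A" & alt_base == "C")) {
    stopf("A-to-C calls must be excluded before classification")
  }
  label <- subst_label(ref_base, alt_base)
  label[ref_base == "A" & alt_base == "G"] <- "A-to-I"
  category <- ifelse(label %in% c("A-to-I", "C-to-U"),
                     "canonical", "non-canonical")
  data.frame(label = label, category = category, stringsAsFactors = FALSE)
}

#' Locate a hairpin position within a mature annotation
#'
#' Converts a hairpin coordinate to a 1-based position from the mature 5'
#' end and flags the seed region (bases 2-8 of the mature). Positions
#' outside every mature annotation are reported with `in_mature = FALSE`.
#'
#' @param premirna_id,position vectors of hairpin id and 1-based hairpin
#'   position.
#' @param refs a [premirna_set()].
#' @return data.frame `mirna_name`, `arm`, `mature_position`, `seed`,
#'   `in_mature` (row-parallel with the input).
#' @export
locate_in_mature <- function(premirna_id, position, refs) {
  m <- refs$matures
  n <- length(premirna_id)
  out <- data.frame(mirna_name = rep(NA_character_, n),
                    arm = rep(NA_character_, n),
                    mature_position = rep(NA_integer_, n),
                    seed = rep(NA, n), in_mature = rep(FALSE, n),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    hit <- which(m$premirna_id == premirna_id[i] & m$start <= position[i] &
                   m$end >= position[i])
    if (!length(hit)) next
    if (length(hit) > 1L) {
      warnf("position %s:%d lies in overlapping matures; using '%s'",
            premirna_id[i], position[i], m$mature_name[hit[1]])
      hit <- hit[1]
    }
    mp <- position[i] - m$start[hit] + 1L
    out$mirna_name[i] <- m$mature_name[hit]
    out$arm[i] <- m$arm[hit]
    out$mature_position[i] <- mp
    out$seed[i] <- mp >= 2L && mp <= 8L
    out$in_mature[i] <- TRUE
  }
  out
}

#' Annotate calls with mature coordinates and substitution class
#'
#' @param calls editing-call data.frame (`premirna_id`, `position`,
#'   `ref_base`, `alt_base`, `sample_id`, ...).
#' @param refs a [premirna_set()].
#' @param keep_outside keep calls outside every mature annotation (flagged
#'   `in_mature = FALSE`); by default they are split off into the
#'   `outside_mature` attribute and excluded from event summaries.
#' @return annotated calls with `mirna_name`, `arm`, `mature_position`,
#'   `seed`, `subst_type`, `category`.
#' @export
annotate_calls <- function(calls, refs, keep_outside = FALSE) {
  loc <- locate_in_mature(calls$premirna_id, calls$position, refs)
  out <- cbind(calls, loc)
  if (nrow(out)) {
    cls <- classify_type(out$ref_base, out$alt_base)
    out$subst_type <- cls$label
    out$category <- cls$category
  } else {
    out$subst_type <- character(0)
    out$category <- character(0)
  }
  if (!keep_outside) {
    outside <- out[!out$in_mature, , drop = FALSE]
    out <- out[out$in_mature, , drop = FALSE]
    rownames(out) <- NULL
    attr(out, "outside_mature") <- outside
  }
  out
}

#' Deduplicate calls into unique editing events with recurrence
#'
#' An event's identity is (mirna_name, arm, mature_position, subst_type).
#' Calls sharing an identity across samples are merged; recurrence is the
#' number of distinct samples carrying the event, counted per tissue and
#' overall. An event is `recurring` when it is present in at least
#' `recur_threshold` samples of one tissue.
#'
#' @param annotated annotated calls (see [annotate_calls()]) across samples.
#' @param tissues named character vector mapping `sample_id` to tissue; if
#'   `NULL`, all samples form a single `"all"` tissue.
#' @param recur_threshold samples within a tissue needed to flag an event as
#'   recurring.
#' @return data.frame of unique events: identity columns, `category`,
#'   `seed`, `samples_present` (comma-separated), `recurrence`, one
#'   `rec_<tissue>` column per tissue, `tissues` (comma-separated tissues of
#'   presence), `recurring`, and `max_level` (largest per-sample editing
#'   level observed).
#' @export
dedupe_and_recur <- function(annotated, tissues = NULL, recur_threshold = 3) {
  if (is.null(tissues)) {
    ids <- unique(annotated$sample_id)
    tissues <- stats::setNames(rep("all", length(ids)), ids)
  }
  tissue_levels <- unique(unname(tissues))
  empty <- data.frame(mirna_name = character(), arm = character(),
                      mature_position = integer(), subst_type = character(),
                      category = character(), seed = logical(),
                      samples_present = character(), recurrence = integer(),
                      stringsAsFactors = FALSE)
  for (t in tissue_levels) empty[[paste0("rec_", t)]] <- integer(0)
  empty$tissues <- character(0)
  empty$recurring <- logical(0)
  empty$max_level <- numeric(0)
  if (!nrow(annotated)) return(empty)
  unknown <- setdiff(unique(annotated$sample_id), names(tissues))
  if (length(unknown)) stopf("sample '%s' has no tissue assignment",
                             unknown[1])
  key <- paste(annotated$mirna_name, annotated$arm,
               annotated$mature_position, annotated$subst_type, sep = "\r")
  groups <- split(seq_len(nrow(annotated)), key)
  rows <- lapply(groups, function(ix) {
    g <- annotated[ix, , drop = FALSE]
    samp <- sort(unique(g$sample_id))
    rec_t <- vapply(tissue_levels, function(t) {
      sum(tissues[samp] == t)
    }, integer(1))
    row <- data.frame(mirna_name = g$mirna_name[1], arm = g$arm[1],
                      mature_position = g$mature_position[1],
                      subst_type = g$subst_type[1],
                      category = g$category[1], seed = g$seed[1],
                      samples_present = paste(samp, collapse = ","),
                      recurrence = length(samp),
                      stringsAsFactors = FALSE)
    for (t in tissue_levels) row[[paste0("rec_", t)]] <- rec_t[[t]]
    row$tissues <- paste(tissue_levels[rec_t > 0], collapse = ",")
    row$recurring <- any(rec_t >= recur_threshold)
    row$max_level <- if ("editing_level" %in% names(g))
      max(g$editing_level) else NA_real_
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$mirna_name, out$mature_position, out$subst_type), ]
  rownames(out) <- NULL
  attr(out, "tissue_levels") <- tissue_levels
  out
}

#' Summarise unique editing events per tissue
#'
#' An event counts towards a tissue when it was observed in at least one of
#' that tissue's samples. Percentages are rounded half-up to 2 decimals and
#' reported as `NA` (undefined) when the denominator is zero. Seed
#' percentages and per-substitution-type percentages are taken within each
#' category (seed enrichment among non-canonical events is the headline
#' statistic of this analysis).
#'
#' @param events output of [dedupe_and_recur()].
#' @return list with `totals` (per tissue and category: `n_events`,
#'   `n_seed`, `pct_seed`, `n_recurring`, `pct_recurring`) and `types` (per
#'   tissue, category and substitution type: `n`, `pct` of the category
#'   total).
#' @export
summarize_events <- function(events) {
  tissue_levels <- attr(events, "tissue_levels")
  if (is.null(tissue_levels)) {
    tissue_levels <- sub("^rec_", "", grep("^rec_", names(events),
                                           value = TRUE))
  }
  pct <- function(k, n) {
    out <- round_half_up(100 * k / ifelse(n > 0, n, NA_real_), 2)
    rep_len(out, length(k))
  }
  totals <- list()
  types <- list()
  for (t in tissue_levels) {
    present <- events[[paste0("rec_", t)]] > 0
    for (cat in c("canonical", "non-canonical")) {
      e <- events[present & events$category == cat, , drop = FALSE]
      n <- nrow(e)
      totals[[paste(t, cat)]] <- data.frame(
        tissue = t, category = cat, n_events = n, n_seed = sum(e$seed),
        pct_seed = pct(sum(e$seed), n), n_recurring = sum(e$recurring),
        pct_recurring = pct(sum(e$recurring), n), stringsAsFactors = FALSE)
      if (n) {
        tab <- table(e$subst_type)
        types[[paste(t, cat)]] <- data.frame(
          tissue = t, category = cat, subst_type = names(tab),
          n = as.integer(tab), pct = pct(as.integer(tab), n),
          stringsAsFactors = FALSE)
      }
    }
  }
  totals <- do.call(rbind, totals)
  rownames(totals) <- NULL
  types <- if (length(types)) do.call(rbind, types) else
    data.frame(tissue = character(), category = character(),
               subst_type = character(), n = integer(), pct = numeric(),
               stringsAsFactors = FALSE)
  rownames(types) <- NULL
  list(totals = totals, types = types)
}
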