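#' Alignment index over hairpin substrings
#'
#' Builds a hash from every hairpin substring of the requested lengths to its
#' locations. [align_read()] finds all candidate placements of a read with at
#' most one mismatch by exact lookup of the read's two halves: any placement
#' with <= 1 mismatch leaves at least one half mismatch-free, so the half
#' lookups enumerate every admissible location (pigeonhole), which is then
#' verified base by base.
#'
#' @param refs a [premirna_set()].
#' @return an opaque index environment, reusable across reads.
#' @export
build_align_index <- function(refs) {
  idx <- new.env(parent = emptyenv())
  idx$tab <- new.env(hash = TRUE, size = 65536L, parent = emptyenv())
  idx$lengths <- integer(0)
  idx$seqs <- refs$seq
  idx$ids <- names(refs$seq)
  idx$lens <- nchar(refs$seq)
  idx
}

index_ensure_length <- function(idx, k) {
  if (k %in% idx$lengths || k < 1L) return(invisible(idx))
  keys <- character(0)
  refi <- integer(0)
  starts <- integer(0)
  for (i in seq_along(idx$seqs)) {
    M <- idx$lens[i]
    if (M < k) next
    s <- seq_len(M - k + 1L)
    keys <- c(keys, substring(idx$seqs[i], s, s + k - 1L))
    refi <- c(refi, rep.int(i, length(s)))
    starts <- c(starts, s)
  }
  if (length(keys)) {
    o <- order(keys, method = "radix")
    keys <- keys[o]; refi <- refi[o]; starts <- starts[o]
    grp_start <- which(!duplicated(keys))
    grp_end <- c(grp_start[-1] - 1L, length(keys))
    tab <- idx$tab
    for (g in seq_along(grp_start)) {
      rows <- grp_start[g]:grp_end[g]
      m <- cbind(refi[rows], starts[rows])
      key <- keys[grp_start[g]]
      old <- tab[[key]]
      tab[[key]] <- if (is.null(old)) m else rbind(old, m)
    }
  }
  idx$lengths <- c(idx$lengths, k)
  invisible(idx)
}

#' Align one read to the hairpin references
#'
#' Scans all hairpins and offsets on the sense strand, allowing at most one
#' mismatch. The best stratum is the fewest mismatches among {0, 1}; the
#' read is aligned iff exactly one location attains the best stratum
#' (unique-best rule: any 0-mismatch hit suppresses all 1-mismatch hits),
#' `"ambiguous"` if several do, `"unaligned"` if none has <= 1 mismatch.
#' Mismatches at read ends count like internal ones; there is no
#' soft-clipping and no indel model.
#'
#' @param sequence read sequence (character scalar, DNA alphabet).
#' @param refs a [premirna_set()].
#' @param quality optional Phred+33 quality string (recorded with the
#'   mismatch).
#' @param index optional prebuilt [build_align_index()] for `refs`.
#' @return a list with `status` (`"aligned"`, `"unaligned"` or
#'   `"ambiguous"`), and for aligned reads `premirna_id`, `offset` (1-based
#'   start on the hairpin), `n_mismatches`, and `mismatch` (list with
#'   `position` on the hairpin, `read_pos`, `ref_base`, `read_base`,
#'   `read_quality`) when `n_mismatches == 1`.
#' @export
align_read <- function(sequence, refs, quality = NULL, index = NULL) {
  L <- nchar(sequence)
  if (L < 2L) stopf("read too short to align (%d base)", L)
  if (is.null(index)) index <- build_align_index(refs)
  k1 <- L %/% 2L
  k2 <- L - k1
  index_ensure_length(index, k1)
  index_ensure_length(index, k2)
  tab <- index$tab
  cand_ref <- integer(0)
  cand_off <- integer(0)
  hitA <- tab[[substr(sequence, 1L, k1)]]
  if (!is.null(hitA)) {
    cand_ref <- hitA[, 1L]
    cand_off <- hitA[, 2L]
  }
  hitB <- tab[[substr(sequence, k1 + 1L, L)]]
  if (!is.null(hitB)) {
    cand_ref <- c(cand_ref, hitB[, 1L])
    cand_off <- c(cand_off, hitB[, 2L] - k1)
  }
  if (!length(cand_ref)) return(list(status = "unaligned"))
  ok <- cand_off >= 1L & cand_off + L - 1L <= index$lens[cand_ref]
  cand_ref <- cand_ref[ok]; cand_off <- cand_off[ok]
  if (!length(cand_ref)) return(list(status = "unaligned"))
  dup <- duplicated(cand_ref * 1000000L + cand_off)
  cand_ref <- cand_ref[!dup]; cand_off <- cand_off[!dup]

  rraw <- charToRaw(sequence)
  nmm <- integer(length(cand_ref))
  mmpos <- integer(length(cand_ref))
  for (i in seq_along(cand_ref)) {
    win <- substr(index$seqs[cand_ref[i]], cand_off[i], cand_off[i] + L - 1L)
    d <- which(charToRaw(win) != rraw)
    nmm[i] <- length(d)
    mmpos[i] <- if (length(d) == 1L) d[1L] else NA_integer_
  }
  admissible <- nmm <= 1L
  if (!any(admissible)) return(list(status = "unaligned"))
  best <- min(nmm[admissible])
  at_best <- which(nmm == best)
  if (length(at_best) > 1L) return(list(status = "ambiguous"))
  i <- at_best
  out <- list(status = "aligned",
              premirna_id = unname(index$ids[cand_ref[i]]),
              offset = unname(as.integer(cand_off[i])),
              n_mismatches = unname(best))
  if (best == 1L) {
    rp <- mmpos[i]
    hp <- cand_off[i] + rp - 1L
    out$mismatch <- list(
      position = unname(hp),
      read_pos = unname(rp),
      ref_base = unname(substr(index$seqs[cand_ref[i]], hp, hp)),
      read_base = substr(sequence, rp, rp),
      read_quality = if (is.null(quality)) NA_character_ else
        substr(quality, rp, rp))
  }
  out
}

#' Align a set of reads
#'
#' Collapses identical (sequence, quality) records, aligns each distinct
#' read once with [align_read()], and returns the retained alignments with
#' their multiplicities. Ambiguous and unaligned reads are discarded and
#' tallied.
#'
#' @param reads reads data.frame (optionally carrying `weight`).
#' @param refs a [premirna_set()].
#' @param index optional prebuilt [build_align_index()].
#' @param min_len reads shorter than this are counted as unaligned rather
#'   than scanned.
#' @return data.frame of alignments: `read_id`, `sequence`, `quality`,
#'   `weight`, `premirna_id`, `offset`, `n_mismatches`, `mm_pos` (hairpin
#'   coordinate), `mm_read_pos`, `mm_ref`, `mm_read`, `mm_qual`. Attribute
#'   `counts` holds the weighted totals of aligned / ambiguous / unaligned
#'   reads.
#' @export
align_reads <- function(reads, refs, index = NULL, min_len = 16) {
  u <- collapse_reads(reads)
  if (is.null(index)) index <- build_align_index(refs)
  n <- nrow(u)
  status <- character(n)
  pid <- character(n); off <- integer(n); nmm <- integer(n)
  mpos <- rep(NA_integer_, n); mrpos <- rep(NA_integer_, n)
  mref <- rep(NA_character_, n); mread <- rep(NA_character_, n)
  mqual <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (nchar(u$sequence[i]) < min_len) {
      status[i] <- "unaligned"
      next
    }
    a <- align_read(u$sequence[i], refs, quality = u$quality[i],
                    index = index)
    status[i] <- a$status
    if (a$status == "aligned") {
      pid[i] <- a$premirna_id
      off[i] <- a$offset
      nmm[i] <- a$n_mismatches
      if (a$n_mismatches == 1L) {
        mpos[i] <- a$mismatch$position
        mrpos[i] <- a$mismatch$read_pos
        mref[i] <- a$mismatch$ref_base
        mread[i] <- a$mismatch$read_base
        mqual[i] <- a$mismatch$read_quality
      }
    }
  }
  keep <- status == "aligned"
  out <- data.frame(read_id = u$read_id[keep], sequence = u$sequence[keep],
                    quality = u$quality[keep], weight = u$weight[keep],
                    premirna_id = pid[keep], offset = off[keep],
                    n_mismatches = nmm[keep], mm_pos = mpos[keep],
                    mm_read_pos = mrpos[keep], mm_ref = mref[keep],
                    mm_read = mread[keep], mm_qual = mqual[keep],
                    stringsAsFactors = FALSE)
  attr(out, "counts") <- c(
    aligned = sum(u$weight[keep]),
    ambiguous = sum(u$weight[status == "ambiguous"]),
    unaligned = sum(u$weight[status == "unaligned"]))
  out
}

#' Build per-site pileups from retained alignments
#'
#' For every covered hairpin position, accumulates read depth, per-base read
#' counts and the coverage-weighted mean Phred-implied error probability —
#' the inputs to the binomial sequencing-error test.
#'
#' @param alignments output of [align_reads()].
#' @param refs a [premirna_set()].
#' @return data.frame of class `site_pileup`: `premirna_id`, `position`,
#'   `ref_base`, `coverage`, base count columns `A`, `C`, `G`, `T`, and
#'   `err_prob` (mean per-base error probability over covering reads).
#' @export
build_pileup <- function(alignments, refs) {
  empty <- data.frame(premirna_id = character(), position = integer(),
                      ref_base = character(), coverage = numeric(),
                      A = numeric(), C = numeric(), G = numeric(),
                      T = numeric(), err_prob = numeric(),
                      stringsAsFactors = FALSE)
  if (!nrow(alignments)) return(structure(empty, class = c("site_pileup",
                                                           "data.frame")))
  ids <- names(refs$seq)
  refidx <- match(alignments$premirna_id, ids)
  if (anyNA(refidx)) stopf("alignment references unknown hairpin '%s'",
                           alignments$premirna_id[is.na(refidx)][1])
  L <- nchar(alignments$sequence)
  mult <- max(nchar(refs$seq)) + 1L
  pos <- rep(alignments$offset, L) + sequence(L) - 1L
  key <- rep(refidx, L) * mult + pos
  w <- rep(alignments$weight, L)
  eprob <- qual_to_errprob(paste(alignments$quality, collapse = ""))
  cov <- rowsum(w, key)
  esum <- rowsum(w * eprob, key)
  ukey <- as.numeric(rownames(cov))
  o <- order(ukey)
  ukey <- ukey[o]; cov <- cov[o, 1]; esum <- esum[o, 1]
  uref <- as.integer(ukey %/% mult)
  upos <- as.integer(ukey %% mult)
  ref_base <- substr(refs$seq[uref], upos, upos)
  base_counts <- matrix(0, nrow = length(ukey), ncol = 4,
                        dimnames = list(NULL, DNA_BASES))
  base_counts[cbind(seq_along(ukey), match(ref_base, DNA_BASES))] <- cov
  mm <- alignments[alignments$n_mismatches == 1L, , drop = FALSE]
  if (nrow(mm)) {
    mkey <- match(mm$premirna_id, ids) * mult + mm$mm_pos
    site <- match(mkey, ukey)
    aw <- rowsum(mm$weight, paste(site, mm$mm_read))
    parts <- strsplit(rownames(aw), " ")
    si <- as.integer(vapply(parts, `[`, character(1), 1))
    bi <- match(vapply(parts, `[`, character(1), 2), DNA_BASES)
    base_counts[cbind(si, bi)] <- base_counts[cbind(si, bi)] + aw[, 1]
    ri <- match(ref_base[si], DNA_BASES)
    base_counts[cbind(si, ri)] <- base_counts[cbind(si, ri)] - aw[, 1]
  }
  out <- data.frame(premirna_id = ids[uref], position = upos,
                    ref_base = ref_base, coverage = cov,
                    A = base_counts[, "A"], C = base_counts[, "C"],
                    G = base_counts[, "G"], T = base_counts[, "T"],
                    err_prob = esum / cov,
                    stringsAsFactors = FALSE, row.names = NULL)
  structure(out, class = c("site_pileup", "data.frame"))
}
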