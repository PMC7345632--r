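#' Read and write FASTQ
#'
#' Thin wrappers over Biostrings' FASTQ support (4-line records, Phred+33).
#' Reads are represented throughout the package as a data.frame with columns
#' `read_id`, `sequence`, `quality` (and optionally `weight` after
#' [collapse_reads()]).
#'
#' @param path FASTQ file path.
#' @return `read_fastq()`: a reads data.frame.
#' @export
read_fastq <- function(path) {
  # Biostrings warns about dropping its own internal metadata columns here
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    })
  data.frame(read_id = sub("\\s.*$", "", names(x)),
             sequence = as.character(x),
             quality = as.character(Biostrings::quality(x)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' @rdname read_fastq
#' @param reads reads data.frame (`read_id`, `sequence`, `quality`).
#' @return `write_fastq()`: invisibly, `path`.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::QualityScaledDNAStringSet(
    Biostrings::DNAStringSet(reads$sequence),
    Biostrings::PhredQuality(reads$quality))
  names(x) <- reads$read_id
  Biostrings::writeQualityScaledXStringSet(x, path)
  invisible(path)
}

#' Collapse reads to unique (sequence, quality) records
#'
#' Identical records are merged and their multiplicity kept in `weight`, so
#' that trimming, filtering and alignment run once per distinct read while
#' every read still counts once in pileups. `read_id` keeps the first
#' representative.
#'
#' @param reads reads data.frame; an existing `weight` column is honoured.
#' @return reads data.frame with a `weight` column.
#' @export
collapse_reads <- function(reads) {
  w <- if ("weight" %in% names(reads)) reads$weight else rep(1L, nrow(reads))
  key <- paste(reads$sequence, reads$quality, sep = "\r")
  first <- !duplicated(key)
  out <- reads[first, c("read_id", "sequence", "quality"), drop = FALSE]
  out$weight <- as.integer(rowsum(w, key, reorder = FALSE)[, 1])
  rownames(out) <- NULL
  out
}

#' Trim a 3' adapter
#'
#' Removes the longest read suffix that matches a prefix of the adapter
#' (at least `min_overlap` bases; exact match by default, or at most
#' `max_mismatch` mismatches). Qualities are trimmed in lockstep; reads with
#' no match are returned unchanged.
#'
#' @param reads reads data.frame.
#' @param adapter adapter sequence (DNA alphabet).
#' @param min_overlap minimum suffix/prefix overlap to trim (>= 1).
#' @param max_mismatch mismatches tolerated in the overlap (default 0).
#' @return reads data.frame with trimmed `sequence`/`quality`.
#' @export
trim_adapter <- function(reads, adapter, min_overlap = 5, max_mismatch = 0) {
  stopifnot(min_overlap >= 1)
  adapter <- toupper(chartr("Uu", "Tt", adapter))
  L <- nchar(reads$sequence)
  keep_len <- L
  done <- rep(FALSE, nrow(reads))
  kmax <- min(max(L, 0), nchar(adapter))
  if (kmax >= min_overlap) {
    for (k in seq(kmax, min_overlap)) {
      todo <- !done & L >= k
      if (!any(todo)) next
      suff <- substring(reads$sequence[todo], L[todo] - k + 1L, L[todo])
      apre <- substr(adapter, 1, k)
      if (max_mismatch == 0) {
        hit <- suff == apre
      } else {
        araw <- charToRaw(apre)
        hit <- vapply(suff, function(s) {
          sum(charToRaw(s) != araw) <= max_mismatch
        }, logical(1), USE.NAMES = FALSE)
      }
      idx <- which(todo)[hit]
      keep_len[idx] <- L[idx] - k
      done[idx] <- TRUE
    }
  }
  reads$sequence <- substr(reads$sequence, 1, keep_len)
  reads$quality <- substr(reads$quality, 1, keep_len)
  reads
}

#' Filter reads on length, mean quality and N content
#'
#' A read is kept iff its length is at least `min_len`, its mean Phred score
#' at least `min_mean_q`, and (by default) it contains no N.
#'
#' @param reads reads data.frame.
#' @param min_len minimum read length (default 16, the shortest plausible
#'   mature fragment).
#' @param min_mean_q minimum mean Phred score.
#' @param drop_n drop reads containing N.
#' @return filtered reads data.frame; attribute `n_dropped` holds the
#'   (weighted) number of reads removed.
#' @export
quality_filter <- function(reads, min_len = 16, min_mean_q = 20,
                           drop_n = TRUE) {
  L <- nchar(reads$sequence)
  keep <- L >= min_len
  if (any(keep)) {
    mq <- rep(NA_real_, nrow(reads))
    mq[keep] <- vapply(reads$quality[keep], mean_phred, numeric(1),
                       USE.NAMES = FALSE)
    keep <- keep & mq >= min_mean_q
  }
  if (drop_n) keep <- keep & !grepl("N", reads$sequence, fixed = TRUE)
  w <- if ("weight" %in% names(reads)) reads$weight else rep(1L, nrow(reads))
  out <- reads[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- sum(w[!keep])
  out
}
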