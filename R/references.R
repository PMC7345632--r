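#' Pre-miRNA reference set
#'
#' A `premirna_set` bundles hairpin sequences with their mature-arm
#' annotations and is the coordinate frame for every downstream call: all
#' positions are 1-based, inclusive, on the hairpin plus strand.
#'
#' @param sequences named character vector of hairpin sequences (DNA or RNA
#'   alphabet; U is normalised to T, case is folded to upper).
#' @param matures data.frame with columns `premirna_id`, `mature_name`,
#'   `arm` (one of `"5p"`, `"3p"`, `"mature"`), `start`, `end` (1-based,
#'   inclusive, within the hairpin).
#' @return an object of class `premirna_set`: a list with elements `seq`
#'   (named character) and `matures` (data.frame).
#' @examples
#' refs <- premirna_set(
#'   c(hp1 = "ACGUACGUACGUACGUACGUACGUACGU"),
#'   data.frame(premirna_id = "hp1", mature_name = "hp1-5p", arm = "5p",
#'              start = 2, end = 23)
#' )
#' mature_sequences(refs)
#' @export
premirna_set <- function(sequences, matures = NULL) {
  nm <- names(sequences)
  sequences <- stats::setNames(toupper(chartr("Uu", "Tt",
                                              as.character(sequences))), nm)
  if (length(sequences) && is.null(names(sequences))) {
    stopf("hairpin sequences must be named")
  }
  if (anyDuplicated(names(sequences))) stopf("duplicate hairpin ids")
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad)) stopf("non-nucleotide characters in hairpin '%s'",
                      names(sequences)[bad][1])
  if (is.null(matures)) {
    matures <- data.frame(premirna_id = character(), mature_name = character(),
                          arm = character(), start = integer(), end = integer(),
                          stringsAsFactors = FALSE)
  }
  matures <- as.data.frame(matures, stringsAsFactors = FALSE)
  need <- c("premirna_id", "mature_name", "arm", "start", "end")
  miss <- setdiff(need, names(matures))
  if (length(miss)) stopf("mature annotation lacks column(s): %s",
                          paste(miss, collapse = ", "))
  matures <- matures[need]
  matures$start <- as.integer(matures$start)
  matures$end <- as.integer(matures$end)
  if (nrow(matures)) {
    unknown <- setdiff(matures$premirna_id, names(sequences))
    if (length(unknown)) {
      stopf("mature annotation references unknown hairpin '%s'", unknown[1])
    }
    len <- nchar(sequences)[matures$premirna_id]
    bad <- matures$start < 1L | matures$end > len | matures$start > matures$end
    if (any(bad)) {
      stopf("mature '%s' lies outside its hairpin",
            matures$mature_name[bad][1])
    }
    dup <- duplicated(matures[c("premirna_id", "arm")])
    if (any(dup)) {
      stopf("hairpin '%s' has duplicate '%s' arm annotations",
            matures$premirna_id[dup][1], matures$arm[dup][1])
    }
  }
  structure(list(seq = sequences, matures = matures), class = "premirna_set")
}

#' @export
print.premirna_set <- function(x, ...) {
  cat(sprintf("premirna_set: %d hairpins, %d mature annotations\n",
              length(x$seq), nrow(x$matures)))
  invisible(x)
}

#' @rdname premirna_set
#' @param refs a `premirna_set`.
#' @return `mature_sequences()`: named character vector of mature sequences
#'   (names are `mature_name`).
#' @export
mature_sequences <- function(refs) {
  m <- refs$matures
  out <- substr(refs$seq[m$premirna_id], m$start, m$end)
  names(out) <- m$mature_name
  out
}

#' Base composition of the mature sequences
#'
#' The default null proportions for flanking-context tests: each base's
#' frequency across all annotated mature sequences of the reference set.
#'
#' @param refs a `premirna_set`.
#' @return named numeric of length 4 (A, C, G, T) summing to 1.
#' @export
mature_base_freqs <- function(refs) {
  seqs <- mature_sequences(refs)
  if (!length(seqs)) stopf("reference set has no mature annotations")
  counts <- colSums(Biostrings::letterFrequency(
    Biostrings::DNAStringSet(seqs), DNA_BASES))
  counts / sum(counts)
}

#' Read pre-miRNA references from FASTA plus an annotation file
#'
#' The annotation may be a 6-column TSV (`premirna_id`, `mature_name`, `arm`,
#' `start`, `end`, `strand`) or a GFF3 in the miRBase dialect
#' (`miRNA_primary_transcript` and `miRNA` features; the `miRNA` features'
#' seqid must be the hairpin id). U is converted to T on input.
#'
#' @param fasta path to a hairpin FASTA file.
#' @param annotation path to the mature annotation (TSV or GFF3, selected by
#'   file extension).
#' @return a [premirna_set()].
#' @export
parse_references <- function(fasta, annotation) {
  ss <- Biostrings::readBStringSet(fasta)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (grepl("\\.gff3?$", annotation, ignore.case = TRUE)) {
    matures <- read_mature_gff3(annotation)
  } else {
    tab <- utils::read.delim(annotation, stringsAsFactors = FALSE)
    need <- c("premirna_id", "mature_name", "arm", "start", "end")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stopf("annotation TSV lacks column(s): %s",
                            paste(miss, collapse = ", "))
    matures <- tab[need]
  }
  premirna_set(seqs, matures)
}

read_mature_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mi <- gr[gr$type == "miRNA"]
  nm <- if (!is.null(mi$Name)) as.character(mi$Name) else as.character(mi$ID)
  arm <- ifelse(grepl("-5p$", nm), "5p", ifelse(grepl("-3p$", nm), "3p", "mature"))
  data.frame(
    premirna_id = as.character(GenomicRanges::seqnames(mi)),
    mature_name = nm,
    arm = arm,
    start = GenomicRanges::start(mi),
    end = GenomicRanges::end(mi),
    stringsAsFactors = FALSE
  )
}

#' Write a reference set to disk
#'
#' @param refs a [premirna_set()].
#' @param fasta output FASTA path for the hairpins.
#' @param annotation output path for the mature annotation.
#' @param format `"tsv"` (6-column table) or `"gff3"` (miRBase dialect).
#' @return invisibly, the paths written.
#' @export
write_references <- function(refs, fasta, annotation, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(refs$seq), fasta)
  m <- refs$matures
  if (format == "tsv") {
    out <- cbind(m, strand = rep("+", nrow(m)))
    utils::write.table(out, annotation, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    write_mature_gff3(refs, annotation)
  }
  invisible(c(fasta = fasta, annotation = annotation))
}

write_mature_gff3 <- function(refs, path) {
  m <- refs$matures
  hp <- GenomicRanges::GRanges(
    seqnames = names(refs$seq),
    ranges = IRanges::IRanges(1L, nchar(refs$seq)),
    strand = "+",
    type = "miRNA_primary_transcript",
    source = "miredscan",
    ID = names(refs$seq), Name = names(refs$seq),
    Derives_from = NA_character_
  )
  mi <- GenomicRanges::GRanges(
    seqnames = m$premirna_id,
    ranges = IRanges::IRanges(m$start, m$end),
    strand = "+",
    type = "miRNA",
    source = "miredscan",
    ID = m$mature_name, Name = m$mature_name,
    Derives_from = m$premirna_id
  )
  gr <- c(hp, mi)
  GenomeInfoDb::seqlengths(gr) <- nchar(refs$seq)[GenomeInfoDb::seqlevels(gr)]
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a known-variant table
#'
#' Accepts either a 4-column TSV (`premirna_id`, `pos`, `ref`, `alt`) in
#' hairpin coordinates, or a VCF whose CHROM column holds hairpin ids
#' (requires the vcfR package). Variants in a parent (e.g. genomic)
#' coordinate system can be converted first with [lift_variants()].
#'
#' @param path path to the TSV or `.vcf` file.
#' @return data.frame with columns `premirna_id`, `pos`, `ref`, `alt`.
#' @export
read_variants <- function(path) {
  if (grepl("\\.vcf(\\.gz)?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("vcfR", quietly = TRUE)) {
      stopf("reading VCF requires the vcfR package")
    }
    v <- vcfR::read.vcfR(path, verbose = FALSE)
    fx <- vcfR::getFIX(v)
    fx <- if (is.null(dim(fx))) as.data.frame(t(fx)) else as.data.frame(fx)
    out <- data.frame(premirna_id = as.character(fx$CHROM),
                      pos = as.integer(as.character(fx$POS)),
                      ref = as.character(fx$REF),
                      alt = as.character(fx$ALT),
                      stringsAsFactors = FALSE)
  } else {
    out <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("premirna_id", "pos", "ref", "alt")
    miss <- setdiff(need, names(out))
    if (length(miss)) stopf("variant TSV lacks column(s): %s",
                            paste(miss, collapse = ", "))
    out <- out[need]
  }
  out$pos <- as.integer(out$pos)
  out
}

#' Write a known-variant table
#'
#' @param variants data.frame with `premirna_id`, `pos`, `ref`, `alt`.
#' @param path output path; a `.vcf` extension selects minimal VCF 4.2
#'   output (CHROM = hairpin id), anything else a 4-column TSV.
#' @return invisibly, `path`.
#' @export
write_variants <- function(variants, path) {
  if (grepl("\\.vcf$", path, ignore.case = TRUE)) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("##fileformat=VCFv4.2",
                 "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), con)
    if (nrow(variants)) {
      writeLines(sprintf("%s\t%d\t.\t%s\t%s\t.\t.\t.",
                         variants$premirna_id, variants$pos,
                         variants$ref, variants$alt), con)
    }
  } else {
    utils::write.table(variants, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}
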