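test_that("adapter trimming removes the longest suffix matching an adapter prefix", {
  reads <- make_reads(c("ACGTACGTTGGAATTC",   # 8-base exact overlap
                        "ACGTACGTACGTACGT",   # adapter absent
                        "TGGAATTCTCGG"))      # read entirely adapter
  out <- trim_adapter(reads, "TGGAATTCTCGG", min_overlap = 5)
  expect_identical(out$sequence, c("ACGTACGT", "ACGTACGTACGTACGT", ""))
  expect_identical(nchar(out$quality), nchar(out$sequence))
  # bases upstream of the trim point are untouched
  expect_identical(substr(reads$sequence[1], 1, 8), out$sequence[1])
  # a full-trim read is then removed by the length rule
  expect_identical(nrow(quality_filter(out, min_len = 16)), 1L)
})

test_that("overlaps shorter than min_overlap are not trimmed", {
  reads <- make_reads("ACGTACGTACGTTGGA")  # only 4 adapter bases present
  out <- trim_adapter(reads, "TGGAATTCTCGG", min_overlap = 5)
  expect_identical(out$sequence, reads$sequence)
  out2 <- trim_adapter(reads, "TGGAATTCTCGG", min_overlap = 4)
  expect_identical(out2$sequence, "ACGTACGTACGT")
})

test_that("one-mismatch adapter tolerance trims when enabled", {
  reads <- make_reads("ACGTACGTTGGAATTG")  # last base mismatches adapter
  exact <- trim_adapter(reads, "TGGAATTC", min_overlap = 5)
  expect_identical(exact$sequence, reads$sequence)
  loose <- trim_adapter(reads, "TGGAATTC", min_overlap = 5, max_mismatch = 1)
  expect_identical(loose$sequence, "ACGTACGT")
})

test_that("quality filter gates on length, mean quality and N content", {
  reads <- make_reads(
    c(strrep("A", 16), strrep("A", 10), strrep("A", 16), strrep("A", 16)),
    quals = c(strrep("?", 16), strrep("?", 10), strrep("'", 16),  # Q6
              strrep("?", 16)))
  reads$sequence[4] <- paste0(strrep("A", 15), "N")
  out <- quality_filter(reads, min_len = 16, min_mean_q = 20)
  expect_identical(out$read_id, "r001")
  expect_identical(attr(out, "n_dropped"), 3L)
  keep_n <- quality_filter(reads, min_len = 16, min_mean_q = 20,
                           drop_n = FALSE)
  expect_identical(nrow(keep_n), 2L)
})

test_that("references round-trip through FASTA + TSV and normalise U to T", {
  refs <- tiny_refs()
  fa <- tempfile(fileext = ".fa"); tsv <- tempfile(fileext = ".tsv")
  write_references(refs, fa, tsv)
  back <- parse_references(fa, tsv)
  expect_identical(back$seq, refs$seq)
  expect_identical(back$matures, refs$matures)

  # RNA-alphabet FASTA input is stored as DNA, length preserved
  fa2 <- tempfile(fileext = ".fa")
  writeLines(c(">hp1", "acguACGU"), fa2)
  tsv2 <- tempfile(fileext = ".tsv")
  writeLines(c("premirna_id\tmature_name\tarm\tstart\tend\tstrand",
               "hp1\thp1-5p\t5p\t1\t8\t+"), tsv2)
  r2 <- parse_references(fa2, tsv2)
  expect_identical(unname(r2$seq), "ACGTACGT")
})

test_that("references round-trip through miRBase-style GFF3", {
  refs <- tiny_refs()
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_references(refs, fa, gff, format = "gff3")
  back <- parse_references(fa, gff)
  m1 <- refs$matures[order(refs$matures$mature_name), ]
  m2 <- back$matures[order(back$matures$mature_name), ]
  rownames(m1) <- rownames(m2) <- NULL
  expect_identical(m1, m2)
  expect_identical(back$seq, refs$seq)
})

test_that("annotations referencing unknown hairpins or out-of-bounds matures error", {
  expect_error(premirna_set(c(h = "ACGT"),
                            data.frame(premirna_id = "x", mature_name = "m",
                                       arm = "5p", start = 1, end = 3)),
               "unknown hairpin")
  expect_error(premirna_set(c(h = "ACGT"),
                            data.frame(premirna_id = "h", mature_name = "m",
                                       arm = "5p", start = 2, end = 9)),
               "outside")
})

test_that("FASTQ round-trips through Biostrings with qualities intact", {
  reads <- make_reads(c("ACGTACGTACGTACGT", "TTTTCCCCGGGGAAAA"),
                      quals = c(strrep("?", 16), strrep("I", 16)))
  fq <- tempfile(fileext = ".fastq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_identical(back, reads)
})

test_that("variant tables round-trip as TSV and VCF", {
  v <- data.frame(premirna_id = c("hpA", "hpB"), pos = c(7L, 10L),
                  ref = c("C", "G"), alt = c("A", "T"),
                  stringsAsFactors = FALSE)
  tsv <- tempfile(fileext = ".tsv")
  write_variants(v, tsv)
  expect_identical(read_variants(tsv), v)
  skip_if_not_installed("vcfR")
  vcf <- tempfile(fileext = ".vcf")
  write_variants(v, vcf)
  expect_identical(read_variants(vcf), v)
})
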