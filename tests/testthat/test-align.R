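test_that("exact, one-mismatch and ambiguous placements follow the unique-best rule", {
  refs1 <- premirna_set(c(r = "AAGGCCTT"))
  a <- align_read("GGCC", refs1)
  expect_identical(a[c("status", "premirna_id", "offset", "n_mismatches")],
                   list(status = "aligned", premirna_id = "r", offset = 3L,
                        n_mismatches = 0L))

  refs2 <- premirna_set(c(r = "ACGTACGTAC"))
  expect_identical(align_read("GTAC", refs2)$status, "ambiguous")

  b <- align_read("GACC", refs1, quality = "IIII")
  expect_identical(b$status, "aligned")
  expect_identical(b$offset, 3L)
  expect_identical(b$n_mismatches, 1L)
  expect_identical(b$mismatch$position, 4L)  # hairpin coordinate
  expect_identical(b$mismatch$ref_base, "G")
  expect_identical(b$mismatch$read_base, "A")
  expect_identical(b$mismatch$read_quality, "I")

  expect_identical(align_read("TTTT", refs1)$status, "unaligned")
})

test_that("a 0-mismatch hit suppresses 1-mismatch hits elsewhere", {
  # read matches hpX exactly and hpY with one mismatch: must align to hpX
  refs <- premirna_set(c(hpX = "TTACGGATCCTT", hpY = "GGACGGATCGTTAA"))
  a <- align_read("ACGGATCC", refs)
  expect_identical(a$status, "aligned")
  expect_identical(a$premirna_id, "hpX")
  expect_identical(a$n_mismatches, 0L)
})

test_that("align_read agrees with brute-force enumeration on random instances", {
  set.seed(71)
  n_agree <- 0L
  for (i in 1:200) {
    nref <- sample(1:3, 1)
    seqs <- vapply(seq_len(nref), function(j) random_seq(sample(20:60, 1)),
                   character(1))
    names(seqs) <- paste0("h", seq_len(nref))
    refs <- premirna_set(seqs)
    L <- sample(6:12, 1)
    # mix of planted (possibly mutated) and fully random reads
    if (runif(1) < 0.7) {
      src <- sample(nref, 1)
      off <- sample(nchar(seqs[src]) - L + 1, 1)
      read <- substr(seqs[src], off, off + L - 1)
      if (runif(1) < 0.5) {
        p <- sample(L, 1)
        substr(read, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
    } else {
      read <- random_seq(L)
    }
    got <- align_read(read, refs)
    want <- brute_force_align(read, refs)
    expect_identical(got$status, want$status)
    if (want$status == "aligned") {
      expect_identical(got$premirna_id, want$premirna_id)
      expect_identical(got$offset, want$offset)
      expect_identical(got$n_mismatches, want$n_mismatches)
    }
    n_agree <- n_agree + 1L
  }
  expect_identical(n_agree, 200L)
})

test_that("pileups count coverage, alternates and qualities correctly", {
  refs <- premirna_set(c(hp = "AACCGCCTTGGA"))
  # 7 exact reads and 3 reads carrying C>A at hairpin position 5
  reads <- make_reads(c(rep("CCGCCTTG", 7), rep("CCGACTTG", 0)))
  reads <- rbind(reads, make_reads(rep("CCACCTTG", 3),
                                   ids = sprintf("m%d", 1:3)))
  aln <- align_reads(reads, refs, min_len = 8)
  pile <- build_pileup(aln, refs)
  site <- pile[pile$position == 5, ]
  expect_identical(site$ref_base, "G")
  expect_equal(site$coverage, 10)
  expect_equal(site$A, 3)
  expect_equal(site$G, 7)
  # all bases Q30 -> site error probability 0.001
  expect_equal(unique(pile$err_prob), 0.001, tolerance = 1e-12)
  # all-reference sites carry no alternates
  clean <- pile[pile$position != 5, ]
  expect_true(all(clean$A + clean$C + clean$T + clean$G == clean$coverage))
  bc <- as.matrix(clean[c("A", "C", "G", "T")])
  expect_true(all(bc[cbind(seq_len(nrow(clean)),
                           match(clean$ref_base, c("A", "C", "G", "T")))] ==
                    clean$coverage))
})

test_that("pileup coverage is conserved: sum(coverage) equals total aligned bases", {
  refs <- tiny_refs()
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 500, adapter = "", rng_seed = 3)
  s <- simulate_reads(refs, cfg, "S", seed = 8)
  aln <- align_reads(s$reads, refs)
  pile <- build_pileup(aln, refs)
  expect_equal(sum(pile$coverage),
               sum(aln$weight * nchar(aln$sequence)))
  cnt <- attr(aln, "counts")
  expect_equal(sum(cnt), 500)
})

test_that("collapsed alignment gives identical pileups to per-read alignment", {
  refs <- tiny_refs()
  reads <- make_reads(c(rep("ACGTTCAGGTCCATGAACGTTC", 5),
                        rep("ACGTTCAGTTCCATGAACGTTC", 2)))
  aln_w <- align_reads(reads, refs)             # collapsed, weighted
  expect_identical(sum(aln_w$weight), 7L)
  pile <- build_pileup(aln_w, refs)
  site <- pile[pile$premirna_id == "hpA" & pile$position == 11, ]
  expect_equal(site$T, 2)
  expect_equal(site$coverage, 7)
})
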