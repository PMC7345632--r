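test_that("reference generation is deterministic and internally consistent", {
  cfg <- sim_config(n_premirnas = 5, reads_per_sample = 100, rng_seed = 1)
  r1 <- generate_premirnas(cfg)
  r2 <- generate_premirnas(cfg)
  expect_identical(r1, r2)

  f1 <- tempfile(fileext = ".fa"); a1 <- tempfile(fileext = ".tsv")
  f2 <- tempfile(fileext = ".fa"); a2 <- tempfile(fileext = ".tsv")
  write_references(r1, f1, a1)
  write_references(r2, f2, a2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # every mature interval inside its hairpin, alphabet is DNA
  len <- nchar(r1$seq)[r1$matures$premirna_id]
  expect_true(all(r1$matures$start >= 1 & r1$matures$end <= len))
  expect_false(any(grepl("[^ACGT]", r1$seq)))

  empty <- generate_premirnas(sim_config(n_premirnas = 0,
                                         reads_per_sample = 100))
  expect_s3_class(empty, "premirna_set")
  expect_length(empty$seq, 0)
})

test_that("mature arms that cannot fit the hairpin are a configuration error", {
  expect_error(sim_config(premirna_len = c(30, 40), mature_len = c(35, 36)),
               "mature_len")
  expect_error(sim_config(premirna_len = c(50, 60), mature_len = c(22, 23)),
               "cannot hold")
})

test_that("read simulation is deterministic, exact in count, and edits at the configured level", {
  refs <- tiny_refs()
  ed <- injected_edits("hpA", 8, ref = "C", alt = "A", editing_level = 0.3)
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 4000, edits = ed, rng_seed = 5,
                    adapter = "")
  s1 <- simulate_reads(refs, cfg, "FC1", seed = 42)
  s2 <- simulate_reads(refs, cfg, "FC1", seed = 42)
  expect_identical(s1, s2)
  expect_identical(nrow(s1$reads), 4000L)

  # realized editing close to the configured level (binomial concentration)
  tr <- s1$truth
  expect_lte(tr$n_edited, tr$n_covering)
  expect_gt(tr$n_covering, 500)
  frac <- tr$n_edited / tr$n_covering
  expect_true(frac > 0.26 && frac < 0.34)
})

test_that("a noise-free, edit-free simulation emits exact mature subsequences", {
  refs <- tiny_refs()
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 300, base_error_rate = 1e-12,
                    adapter = "", rng_seed = 2)
  s <- simulate_reads(refs, cfg, "S", seed = 9)
  mats <- unname(mature_sequences(refs))
  expect_true(all(s$reads$sequence %in% mats))
})

test_that("quality strings encode the error rate as a Phred score", {
  expect_identical(phred_char(0.001), "?")  # Q30 -> chr(63)
  refs <- tiny_refs()
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 10, adapter = "", rng_seed = 2)
  s <- simulate_reads(refs, cfg, "S", seed = 1)
  expect_true(all(strsplit(paste(s$reads$quality, collapse = ""),
                           "")[[1]] == "?"))
  expect_equal(qual_to_errprob("?"), 0.001, tolerance = 1e-12)
})

test_that("adapter read-through fills the instrument length and is recoverable", {
  refs <- tiny_refs()
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 50, base_error_rate = 1e-12,
                    rng_seed = 2)  # default TruSeq-style adapter, 50 bases
  s <- simulate_reads(refs, cfg, "S", seed = 3)
  expect_true(all(nchar(s$reads$sequence) <= 50))
  expect_true(all(nchar(s$reads$sequence) > 23))
  trimmed <- trim_adapter(s$reads, cfg$adapter)
  expect_true(all(trimmed$sequence %in% unname(mature_sequences(refs))))
  expect_identical(nchar(trimmed$sequence), nchar(trimmed$quality))
})

test_that("an edit whose ref base contradicts the hairpin is rejected", {
  refs <- tiny_refs()
  ed <- injected_edits("hpA", 7, ref = "G", alt = "A", editing_level = 0.5)
  cfg <- sim_config(n_premirnas = 2, premirna_len = c(60, 60),
                    reads_per_sample = 10, edits = ed, rng_seed = 1)
  expect_error(simulate_reads(refs, cfg, "S", seed = 1),
               "does not match the hairpin|does not match hairpin")
})

test_that("known-variant generation masks chosen edits and places decoys elsewhere", {
  refs <- tiny_refs()
  ed <- injected_edits(c("hpA", "hpB"), c(7, 10), ref = c("C", "G"),
                       alt = c("A", "T"), editing_level = c(0.3, 0.3))
  v <- generate_known_variants(refs, ed, mask = 1, n_decoys = 10, seed = 4)
  expect_identical(nrow(v), 11L)
  expect_true(any(v$premirna_id == "hpA" & v$pos == 7))
  # decoys never coincide with an injected edit
  decoys <- v[-1, ]
  expect_false(any(paste(decoys$premirna_id, decoys$pos) %in%
                     paste(ed$premirna_id, ed$position)))
  # decoy ref matches the hairpin base
  expect_identical(unname(substr(refs$seq[decoys$premirna_id], decoys$pos,
                                 decoys$pos)), decoys$ref)
  # empty request yields an empty, well-formed table
  v0 <- generate_known_variants(refs, ed)
  expect_identical(nrow(v0), 0L)
})

test_that("mean alt fraction at an edited site converges to level plus error leakage", {
  # single-mature reference so every read covers the site at read position 6
  base <- tiny_refs()
  refs <- premirna_set(base$seq["hpA"], base$matures[1, ])
  lev <- 0.2; err <- 0.01
  ed <- injected_edits("hpA", 8, ref = "C", alt = "A", editing_level = lev)
  cfg <- sim_config(n_premirnas = 1, premirna_len = c(60, 60),
                    reads_per_sample = 2000, edits = ed, rng_seed = 1,
                    base_error_rate = err, adapter = "")
  fracs <- vapply(1:30, function(i) {
    s <- simulate_reads(refs, cfg, "S", seed = 100 + i)
    mean(substr(s$reads$sequence, 6, 6) == "A")
  }, numeric(1))
  # expected alt fraction: edited reads minus error flips away, plus error
  # flips from the unedited remainder into the alt base
  expected <- lev * (1 - err) + (1 - lev) * err / 3
  se <- sd(fracs) / sqrt(length(fracs))
  expect_lt(abs(mean(fracs) - expected), 3 * se + 1e-3)
})
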