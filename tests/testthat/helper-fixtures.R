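# Shared fixtures, built in code at test time.

# Two toy hairpins with known mature arms. hpA positions 3..24 are the 5p
# mature; its seed region is hairpin positions 4..10.
tiny_refs <- function() {
  premirna_set(
    c(hpA = paste0("GG", "ACGTTCAGGTCCATGAACGTTC", "AACCGGTTAACC",
                   "GAACGTTCATGGACCTGAACGT", "AT"),
      hpB = paste0("TT", "CCGGATATCCGGAGTCAGTCAG", "GGGTTTCCCAAA",
                   "CTGACTGACTCCGGATATCCGG", "CG")),
    data.frame(
      premirna_id = c("hpA", "hpA", "hpB"),
      mature_name = c("miR-A-5p", "miR-A-3p", "miR-B"),
      arm = c("5p", "3p", "mature"),
      start = c(3L, 37L, 3L),
      end = c(24L, 58L, 24L),
      stringsAsFactors = FALSE))
}

# Reads as the package represents them.
make_reads <- function(seqs, quals = NULL, ids = NULL) {
  if (is.null(quals)) quals <- strrep("?", nchar(seqs))  # Q30
  if (is.null(ids)) ids <- sprintf("r%03d", seq_along(seqs))
  data.frame(read_id = ids, sequence = seqs, quality = quals,
             stringsAsFactors = FALSE)
}

# Independent brute-force aligner: enumerate every (hairpin, offset) pair,
# count mismatches by character comparison, apply the unique-best rule.
# Deliberately shares no code with align_read().
brute_force_align <- function(sequence, refs) {
  L <- nchar(sequence)
  rs <- strsplit(sequence, "")[[1]]
  hits <- list()
  for (id in names(refs$seq)) {
    hp <- refs$seq[[id]]
    M <- nchar(hp)
    if (M < L) next
    for (off in seq_len(M - L + 1)) {
      win <- strsplit(substr(hp, off, off + L - 1), "")[[1]]
      nm <- sum(win != rs)
      if (nm <= 1) hits[[length(hits) + 1]] <-
          list(id = id, off = as.integer(off), nm = as.integer(nm))
    }
  }
  if (!length(hits)) return(list(status = "unaligned"))
  nms <- vapply(hits, `[[`, integer(1), "nm")
  best <- min(nms)
  at <- which(nms == best)
  if (length(at) > 1) return(list(status = "ambiguous"))
  list(status = "aligned", premirna_id = hits[[at]]$id,
       offset = hits[[at]]$off, n_mismatches = best)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

make_events <- function(tissue, n_by_type, n_seed, canonical = FALSE) {
  # synthetic unique-event table with controlled type and seed counts
  types <- rep(names(n_by_type), unlist(n_by_type))
  n <- length(types)
  df <- data.frame(
    mirna_name = sprintf("m%04d-%s", seq_len(n), tissue),
    arm = "5p", mature_position = c(rep(3L, n_seed),
                                    rep(12L, n - n_seed)),
    subst_type = types,
    category = if (canonical) "canonical" else "non-canonical",
    seed = c(rep(TRUE, n_seed), rep(FALSE, n - n_seed)),
    samples_present = paste0(tissue, "1"), recurrence = 1L,
    stringsAsFactors = FALSE)
  df[[paste0("rec_", tissue)]] <- 1L
  df$tissues <- tissue
  df$recurring <- FALSE
  df$max_level <- 0.1
  df
}
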