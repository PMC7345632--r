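#' Simulation configuration
#'
#' Defines the study conditions emulated by the synthetic small RNA-seq
#' generator: hairpin references with mature arms, heterogeneous expression,
#' site-specific editing, and Phred-calibrated sequencing error. Defaults
#' emulate a paired two-tissue brain small RNA-seq design at desk scale:
#' 50-base single-end reads, a TruSeq-style 3' adapter read through when the
#' insert is shorter than the instrument length, constant Q30 base quality.
#'
#' @param n_premirnas number of hairpins to generate.
#' @param premirna_len length-2 integer range of hairpin lengths (bases).
#' @param mature_len length-2 integer range of mature miRNA lengths (bases).
#' @param n_samples number of samples per run (ids are supplied at
#'   simulation time; this is the default count used by [run_pipeline()]).
#' @param reads_per_sample reads written per sample (exactly).
#' @param expression_sigma log-normal sigma of per-mature relative abundance.
#' @param edits data.frame of injected edits (see [injected_edits()]), or
#'   `NULL` for an error-only simulation.
#' @param base_error_rate per-base sequencing error probability; encoded in
#'   the quality string (0.001 encodes as Q30).
#' @param quality_jitter integer sd of per-base Phred jitter around the
#'   nominal score (0 = constant quality).
#' @param adapter 3' adapter sequence appended when the insert is shorter
#'   than `instrument_len`; `""` disables adapter read-through.
#' @param instrument_len instrument read length (bases).
#' @param prob_two_arm probability that a hairpin carries both a 5p and a 3p
#'   mature annotation (otherwise a single arm).
#' @param rng_seed integer seed; identical configurations and seeds yield
#'   byte-identical outputs.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_premirnas = 50,
                       premirna_len = c(70, 110),
                       mature_len = c(20, 23),
                       n_samples = 9,
                       reads_per_sample = 100000,
                       expression_sigma = 1,
                       edits = NULL,
                       base_error_rate = 0.001,
                       quality_jitter = 0,
                       adapter = "TGGAATTCTCGGGTGCCAAGG",
                       instrument_len = 50,
                       prob_two_arm = 0.8,
                       rng_seed = 1) {
  cfg <- list(n_premirnas = as.integer(n_premirnas),
              premirna_len = as.integer(premirna_len),
              mature_len = as.integer(mature_len),
              n_samples = as.integer(n_samples),
              reads_per_sample = as.integer(reads_per_sample),
              expression_sigma = expression_sigma,
              edits = edits,
              base_error_rate = base_error_rate,
              quality_jitter = quality_jitter,
              adapter = toupper(chartr("Uu", "Tt", adapter)),
              instrument_len = as.integer(instrument_len),
              prob_two_arm = prob_two_arm,
              rng_seed = as.integer(rng_seed))
  if (cfg$n_premirnas < 0) stopf("n_premirnas must be >= 0")
  if (length(cfg$premirna_len) != 2 || any(cfg$premirna_len <= 0) ||
      diff(cfg$premirna_len) < 0) stopf("premirna_len must be a positive range")
  if (length(cfg$mature_len) != 2 || any(cfg$mature_len <= 0) ||
      diff(cfg$mature_len) < 0) stopf("mature_len must be a positive range")
  if (max(cfg$mature_len) >= min(cfg$premirna_len)) {
    stopf("mature_len must be smaller than premirna_len")
  }
  # both arms plus the worst-case end offsets must fit in the shortest hairpin
  if (2 * max(cfg$mature_len) + 14 > min(cfg$premirna_len)) {
    stopf("hairpins of length %d cannot hold two %d-base arms",
          min(cfg$premirna_len), max(cfg$mature_len))
  }
  if (cfg$reads_per_sample < 0 || cfg$n_samples < 0) {
    stopf("sample and read counts must be >= 0")
  }
  if (cfg$base_error_rate <= 0 || cfg$base_error_rate >= 1) {
    stopf("base_error_rate must be in (0,1)")
  }
  if (cfg$prob_two_arm < 0 || cfg$prob_two_arm > 1) {
    stopf("prob_two_arm must be in [0,1]")
  }
  if (grepl("[^ACGT]", cfg$adapter)) stopf("adapter must be over {A,C,G,T}")
  if (!is.null(edits)) cfg$edits <- as_injected_edits(edits)
  class(cfg) <- "sim_config"
  cfg
}

#' Injected editing events
#'
#' Describes the ground-truth edits the simulator plants: for reads of the
#' listed samples that cover `position`, the hairpin base `ref` is replaced
#' by `alt` with probability `editing_level` (before sequencing error is
#' applied).
#'
#' @param premirna_id hairpin id.
#' @param position 1-based position on the hairpin.
#' @param ref,alt reference and alternate base; `ref` must equal the hairpin
#'   base at `position` (checked at simulation time), `alt` must differ.
#' @param editing_level per-read substitution probability in (0, 1].
#' @param samples comma-separated sample ids the edit applies to; `""`
#'   applies it to every sample.
#' @return data.frame of class `injected_edits`.
#' @export
injected_edits <- function(premirna_id, position, ref, alt, editing_level,
                           samples = "") {
  df <- data.frame(premirna_id = premirna_id, position = as.integer(position),
                   ref = toupper(ref), alt = toupper(alt),
                   editing_level = editing_level, samples = samples,
                   stringsAsFactors = FALSE)
  as_injected_edits(df)
}

as_injected_edits <- function(df) {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  need <- c("premirna_id", "position", "ref", "alt", "editing_level")
  miss <- setdiff(need, names(df))
  if (length(miss)) stopf("edit table lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(df$samples)) df$samples <- ""
  df$samples[is.na(df$samples)] <- ""
  if (any(df$ref == df$alt)) stopf("injected edit with alt == ref")
  if (any(df$editing_level <= 0 | df$editing_level > 1)) {
    stopf("editing_level must be in (0,1]")
  }
  class(df) <- c("injected_edits", "data.frame")
  df
}

edit_applies <- function(samples_field, sample_id) {
  samples_field == "" |
    vapply(strsplit(samples_field, ","),
           function(s) sample_id %in% trimws(s), logical(1))
}

#' Generate a synthetic pre-miRNA reference set
#'
#' Draws `n_premirnas` random hairpins over {A,C,G,T}; each carries a 5p
#' and/or 3p mature annotation near its ends, fully inside the hairpin.
#' Deterministic under `config$rng_seed`.
#'
#' @param config a [sim_config()].
#' @return a [premirna_set()].
#' @export
generate_premirnas <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_premirnas
  if (n == 0) return(premirna_set(character(0)))
  with_seed(config$rng_seed, {
    lens <- sample(seq(config$premirna_len[1], config$premirna_len[2]), n,
                   replace = TRUE)
    seqs <- vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    ids <- sprintf("sim-mir-%03d", seq_len(n))
    names(seqs) <- ids
    rows <- vector("list", n)
    for (i in seq_len(n)) {
      two <- stats::runif(1) < config$prob_two_arm
      arms <- if (two) c("5p", "3p") else sample(c("5p", "3p"), 1)
      mk <- list()
      for (arm in arms) {
        mlen <- sample(seq(config$mature_len[1], config$mature_len[2]), 1)
        if (arm == "5p") {
          s <- sample(2:8, 1)
          e <- s + mlen - 1L
        } else {
          e <- lens[i] - sample(1:7, 1)
          s <- e - mlen + 1L
        }
        mk[[arm]] <- data.frame(
          premirna_id = ids[i],
          mature_name = sprintf("sim-miR-%03d-%s", i, arm),
          arm = arm, start = s, end = e, stringsAsFactors = FALSE)
      }
      rows[[i]] <- do.call(rbind, mk)
    }
    premirna_set(seqs, do.call(rbind, rows))
  })
}

#' Simulate one sample's small RNA reads
#'
#' Reads are full mature-arm subsequences assigned multinomially under a
#' log-normal per-mature abundance model. At each injected edit site the
#' alternate base is emitted with probability `editing_level` (for reads of
#' the samples the edit applies to); independent per-base errors then
#' substitute a uniformly random different base at `base_error_rate`; when an
#' adapter is configured and the insert is shorter than the instrument
#' length, the 3' adapter is read through. Quality strings encode the error
#' rate as a constant Phred score (0.001 -> Q30).
#'
#' @param refs a [premirna_set()].
#' @param config a [sim_config()].
#' @param sample_id sample identifier used in read names and edit matching.
#' @param seed integer seed for this sample (defaults to `config$rng_seed`).
#' @return list with `reads` (data.frame `read_id`, `sequence`, `quality`)
#'   and `truth` (the realized truth table: one row per injected edit with
#'   `n_covering` reads over the site and `n_edited` reads that received the
#'   alternate base, before sequencing error).
#' @export
simulate_reads <- function(refs, config, sample_id, seed = config$rng_seed) {
  stopifnot(inherits(config, "sim_config"), inherits(refs, "premirna_set"))
  m <- refs$matures
  nread <- config$reads_per_sample
  edits <- config$edits
  if (!is.null(edits) && nrow(edits)) {
    hp_base <- substr(refs$seq[edits$premirna_id], edits$position,
                      edits$position)
    bad <- hp_base != edits$ref
    if (any(bad)) {
      stopf("injected edit at %s:%d: ref '%s' does not match hairpin base '%s'",
            edits$premirna_id[bad][1], edits$position[bad][1],
            edits$ref[bad][1], hp_base[bad][1])
    }
  }
  empty_truth <- data.frame(
    sample_id = character(), premirna_id = character(), position = integer(),
    ref = character(), alt = character(), editing_level = numeric(),
    mature_name = character(), n_covering = integer(), n_edited = integer(),
    stringsAsFactors = FALSE)
  if (nread == 0 || nrow(m) == 0) {
    return(list(reads = data.frame(read_id = character(),
                                   sequence = character(),
                                   quality = character(),
                                   stringsAsFactors = FALSE),
                truth = empty_truth))
  }
  with_seed(seed, {
    mseq <- mature_sequences(refs)
    abund <- stats::rlnorm(nrow(m), meanlog = 0,
                           sdlog = config$expression_sigma)
    midx <- sample.int(nrow(m), nread, replace = TRUE, prob = abund)
    seqs <- unname(mseq[midx])
    lens <- nchar(seqs)

    truth <- empty_truth
    if (!is.null(edits) && nrow(edits)) {
      for (j in seq_len(nrow(edits))) {
        e <- edits[j, ]
        if (!edit_applies(e$samples, sample_id)) next
        hit_m <- which(m$premirna_id == e$premirna_id &
                         m$start <= e$position & m$end >= e$position)
        n_cov_total <- 0L
        n_edit_total <- 0L
        mat_names <- character(0)
        for (mi in hit_m) {
          ridx <- which(midx == mi)
          n_cov_total <- n_cov_total + length(ridx)
          mat_names <- c(mat_names, m$mature_name[mi])
          if (!length(ridx)) next
          rpos <- e$position - m$start[mi] + 1L
          edited <- ridx[stats::runif(length(ridx)) < e$editing_level]
          if (length(edited)) {
            substr(seqs[edited], rpos, rpos) <- e$alt
            n_edit_total <- n_edit_total + length(edited)
          }
        }
        if (!length(hit_m)) {
          warnf("injected edit at %s:%d is outside every mature annotation; no reads cover it",
                e$premirna_id, e$position)
        }
        truth <- rbind(truth, data.frame(
          sample_id = sample_id, premirna_id = e$premirna_id,
          position = e$position, ref = e$ref, alt = e$alt,
          editing_level = e$editing_level,
          mature_name = paste(mat_names, collapse = ","),
          n_covering = n_cov_total, n_edited = n_edit_total,
          stringsAsFactors = FALSE))
      }
    }

    # sequencing error: per-read error-count, then positions within the read
    nerr <- stats::rbinom(nread, lens, config$base_error_rate)
    which_err <- which(nerr > 0)
    for (ri in which_err) {
      ps <- sample.int(lens[ri], nerr[ri])
      for (p in ps) {
        cur <- substr(seqs[ri], p, p)
        substr(seqs[ri], p, p) <- sample(setdiff(DNA_BASES, cur), 1)
      }
    }

    # adapter read-through and qualities
    if (nzchar(config$adapter)) {
      out_len <- pmin(config$instrument_len, lens + nchar(config$adapter))
      need_ad <- out_len > lens
      seqs[need_ad] <- substr(paste0(seqs[need_ad], config$adapter), 1,
                              out_len[need_ad])
      lens <- out_len
    }
    q0 <- round(-10 * log10(config$base_error_rate))
    if (config$quality_jitter > 0) {
      quals <- vapply(lens, function(L) {
        q <- pmin(41L, pmax(2L, round(stats::rnorm(L, q0,
                                                   config$quality_jitter))))
        intToUtf8(q + 33L)
      }, character(1))
    } else {
      qc <- intToUtf8(q0 + 33L)
      quals <- strrep(qc, lens)
    }
    list(reads = data.frame(
           read_id = sprintf("%s:r%06d", sample_id, seq_len(nread)),
           sequence = seqs, quality = quals, stringsAsFactors = FALSE),
         truth = truth)
  })
}

#' Generate a known-DNA-variant table for filter testing
#'
#' Emits a chosen subset of the injected-edit positions (so the DNA-variant
#' filter can be shown to remove them) plus `n_decoys` positions that carry
#' no injected edit (so the filter can be shown to retain true calls).
#'
#' @param refs a [premirna_set()].
#' @param edits an [injected_edits()] table (or `NULL`).
#' @param mask integer indices of `edits` rows to include as known variants.
#' @param n_decoys number of decoy positions drawn uniformly over hairpin
#'   positions that carry no injected edit.
#' @param seed integer seed for decoy placement.
#' @return data.frame `premirna_id`, `pos`, `ref`, `alt`.
#' @export
generate_known_variants <- function(refs, edits = NULL, mask = integer(0),
                                    n_decoys = 0, seed = 1) {
  rows <- list()
  if (!is.null(edits) && length(mask)) {
    e <- edits[mask, , drop = FALSE]
    rows$masked <- data.frame(premirna_id = e$premirna_id, pos = e$position,
                              ref = e$ref, alt = e$alt,
                              stringsAsFactors = FALSE)
  }
  if (n_decoys > 0) {
    lens <- nchar(refs$seq)
    all_pos <- data.frame(
      premirna_id = rep(names(refs$seq), lens),
      pos = unlist(lapply(lens, seq_len), use.names = FALSE),
      stringsAsFactors = FALSE)
    if (!is.null(edits) && nrow(edits)) {
      taken <- paste(edits$premirna_id, edits$position)
      all_pos <- all_pos[!(paste(all_pos$premirna_id, all_pos$pos) %in% taken), ]
    }
    if (nrow(all_pos) < n_decoys) stopf("not enough positions for %d decoys",
                                        n_decoys)
    rows$decoys <- with_seed(seed, {
      pick <- all_pos[sample.int(nrow(all_pos), n_decoys), ]
      pick$ref <- substr(refs$seq[pick$premirna_id], pick$pos, pick$pos)
      pick$alt <- vapply(pick$ref,
                         function(b) sample(setdiff(DNA_BASES, b), 1),
                         character(1))
      rownames(pick) <- NULL
      pick
    })
  }
  if (!length(rows)) {
    return(data.frame(premirna_id = character(), pos = integer(),
                      ref = character(), alt = character(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Generate random 3'-UTR sequences
#'
#' Uniform-random UTRs for exercising the toy seed-match target predictor;
#' they carry no planted regulatory structure.
#'
#' @param n number of UTRs.
#' @param len length-2 range of UTR lengths (bases).
#' @param seed integer seed.
#' @return named character vector (`utr0001`, ...).
#' @export
generate_utrs <- function(n, len = c(500, 2000), seed = 1) {
  with_seed(seed, {
    lens <- sample(seq(len[1], len[2]), n, replace = TRUE)
    out <- vapply(lens, function(L) {
      paste(sample(DNA_BASES, L, replace = TRUE), collapse = "")
    }, character(1))
    names(out) <- sprintf("utr%04d", seq_len(n))
    out
  })
}
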