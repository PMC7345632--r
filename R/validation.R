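#' Family-wise false-call rate on error-only simulations
#'
#' Simulates sequencing-error-only samples (no injected edits) against a
#' fixed synthetic reference set and reports the fraction of replicates in
#' which the detection stage makes at least one significant call. Under the
#' binomial error model with per-sample Bonferroni correction this fraction
#' is controlled at the significance level.
#'
#' @param n_reps number of replicate samples.
#' @param n_premirnas,reads_per_sample,base_error_rate simulation scale (see
#'   [sim_config()]); reads are emitted without adapter read-through so the
#'   experiment isolates the detection stage.
#' @param alpha,min_cov,min_level calling thresholds (see [call_events()]).
#' @param seed master seed; the reference set derives from it and each
#'   replicate from an offset of it.
#' @return list with `n_reps`, `n_false_reps` (replicates with >= 1 call),
#'   `fwer` (their fraction) and `total_false_calls`.
#' @export
fwer_null_experiment <- function(n_reps = 200, n_premirnas = 50,
                                 reads_per_sample = 100000,
                                 base_error_rate = 0.001, alpha = 0.05,
                                 min_cov = 10, min_level = 0.01, seed = 1) {
  cfg <- sim_config(n_premirnas = n_premirnas,
                    reads_per_sample = reads_per_sample,
                    base_error_rate = base_error_rate, adapter = "",
                    rng_seed = seed)
  refs <- generate_premirnas(cfg)
  index <- build_align_index(refs)
  n_false <- 0L
  total <- 0L
  for (i in seq_len(n_reps)) {
    s <- simulate_reads(refs, cfg, sprintf("rep%03d", i),
                        seed = derive_seed(seed, i))
    det <- detect_editing(s$reads, refs, sample_id = sprintf("rep%03d", i),
                          adapter = "", alpha = alpha, min_cov = min_cov,
                          min_level = min_level, index = index)
    if (nrow(det$calls) > 0) n_false <- n_false + 1L
    total <- total + nrow(det$calls)
  }
  list(n_reps = n_reps, n_false_reps = n_false, fwer = n_false / n_reps,
       total_false_calls = total)
}

# Deterministically pick edit sites on a generated reference set:
# a seed site, a non-seed site, an A-ref seed site (for the A-to-C
# exclusion check) and a fourth site to be masked as a known DNA variant.
pick_validation_edits <- function(refs) {
  m <- refs$matures[refs$matures$arm == "5p", , drop = FALSE]
  base_at <- function(row, mp) {
    pos <- m$start[row] + mp - 1L
    substr(refs$seq[[m$premirna_id[row]]], pos, pos)
  }
  # an A in the seed window of some mature, for the A-to-C edit
  a_row <- NA_integer_; a_mp <- NA_integer_
  for (row in seq_len(nrow(m))) {
    for (mp in 2:8) {
      if (base_at(row, mp) == "A") { a_row <- row; a_mp <- mp; break }
    }
    if (!is.na(a_row)) break
  }
  if (is.na(a_row)) stopf("no A base found in any seed window")
  others <- setdiff(seq_len(nrow(m)), a_row)[1:3]
  alt_for <- function(b) setdiff(c("G", "T", "A"), b)[1]  # never C
  rows <- list(
    seed_site = list(row = others[1], mp = 3L),
    nonseed_site = list(row = others[2], mp = 11L),
    atoc_site = list(row = a_row, mp = a_mp),
    masked_site = list(row = others[3], mp = 5L))
  ed <- do.call(rbind, lapply(names(rows), function(nm) {
    x <- rows[[nm]]
    pos <- m$start[x$row] + x$mp - 1L
    ref <- base_at(x$row, x$mp)
    alt <- if (nm == "atoc_site") "C" else alt_for(ref)
    data.frame(role = nm, premirna_id = m$premirna_id[x$row],
               position = pos, ref = ref, alt = alt,
               mature_name = m$mature_name[x$row], mature_position = x$mp,
               stringsAsFactors = FALSE)
  }))
  ed$editing_level <- c(0.3, 0.15, 0.3, 0.3)
  ed$samples <- ""
  ed
}

#' Recovery of injected edits through the full detection and filter chain
#'
#' Plants four edits on a synthetic reference set — a seed site, a non-seed
#' site, an A-to-C site (excluded class) and a site masked as a known DNA
#' variant — then, over replicate samples, runs detection, DNA-variant
#' filtering, A-to-C exclusion and classification, and scores whether each
#' injected site is recovered with its exact identity (miRNA, mature
#' position, substitution label, seed flag). Sites are scored only in
#' replicates where their realized coverage reaches `min_truth_cov`.
#'
#' @param n_reps number of replicate samples.
#' @param n_premirnas,reads_per_sample simulation scale.
#' @param min_truth_cov minimum realized site coverage for a replicate to
#'   count towards the recovery denominator.
#' @param seed master seed.
#' @return list with `recovery_rate` (detectable seed + non-seed sites
#'   recovered with correct identity), `n_eligible`, `n_recovered`,
#'   `atoc_recovery` and `masked_recovery` (fractions, expected 0), and the
#'   planted `edits` table.
#' @export
edit_recovery_experiment <- function(n_reps = 100, n_premirnas = 10,
                                     reads_per_sample = 20000,
                                     min_truth_cov = 100, seed = 1) {
  cfg0 <- sim_config(n_premirnas = n_premirnas,
                     reads_per_sample = reads_per_sample, adapter = "",
                     rng_seed = seed)
  refs <- generate_premirnas(cfg0)
  ed <- pick_validation_edits(refs)
  cfg <- sim_config(n_premirnas = n_premirnas,
                    reads_per_sample = reads_per_sample, adapter = "",
                    rng_seed = seed,
                    edits = ed[c("premirna_id", "position", "ref", "alt",
                                 "editing_level", "samples")])
  variants <- data.frame(
    premirna_id = ed$premirna_id[ed$role == "masked_site"],
    pos = ed$position[ed$role == "masked_site"],
    ref = ed$ref[ed$role == "masked_site"],
    alt = ed$alt[ed$role == "masked_site"], stringsAsFactors = FALSE)
  index <- build_align_index(refs)
  expected_label <- rep(NA_character_, nrow(ed))
  scored <- ed$role %in% c("seed_site", "nonseed_site")
  expected_label[scored] <- classify_type(ed$ref[scored],
                                          ed$alt[scored])$label
  n_elig <- 0L; n_rec <- 0L
  n_atoc <- 0L; n_masked <- 0L; n_excluded_elig <- 0L
  for (i in seq_len(n_reps)) {
    sid <- sprintf("rep%03d", i)
    s <- simulate_reads(refs, cfg, sid, seed = derive_seed(seed, i))
    det <- detect_editing(s$reads, refs, sample_id = sid, adapter = "",
                          index = index)
    calls <- exclude_substitution_class(
      filter_known_variants(det$calls, variants))
    ann <- annotate_calls(calls, refs)
    for (j in seq_len(nrow(ed))) {
      tr <- s$truth[s$truth$premirna_id == ed$premirna_id[j] &
                      s$truth$position == ed$position[j], ]
      covered <- nrow(tr) == 1 && tr$n_covering >= min_truth_cov
      hit <- ann[ann$mirna_name == ed$mature_name[j] &
                   ann$mature_position == ed$mature_position[j], ,
                 drop = FALSE]
      role <- ed$role[j]
      if (role %in% c("seed_site", "nonseed_site")) {
        if (!covered) next
        n_elig <- n_elig + 1L
        want_seed <- ed$mature_position[j] >= 2 && ed$mature_position[j] <= 8
        ok <- nrow(hit) == 1 &&
          hit$subst_type == expected_label[j] &&
          identical(hit$seed, want_seed) &&
          hit$alt_base == ed$alt[j]
        if (ok) n_rec <- n_rec + 1L
      } else {
        n_excluded_elig <- n_excluded_elig + 1L
        if (nrow(hit) > 0) {
          if (role == "atoc_site") n_atoc <- n_atoc + 1L
          if (role == "masked_site") n_masked <- n_masked + 1L
        }
      }
    }
  }
  list(recovery_rate = if (n_elig) n_rec / n_elig else NA_real_,
       n_eligible = n_elig, n_recovered = n_rec,
       atoc_recovery = n_atoc / n_reps, masked_recovery = n_masked / n_reps,
       edits = ed)
}
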