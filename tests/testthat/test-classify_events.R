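test_that("substitution classification follows the canonical/non-canonical rule", {
  expect_identical(classify_type("A", "G"),
                   data.frame(label = "A-to-I", category = "canonical",
                              stringsAsFactors = FALSE))
  expect_identical(classify_type("C", "T")$label, "C-to-U")
  expect_identical(classify_type("C", "T")$category, "canonical")
  expect_identical(classify_type("C", "A"),
                   data.frame(label = "C-to-A", category = "non-canonical",
                              stringsAsFactors = FALSE))
  expect_identical(classify_type("G", "T")$label, "G-to-U")
  expect_identical(classify_type("T", "G")$label, "U-to-G")
  expect_identical(classify_type("G", "T")$category, "non-canonical")
  # A-to-C must have been excluded upstream
  expect_error(classify_type("A", "C"), "excluded")
  expect_error(classify_type("A", "A"), "differ")
})

test_that("mature positions and the 2-8 seed window are computed from hairpin coordinates", {
  refs <- tiny_refs()  # hpA 5p mature spans 3..24
  loc <- locate_in_mature(rep("hpA", 4), c(5L, 11L, 3L, 30L), refs)
  expect_identical(loc$mature_position, c(3L, 9L, 1L, NA))
  expect_identical(loc$seed, c(TRUE, FALSE, FALSE, NA))
  expect_identical(loc$in_mature, c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(loc$arm[1], "5p")
  # the single-mature hairpin keeps its "mature" arm label
  locB <- locate_in_mature("hpB", 6L, refs)
  expect_identical(locB$arm, "mature")
  # seed flag over all mature positions 1..23 matches the [2,8] rule
  pos <- 1:22
  loc_all <- locate_in_mature(rep("hpA", 22), pos + 2L, refs)
  expect_identical(loc_all$seed, pos >= 2 & pos <= 8)
})

events_fixture <- function() {
  # three samples in FC, two in CC; one shared event, one FC-only
  data.frame(
    sample_id = c("FC1", "FC2", "FC3", "CC1", "FC1"),
    premirna_id = "hpA", position = c(5L, 5L, 5L, 5L, 11L),
    ref_base = c("C", "C", "C", "C", "G"),
    alt_base = c("A", "A", "A", "A", "T"),
    editing_level = c(0.2, 0.25, 0.3, 0.1, 0.05),
    mirna_name = "miR-A-5p", arm = "5p",
    mature_position = c(3L, 3L, 3L, 3L, 9L),
    seed = c(TRUE, TRUE, TRUE, TRUE, FALSE), in_mature = TRUE,
    subst_type = c("C-to-A", "C-to-A", "C-to-A", "C-to-A", "G-to-U"),
    category = "non-canonical", stringsAsFactors = FALSE)
}

test_that("deduplication merges identities and counts recurrence per tissue", {
  tissues <- c(FC1 = "FC", FC2 = "FC", FC3 = "FC", CC1 = "CC", CC5 = "CC")
  ev <- dedupe_and_recur(events_fixture(), tissues, recur_threshold = 3)
  expect_identical(nrow(ev), 2L)
  shared <- ev[ev$mature_position == 3, ]
  expect_identical(shared$recurrence, 4L)
  expect_identical(shared$rec_FC, 3L)
  expect_identical(shared$rec_CC, 1L)
  expect_true(shared$recurring)
  expect_identical(shared$tissues, "FC,CC")
  fc_only <- ev[ev$mature_position == 9, ]
  expect_identical(fc_only$tissues, "FC")
  expect_false(fc_only$recurring)
  expect_equal(shared$max_level, 0.3)
  # a sample with zero events (CC5) contributes nothing and causes no error
  expect_identical(sort(unique(unlist(
    strsplit(ev$samples_present, ",")))), c("CC1", "FC1", "FC2", "FC3"))
})

test_that("deduplication is a projection: applying the identity grouping twice changes nothing", {
  tissues <- c(FC1 = "FC", FC2 = "FC", FC3 = "FC", CC1 = "CC")
  ev1 <- dedupe_and_recur(events_fixture(), tissues)
  # re-expand one call per (event, sample) and dedupe again
  expanded <- do.call(rbind, lapply(seq_len(nrow(ev1)), function(i) {
    s <- strsplit(ev1$samples_present[i], ",")[[1]]
    data.frame(sample_id = s, mirna_name = ev1$mirna_name[i],
               arm = ev1$arm[i], mature_position = ev1$mature_position[i],
               subst_type = ev1$subst_type[i], category = ev1$category[i],
               seed = ev1$seed[i], editing_level = ev1$max_level[i],
               stringsAsFactors = FALSE)
  }))
  ev2 <- dedupe_and_recur(expanded, tissues)
  expect_identical(ev1[c("mirna_name", "mature_position", "subst_type",
                         "samples_present", "recurrence", "rec_FC",
                         "rec_CC")],
                   ev2[c("mirna_name", "mature_position", "subst_type",
                         "samples_present", "recurrence", "rec_FC",
                         "rec_CC")])
})

test_that("summaries report per-type counts and half-up percentages within category", {
  fc <- make_events("FC", list(`C-to-A` = 50, `G-to-U` = 45, `U-to-G` = 10,
                               `G-to-C` = 8), n_seed = 81)
  fc$rec_CC <- 0L
  cc <- make_events("CC", list(`C-to-A` = 49, `G-to-U` = 31, `U-to-C` = 10),
                    n_seed = 67)
  cc$rec_FC <- 0L
  ev <- rbind(fc[names(fc)], cc[names(fc)])
  attr(ev, "tissue_levels") <- c("FC", "CC")
  sm <- summarize_events(ev)
  fc_tot <- sm$totals[sm$totals$tissue == "FC" &
                        sm$totals$category == "non-canonical", ]
  expect_identical(fc_tot$n_events, 113L)
  expect_equal(fc_tot$pct_seed, 71.68)
  cc_tot <- sm$totals[sm$totals$tissue == "CC" &
                        sm$totals$category == "non-canonical", ]
  expect_equal(cc_tot$pct_seed, 74.44)
  gtu <- sm$types[sm$types$tissue == "FC" & sm$types$subst_type == "G-to-U", ]
  expect_equal(gtu$pct, 39.82)
  # per-type counts add up to the category total
  expect_identical(sum(sm$types$n[sm$types$tissue == "FC"]), 113L)
  # seed% + non-seed% = 100 within rounding
  expect_lt(abs(fc_tot$pct_seed +
                  round_half_up(100 * (113 - 81) / 113, 2) - 100), 0.011)
})

test_that("zero-event categories report undefined (NA) percentages", {
  fc <- make_events("FC", list(`C-to-A` = 3), n_seed = 2)
  sm <- summarize_events(fc)
  can <- sm$totals[sm$totals$category == "canonical", ]
  expect_identical(can$n_events, 0L)
  expect_true(is.na(can$pct_seed))
})

test_that("half-up rounding differs from banker's rounding where it matters", {
  expect_equal(round_half_up(0.125, 2), 0.13)
  expect_equal(round_half_up(44.2477876, 2), 44.25)
  expect_equal(round_half_up(0, 2), 0)
})
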