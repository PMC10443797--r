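test_that("percent rescue matches the defining formula on hand examples", {
  # splicing convention: PSI values with the control mean as reference
  expect_equal(percent_rescue(0.8, 0.5, 0.5), 100)
  expect_equal(percent_rescue(0.8, 0.62, 0.5), 60)
  expect_equal(percent_rescue(0.8, 0.4, 0.5), 400 / 3)
  # gene convention: vs-control log2FCs, reference 0
  expect_equal(percent_rescue(3.0, 4.0), -100 / 3)
  # denominator guard
  expect_true(is.na(percent_rescue(0.5, 0.4, 0.5)))
})

test_that("rescue categories follow the printed boundaries", {
  expect_equal(as.character(classify_rescue(60)), "rescued")
  expect_equal(as.character(classify_rescue(110)), "overrescued")
  expect_equal(as.character(classify_rescue(10)), "unchanged")
  expect_equal(as.character(classify_rescue(-10)), "unchanged")
  expect_equal(as.character(classify_rescue(-25)), "misrescued")
  expect_equal(as.character(classify_rescue(0)), "unchanged")
  expect_error(classify_rescue(NaN), class = "dmrescue_validation_error")
})

test_that("dysregulation scores average absolute deviations", {
  expect_equal(dysregulation_score(c(0.3, -0.25, 0.4)), 0.95 / 3)
  expect_equal(dysregulation_score(c(0, 0, 0)), 0)
  expect_error(dysregulation_score(numeric(0)),
               class = "dmrescue_validation_error")
  # order invariance
  set.seed(3)
  d <- rnorm(20)
  expect_equal(dysregulation_score(d), dysregulation_score(rev(d)))
})

test_that("percent of units rescued counts only the rescued category by default", {
  rec <- data.frame(unit_id = paste0("u", 1:4), subject_id = "P1",
                    modality = "gene", pre_effect = 1, post_effect = 0,
                    percent_rescue = c(60, 120, -40, 0),
                    category = classify_rescue(c(60, 120, -40, 0)),
                    defined = TRUE)
  expect_equal(percent_units_rescued(rec), 25)
  expect_equal(percent_units_rescued(rec, include_overrescued = TRUE), 50)

  rec6 <- rec[rep(1, 10), ]
  rec6$category <- classify_rescue(c(rep(60, 6), rep(0, 4)))
  expect_equal(percent_units_rescued(rec6), 60)

  undef <- rec; undef$defined <- FALSE
  expect_warning(out <- percent_units_rescued(undef), "no defined")
  expect_true(is.na(out))

  # undefined-denominator units leave both numerator and denominator
  mixed <- rec
  mixed$defined[3:4] <- FALSE
  expect_equal(percent_units_rescued(mixed), 50)
})

test_that("rescue records wire contrasts to categories and flag guard failures", {
  pre <- contrast_table(c("a", "b", "c"), effect = c(0.4, 0.3, 0))
  post <- contrast_table(c("a", "b", "c"), effect = c(0.0, 0.24, 0))
  rec <- rescue_records(pre, post, c("a", "b", "c"), "P1", "event")
  expect_equal(rec$percent_rescue[rec$unit_id == "a"], 100)
  expect_equal(rec$percent_rescue[rec$unit_id == "b"], 20)
  expect_false(rec$defined[rec$unit_id == "c"])
  expect_equal(as.character(rec$category[rec$unit_id == "b"]), "rescued")
})

test_that("shared-rescue overlaps have exact upset semantics", {
  sets <- list(A = c("a", "b"), B = "b", C = character(0))
  ov <- shared_rescue_overlaps(sets)
  expect_equal(ov$combos$exact_count[ov$combos$combo == "A"], 1L)
  expect_equal(ov$combos$exact_count[ov$combos$combo == "A+B"], 1L)
  expect_equal(nrow(ov$combos), 2L)
  expect_equal(ov$per_subject$n_unique[ov$per_subject$subject_id == "A"], 1L)

  same <- shared_rescue_overlaps(list(X = c("a", "b"), Y = c("a", "b")))
  expect_equal(same$combos$combo, "X+Y")
  expect_equal(same$combos$exact_count, 2L)

  disj <- shared_rescue_overlaps(list(X = "a", Y = "b"))
  expect_equal(sort(disj$combos$combo), c("X", "Y"))
  expect_equal(disj$per_subject$pct_unique, c(100, 100))
})

test_that("overlap counts agree with brute-force subset enumeration", {
  set.seed(11)
  for (i in 1:10) {
    n_sub <- sample(2:5, 1)
    sets <- setNames(lapply(seq_len(n_sub), function(j) {
      sample(paste0("e", 1:12), sample(0:8, 1))
    }), LETTERS[seq_len(n_sub)])
    ov <- shared_rescue_overlaps(sets)
    oracle <- oracle_exact_counts(sets)
    got <- setNames(ov$combos$exact_count, ov$combos$combo)
    expect_equal(sort(names(got)), sort(names(oracle)))
    expect_equal(got[names(oracle)],
                 unlist(oracle)[names(oracle)],
                 ignore_attr = TRUE)
    # conservation: per-subject sums of exact counts equal set sizes
    for (s in names(sets)) {
      in_combo <- vapply(strsplit(ov$combos$combo, "+", fixed = TRUE),
                         function(m) s %in% m, logical(1))
      expect_equal(sum(ov$combos$exact_count[in_combo]),
                   length(unique(sets[[s]])))
    }
  }
})

test_that("panel classification distinguishes no-reads, untested and rescued", {
  rec <- data.frame(unit_id = c("e1", "e2"), subject_id = "P1",
                    modality = "event", pre_effect = 0.4, post_effect = 0,
                    percent_rescue = c(70, 0),
                    category = classify_rescue(c(70, 0)), defined = TRUE)
  out <- suppressWarnings(panel_classify(
    panel = c("e1", "e2", "e3", "e4", "e5"),
    records = rec,
    significant_ids = c("e1", "e2"),
    no_reads_ids = "e3",
    universe = c("e1", "e2", "e3", "e4")))
  expect_equal(out$state, c("rescued", "not_rescued", "no_reads",
                            "not_significant", "no_reads"))
  expect_warning(panel_classify("missing", rec, character(0),
                                universe = "e1"),
                 "absent")
})
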