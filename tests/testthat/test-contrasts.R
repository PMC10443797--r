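test_that("PSI estimation normalizes by effective length and handles no reads", {
  expect_equal(estimate_psi(10, 5, 2, 1), 0.5)
  expect_equal(estimate_psi(7, 0, 2, 1), 1.0)
  expect_true(is.na(estimate_psi(0, 0, 2, 1)))
  expect_error(estimate_psi(1, 1, 0, 1), class = "dmrescue_validation_error")
})

test_that("CPM log2FC matches hand arithmetic and is scale invariant", {
  counts <- matrix(c(400, 600, 400, 600, 100, 900, 100, 900), nrow = 2,
                   dimnames = list(c("g1", "g2"), c("a1", "a2", "b1", "b2")))
  tbl <- estimate_log2fc(counts, c("a1", "a2"), c("b1", "b2"),
                         pseudocount = 0)
  # CPM(g1): 4e5 in group a vs 1e5 in group b -> log2(4) = 2
  expect_equal(tbl$effect[tbl$unit_id == "g1"], 2)

  same <- estimate_log2fc(counts, c("a1", "a2"), c("a1", "a2"))
  expect_equal(same$effect, c(0, 0))

  doubled <- estimate_log2fc(counts * 2, c("a1", "a2"), c("b1", "b2"),
                             pseudocount = 0)
  expect_equal(doubled$effect, tbl$effect)
  expect_error(estimate_log2fc(counts, character(0), "b1"),
               class = "dmrescue_validation_error")
})

test_that("significance attachment reproduces z/BH arithmetic and Welch oracle", {
  # controls (-1, 0, 1) per unit: mean 0, sd 1, so the patient value is the
  # z-score itself; choose values giving two-sided p = .01,.02,.03,.04
  p_want <- c(0.01, 0.02, 0.03, 0.04)
  vals <- qnorm(1 - p_want / 2)
  units <- paste0("u", 1:4)
  ctrl <- matrix(rep(c(-1, 0, 1), each = 4), nrow = 4,
                 dimnames = list(units, c("c1", "c2", "c3")))
  pat <- matrix(vals, 4, 1, dimnames = list(units, "p"))
  tbl <- contrast_table(units, effect = vals)
  out <- attach_significance(tbl, pat, ctrl, method = "welch_bh")
  expect_equal(out$p_value, p_want, tolerance = 1e-12)
  # hand Benjamini-Hochberg: cummin of p * n / i from the largest
  expect_equal(out$fdr, rep(0.04, 4), tolerance = 1e-12)

  # grouped path agrees with stats::t.test (Welch) per unit
  set.seed(5)
  a <- matrix(rnorm(40, 1), 10, 4, dimnames = list(paste0("g", 1:10), NULL))
  b <- matrix(rnorm(50), 10, 5, dimnames = list(paste0("g", 1:10), NULL))
  tbl2 <- contrast_table(paste0("g", 1:10), effect = rowMeans(a) - rowMeans(b))
  out2 <- attach_significance(tbl2, a, b, method = "welch_bh")
  oracle <- sapply(1:10, function(i) t.test(a[i, ], b[i, ])$p.value)
  expect_equal(out2$p_value, oracle, tolerance = 1e-12)

  # zero control SD -> unit excluded with a warning
  ctrl0 <- ctrl; ctrl0[2, ] <- 5
  expect_warning(out3 <- attach_significance(tbl, pat, ctrl0,
                                             method = "welch_bh"),
                 "untestable")
  expect_equal(nrow(out3), 3L)
  expect_equal(attr(out3, "n_untestable"), 1L)

  # external tables pass through untouched
  ext <- contrast_table(units, effect = vals, p_value = p_want,
                        fdr = p_want * 2)
  expect_identical(attach_significance(ext, method = "external"), ext)
})

test_that("significance filters use strict printed inequalities and presets", {
  th_s <- threshold_preset("strength")
  th_c <- threshold_preset("cycling")
  genes <- contrast_table(c("kept", "boundary", "weak_p"),
                          effect = c(2.5, 2.0, 3.0),
                          p_value = c(0.01, 0.01, 0.05),
                          fdr = c(0.02, 0.02, 0.1))
  expect_equal(filter_significant(genes, th_s, "gene"), "kept")

  ev <- contrast_table("ev1", effect = 0.06, p_value = 1e-5, fdr = 0.01)
  expect_equal(filter_significant(ev, th_c, "event"), "ev1")
  expect_equal(filter_significant(ev, th_s, "event"), character(0))

  ev_na <- contrast_table("ev2", effect = 0.3)
  expect_error(filter_significant(ev_na, th_s, "event"),
               class = "dmrescue_validation_error", regexp = "ev2")

  # monotonicity: relaxing any threshold never loses a kept unit
  set.seed(7)
  for (i in 1:20) {
    tbl <- contrast_table(paste0("u", 1:50), effect = rnorm(50, 0, 2),
                          p_value = runif(50), fdr = runif(50))
    strict <- threshold_preset("custom", lfc_min = runif(1, 1, 3),
                               deg_p_max = runif(1, 0.001, 0.05))
    relaxed <- threshold_preset("custom",
                                lfc_min = strict$lfc_min * runif(1, 0.3, 1),
                                deg_p_max = strict$deg_p_max / runif(1, 0.3, 1))
    expect_true(all(filter_significant(tbl, strict, "gene") %in%
                      filter_significant(tbl, relaxed, "gene")))
  }
})

test_that("count and support filters follow the published rules", {
  counts <- matrix(c(5, 9, 5, 12, 100, 100), nrow = 3, byrow = TRUE,
                   dimnames = list(c("low_all", "low_one", "high"),
                                   c("s1", "s2")))
  kept <- filter_low_counts(counts, 10, scope = "every")
  expect_equal(rownames(kept), c("low_one", "high"))
  kept_any <- filter_low_counts(counts, 10, scope = "any")
  expect_equal(rownames(kept_any), "high")

  psi <- matrix(c(0.5, 0.6), 1, 2, dimnames = list("e1", c("s1", "s2")))
  sup <- matrix(c(5L, 6L), 1, 2, dimnames = list("e1", c("s1", "s2")))
  masked <- mask_low_support(psi_matrix(psi, sup), min_reads = 5)
  expect_true(is.na(masked$psi["e1", "s1"]))     # <= 5 reads is masked
  expect_equal(masked$psi["e1", "s2"], 0.6)
})

test_that("delta log2FC is a simple difference, antisymmetric, warns on mismatch", {
  pre <- contrast_table(c("g1", "g2"), effect = c(2.0, 1.0))
  post <- contrast_table(c("g1", "g2"), effect = c(0.5, 1.0))
  d <- delta_log2fc(pre, post, subject_id = "P1")
  expect_equal(d$delta_lfc[d$unit_id == "g1"], -1.5)
  expect_equal(d$delta_lfc[d$unit_id == "g2"], 0)
  d_swap <- delta_log2fc(post, pre)
  expect_equal(d_swap$delta_lfc, -d$delta_lfc)

  post2 <- contrast_table(c("g1", "g3"), effect = c(0.5, 2))
  expect_warning(d2 <- delta_log2fc(pre, post2), "2 unit")
  expect_equal(d2$unit_id, "g1")
})

test_that("antisymmetric individual changes cancel in the grouped contrast", {
  # subject A: gene up 4x pre, back to baseline post; subject B the mirror
  # image; a stable filler gene keeps library sizes comparable
  counts <- cbind(C1 = c(100, 2000), C2 = c(100, 2000),
                  A_pre = c(400, 2000), A_post = c(100, 2000),
                  B_pre = c(100, 2000), B_post = c(400, 2000))
  rownames(counts) <- c("dmpk", "filler")
  ctrl <- c("C1", "C2")
  d_A <- delta_log2fc(estimate_log2fc(counts, "A_pre", ctrl),
                      estimate_log2fc(counts, "A_post", ctrl), "A")
  d_B <- delta_log2fc(estimate_log2fc(counts, "B_pre", ctrl),
                      estimate_log2fc(counts, "B_post", ctrl), "B")
  d_grp <- delta_log2fc(estimate_log2fc(counts, c("A_pre", "B_pre"), ctrl),
                        estimate_log2fc(counts, c("A_post", "B_post"), ctrl))
  expect_gt(abs(d_A$delta_lfc[d_A$unit_id == "dmpk"]), 1)
  expect_gt(abs(d_B$delta_lfc[d_B$unit_id == "dmpk"]), 1)
  expect_lt(abs(d_grp$delta_lfc[d_grp$unit_id == "dmpk"]), 0.05)
})

test_that("planted units are recovered on a low-noise synthetic cohort", {
  co <- tiny_cohort(n_genes = 400L, nb_dispersion = 0.02, noise_sd_psi = 0.01,
                    severity = rep(0.9, 4))
  an <- suppressWarnings(analyze_cohort(co))
  rr <- an$rescue_records
  for (sj in an$subjects) {
    sig_g <- rr$unit_id[rr$subject_id == sj & rr$modality == "gene"]
    truth <- co$truth$dm_gene_ids
    jacc <- length(intersect(sig_g, truth)) / length(union(sig_g, truth))
    expect_gt(jacc, 0.9)
  }
})
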