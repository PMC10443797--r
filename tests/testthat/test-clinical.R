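test_that("percent change and 1-RM averaging are plain arithmetic", {
  expect_equal(percent_change(100, 133), 33)
  expect_equal(percent_change(50, 50), 0)
  expect_equal(percent_change(50, 127), 154)
  expect_error(percent_change(0, 10), class = "dmrescue_validation_error")

  ch <- c(leg_extension = 10, leg_press = 20, hip_abduction = 30, squat = 40)
  expect_equal(average_1rm_change(ch), 25)
  expect_equal(average_1rm_change(ch * 0 + 12), 12)
  expect_equal(average_1rm_change(c(leg_extension = 0, leg_press = 0,
                                    hip_abduction = 0, squat = 100)), 25)
  expect_error(average_1rm_change(ch[-2]), class = "dmrescue_validation_error",
               regexp = "leg_press")
})

test_that("SEMT and MDC satisfy their closed forms at machine precision", {
  expect_equal(semt(1, 0.75, "sqrt"), 0.5)
  expect_equal(semt(1, 0.75, "linear"), 0.25)
  expect_equal(semt(3, 1), 0)
  expect_equal(semt(3, 0), 3)
  expect_error(semt(1, 1.2), class = "dmrescue_validation_error")

  expect_identical(mdc(0), 0)
  # the published SEMT values propagate through MDC = 1.96 * SEMT * sqrt(2)
  expect_equal(mdc(0.41), 1.96 * 0.41 * sqrt(2))
  expect_equal(mdc(3.77), 1.96 * 3.77 * sqrt(2))
  set.seed(2)
  s <- runif(50, 0, 10)
  expect_equal(mdc(s), 1.96 * s * sqrt(2))
})

test_that("meaningful change strictly exceeds the MDC", {
  expect_false(meaningful_change(10, 11, mdc_value = 1))   # |delta| == mdc
  expect_false(meaningful_change(10, 10, mdc_value = 0.5))
  expect_true(meaningful_change(10, 10.1, mdc_value = 0))
})

test_that("clinical table assembles change, MDC and flags per test", {
  raw <- data.frame(subject_id = c("P1", "P1"), test_name = c("squat", "thirty_ssts"),
                    pre_value = c(50, 10), post_value = c(60, 10.5))
  tab <- clinical_table(raw, semt_values = c(thirty_ssts = 0.41))
  expect_equal(tab$percent_change, c(20, 5))
  expect_true(is.na(tab$mdc[1]))           # no SEMT for the 1-RM method
  expect_equal(tab$mdc[2], 1.96 * 0.41 * sqrt(2))
  expect_false(tab$meaningful[2])          # 0.5 reps < MDC of 1.136
  tab2 <- clinical_table(raw, icc = c(thirty_ssts = 0.75),
                         sd_baseline = c(thirty_ssts = 1))
  expect_equal(tab2$semt[2], 0.5)
})

test_that("Spearman matches hand values and is monotone-transform invariant", {
  expect_equal(spearman_cor(1:3, 1:3)$rho, 1)
  expect_equal(spearman_cor(1:3, 3:1)$rho, -1)
  s <- spearman_cor(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(s$rho, 0.8)       # 1 - 6*2/(4*15)
  expect_error(spearman_cor(1:4, rep(1, 4)),
               class = "dmrescue_validation_error")

  set.seed(13)
  x <- rnorm(12); y <- rnorm(12)
  r0 <- spearman_cor(x, y)$rho
  expect_equal(spearman_cor(exp(x), y)$rho, r0)
  expect_equal(spearman_cor(x, 3 * y + 7)$rho, r0)

  # exact permutation mode: p is the tail mass of the permutation null
  set.seed(14)
  x5 <- rnorm(5); y5 <- rnorm(5)
  ex <- spearman_cor(x5, y5, exact = TRUE)
  rx <- rank(x5); ry <- rank(y5)
  perms <- dmrescue:::permutations(5)
  null_rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
  expect_equal(ex$p_value, mean(abs(null_rhos) >= abs(ex$rho) - 1e-12))
  expect_error(spearman_cor(rnorm(9), rnorm(9), exact = TRUE),
               class = "dmrescue_validation_error")
})

test_that("partial Spearman equals the recursion-formula oracle", {
  set.seed(17)
  for (i in 1:20) {
    x <- rnorm(8); y <- rnorm(8); z <- rnorm(8)
    got <- partial_spearman(x, y, z)
    rx <- rank(x); ry <- rank(y); rz <- rank(z)
    rxy <- cor(rx, ry); rxz <- cor(rx, rz); ryz <- cor(ry, rz)
    oracle <- (rxy - rxz * ryz) / sqrt((1 - rxz^2) * (1 - ryz^2))
    expect_equal(got$rho, oracle, tolerance = 1e-12)
    # rank invariance: shifting or rescaling the covariate changes nothing
    expect_equal(partial_spearman(x, y, 10 * z + 3)$rho, got$rho)
  }
  x <- rnorm(6)
  expect_equal(partial_spearman(x, x, rnorm(6))$rho, 1)
  expect_error(partial_spearman(1:5, rnorm(5), 1:5),
               class = "dmrescue_validation_error")
})

test_that("grouped descending overlap intersects until empty", {
  sets <- list(A = c("g1", "g2", "g3"), B = c("g2", "g3"), C = "g4")
  out <- grouped_descending_overlap(sets)
  expect_equal(out$steps[[1]], c("g2", "g3"))
  expect_equal(out$steps[[2]], character(0))
  expect_equal(out$terminal, c("g2", "g3"))
  expect_equal(out$depth, 2L)

  same <- grouped_descending_overlap(list(A = "g", B = "g", C = "g"))
  expect_equal(same$terminal, "g")
  expect_equal(same$depth, 3L)

  disj <- grouped_descending_overlap(list(A = "a", B = "b"))
  expect_equal(disj$terminal, "a")
  expect_equal(disj$depth, 1L)

  empty <- grouped_descending_overlap(list(A = character(0), B = "x"))
  expect_equal(empty$depth, 0L)

  # ordering by clinical improvement is applied before intersecting
  ord <- grouped_descending_overlap(sets[c("C", "A", "B")],
                                    order_by = c(C = 1, A = 9, B = 5))
  expect_equal(ord$terminal, c("g2", "g3"))

  # steps shrink monotonically
  set.seed(23)
  rnd <- setNames(lapply(1:5, function(i) sample(letters, sample(3:15, 1))),
                  paste0("S", 1:5))
  st <- grouped_descending_overlap(rnd)$steps
  for (i in seq_along(st)[-1]) {
    expect_true(all(st[[i]] %in% st[[i - 1]]))
  }
})

test_that("permuting one vector destroys a perfect rescue-clinical link", {
  x <- c(P1 = 10, P2 = 20, P3 = 35, P4 = 40, P5 = 70, P6 = 80)
  y <- x * 1.5 + 3
  r <- correlate_rescue_with_clinical(x, y, ages = c(P1 = 40, P2 = 50,
                                                     P3 = 45, P4 = 55,
                                                     P5 = 35, P6 = 60))
  expect_equal(r$spearman$rho, 1)
  expect_s3_class(r$partial_age, "correlation_result")
  set.seed(19)
  y_perm <- setNames(sample(y), names(y))
  r2 <- correlate_rescue_with_clinical(x, y_perm)
  expect_lt(abs(r2$spearman$rho), 1)
  expect_warning(correlate_rescue_with_clinical(x[1:3], y[1:3],
                                                ages = c(P1 = 1, P2 = 2,
                                                         P3 = 3)),
                 "omitted")
})
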