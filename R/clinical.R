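# Clinical change metrics (percent change, SEMT, MDC, meaningful change),
# Spearman and age-controlled partial Spearman correlation, and the
# grouped-descending rescued-gene overlap analysis.

#' Percent change of a clinical measurement
#'
#' `100 * (post - pre) / pre`.
#'
#' @param pre,post pre-/post-program values in test units (pre must be
#'   nonzero).
#' @return Percent change (vectorized).
#' @export
percent_change <- function(pre, post) {
  if (any(pre == 0)) {
    stop_dm("percent change undefined: pre-program value is 0",
            class = "dmrescue_validation_error")
  }
  100 * (post - pre) / pre
}

#' Standard error of measurement of a clinical test (SEMT)
#'
#' From the baseline standard deviation of the sample and the test-retest
#' intraclass correlation (ICC). The standard psychometric form is
#' `sd * sqrt(1 - ICC)` (the default); the linear variant `sd * (1 - ICC)`
#' is also in circulation and selectable.
#'
#' @param sd_baseline baseline SD in test units (>= 0).
#' @param icc intraclass correlation in \[0, 1\].
#' @param variant `"sqrt"` (default) or `"linear"`.
#' @return SEMT in test units.
#' @export
semt <- function(sd_baseline, icc, variant = c("sqrt", "linear")) {
  variant <- match.arg(variant)
  assert_number(sd_baseline, "sd_baseline", lower = 0, len = NULL)
  assert_number(icc, "icc", lower = 0, upper = 1, len = NULL)
  if (variant == "sqrt") sd_baseline * sqrt(1 - icc)
  else sd_baseline * (1 - icc)
}

#' Minimal detectable change (MDC)
#'
#' `MDC = 1.96 * SEMT * sqrt(2)`: the smallest change exceeding measurement
#' noise at 95% confidence for a test-retest design.
#'
#' @param semt_value SEMT in test units (>= 0).
#' @return MDC in test units.
#' @export
mdc <- function(semt_value) {
  assert_number(semt_value, "semt_value", lower = 0, len = NULL)
  1.96 * semt_value * sqrt(2)
}

#' Is an individual clinical change meaningful?
#'
#' TRUE iff the raw-unit change strictly exceeds the MDC:
#' `|post - pre| > mdc`.
#'
#' @param pre,post measurement values in test units.
#' @param mdc_value the test's MDC in the same units.
#' @return Logical (vectorized).
#' @export
meaningful_change <- function(pre, post, mdc_value) {
  abs(post - pre) > mdc_value
}

#' Default 1-RM strength test names
#' @export
ONE_RM_TESTS <- c("leg_extension", "leg_press", "hip_abduction", "squat")

#' Average percent change across the four 1-RM strength tests
#'
#' @param changes named numeric vector of per-test percent changes; all four
#'   configured tests must be present.
#' @param tests the four test names (default [ONE_RM_TESTS]).
#' @return Arithmetic mean of the four percent changes.
#' @export
average_1rm_change <- function(changes, tests = ONE_RM_TESTS) {
  missing <- setdiff(tests, names(changes))
  if (length(missing)) {
    stop_dm("missing 1-RM test(s): %s", paste(missing, collapse = ", "),
            class = "dmrescue_validation_error")
  }
  mean(changes[tests])
}

#' Build the per-subject clinical change table
#'
#' Computes percent change per test and, where a SEMT is supplied for the
#' test, the MDC and the meaningful-change flag (raw-unit change strictly
#' exceeding the MDC).
#'
#' @param clinical_raw data frame with `subject_id`, `test_name`,
#'   `pre_value`, `post_value`.
#' @param semt_values optional named numeric vector of SEMT per test name (in
#'   test units); alternatively supply `icc` and `sd_baseline`.
#' @param icc,sd_baseline optional named vectors per test name from which
#'   SEMT is computed with [semt()].
#' @param variant SEMT variant passed to [semt()].
#' @return A `data.frame` with columns `subject_id`, `test_name`, `pre`,
#'   `post`, `percent_change`, `semt`, `mdc`, `meaningful`.
#' @export
clinical_table <- function(clinical_raw, semt_values = NULL, icc = NULL,
                           sd_baseline = NULL, variant = "sqrt") {
  if (is.null(semt_values) && !is.null(icc) && !is.null(sd_baseline)) {
    tests <- intersect(names(icc), names(sd_baseline))
    semt_values <- setNames(semt(sd_baseline[tests], icc[tests],
                                 variant = variant), tests)
  }
  pc <- percent_change(clinical_raw$pre_value, clinical_raw$post_value)
  st <- if (is.null(semt_values)) rep(NA_real_, nrow(clinical_raw))
        else unname(semt_values[clinical_raw$test_name])
  md <- ifelse(is.na(st), NA_real_, mdc(ifelse(is.na(st), 0, st)))
  mf <- ifelse(is.na(md), NA,
               meaningful_change(clinical_raw$pre_value,
                                 clinical_raw$post_value, md))
  data.frame(subject_id = clinical_raw$subject_id,
             test_name = clinical_raw$test_name,
             pre = clinical_raw$pre_value, post = clinical_raw$post_value,
             percent_change = pc, semt = st, mdc = md, meaningful = mf,
             stringsAsFactors = FALSE)
}

#' Spearman rank correlation with a t-approximation p-value
#'
#' rho is Pearson correlation of average ranks; the two-sided p-value uses
#' the t approximation with n - 2 degrees of freedom. An exact full
#' permutation p-value is available for n <= 8.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param exact use full permutation enumeration for the p-value (n <= 8).
#' @return A list of class `"correlation_result"` with `rho`, `p_value`, `n`,
#'   `controlled_for` (NA here).
#' @export
spearman_cor <- function(x, y, exact = FALSE) {
  n <- length(x)
  if (length(y) != n || n < 3L) {
    stop_dm("spearman_cor needs equal-length vectors with n >= 3",
            class = "dmrescue_validation_error")
  }
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  if (sd(rx) == 0 || sd(ry) == 0) {
    stop_dm("spearman undefined: zero variance in ranks",
            class = "dmrescue_validation_error")
  }
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 8L) {
      stop_dm("exact permutation p-value supported for n <= 8 only",
              class = "dmrescue_validation_error")
    }
    perms <- permutations(n)
    rhos <- apply(perms, 1L, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else {
    t_stat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(t_stat), df = n - 2)
    p <- min(p, 1)
  }
  structure(list(rho = rho, p_value = p, n = n, controlled_for = NA_character_),
            class = "correlation_result")
}

permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' First-order partial Spearman correlation (e.g. controlling for age)
#'
#' Rank-transforms x, y and z (average ranks), regresses the x- and y-ranks
#' on the z-ranks, and correlates the residuals — numerically equivalent to
#' the first-order recursion formula
#' `(r_xy - r_xz r_yz) / sqrt((1 - r_xz^2)(1 - r_yz^2))`. The two-sided
#' p-value uses the t approximation with n - 3 degrees of freedom.
#'
#' @param x,y,z numeric vectors of equal length (n >= 4); `z` is the
#'   controlled covariate.
#' @param controlled_for label stored in the result (default `"z"`).
#' @return A `"correlation_result"` list with `rho`, `p_value`, `n`,
#'   `controlled_for`.
#' @export
partial_spearman <- function(x, y, z, controlled_for = "z") {
  n <- length(x)
  if (length(y) != n || length(z) != n || n < 4L) {
    stop_dm("partial_spearman needs equal-length vectors with n >= 4",
            class = "dmrescue_validation_error")
  }
  r <- vapply(list(x, y, z), rank, numeric(n), ties.method = "average")
  if (any(apply(r, 2L, sd) == 0)) {
    stop_dm("partial_spearman undefined: zero variance in ranks",
            class = "dmrescue_validation_error")
  }
  R <- cor(r)
  if (abs(R[1L, 3L]) >= 1 - 1e-12 || abs(R[2L, 3L]) >= 1 - 1e-12) {
    stop_dm("degenerate control: covariate is rank-identical to an input",
            class = "dmrescue_validation_error")
  }
  rz <- cbind(1, r[, 3L])
  res <- r[, 1:2] - rz %*% qr.solve(rz, r[, 1:2])
  rho <- cor(res[, 1L], res[, 2L])
  t_stat <- rho * sqrt((n - 3) / max(1 - rho^2, .Machine$double.eps))
  p <- min(2 * pt(-abs(t_stat), df = n - 3), 1)
  structure(list(rho = rho, p_value = p, n = n,
                 controlled_for = controlled_for),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  ctrl <- if (is.na(x$controlled_for)) "" else
    sprintf(" (controlling for %s)", x$controlled_for)
  cat(sprintf("Spearman rho = %.3f, p = %.4g, n = %d%s\n",
              x$rho, x$p_value, x$n, ctrl))
  invisible(x)
}

#' Cumulative rescued-gene overlap in descending clinical order
#'
#' Starting from the subject with the greatest clinical improvement,
#' intersects rescued-gene sets cumulatively down the clinical ranking
#' (top-1 n top-2, then n top-3, ...) until the running intersection is
#' empty, and reports each step, the last non-empty set and its depth. Step
#' sets are monotonically non-increasing under inclusion.
#'
#' @param rescued_sets named list of rescued gene-id sets, already ordered by
#'   descending clinical improvement (or supply `order_by`).
#' @param order_by optional named numeric vector (e.g. average 1-RM percent
#'   change) used to sort subjects in descending order first.
#' @return A list with `steps` (list of cumulative intersections, one per
#'   depth), `terminal` (last non-empty intersection), `depth` (its number
#'   of subjects).
#' @export
grouped_descending_overlap <- function(rescued_sets, order_by = NULL) {
  if (!is.null(order_by)) {
    rescued_sets <- rescued_sets[names(sort(order_by, decreasing = TRUE))]
  }
  if (length(rescued_sets) == 0L || length(rescued_sets[[1L]]) == 0L) {
    return(list(steps = list(), terminal = character(0), depth = 0L))
  }
  steps <- list()
  current <- rescued_sets[[1L]]
  terminal <- current
  depth <- 1L
  for (i in seq_along(rescued_sets)[-1L]) {
    current <- intersect(current, rescued_sets[[i]])
    steps[[length(steps) + 1L]] <- current
    if (length(current) == 0L) break
    terminal <- current
    depth <- i
  }
  list(steps = steps, terminal = terminal, depth = depth)
}

#' Correlate molecular rescue with clinical improvement
#'
#' Plain Spearman correlation between the per-subject percentage of DEGs
#' rescued and the average 1-RM percent change; when ages are given and
#' n >= 4, an age-controlled partial Spearman correlation is added (with
#' n < 4 the partial correlation is omitted with a warning).
#'
#' @param pct_rescued named numeric vector (per subject) of %DEGs rescued.
#' @param clinical_gain named numeric vector of average 1-RM percent change.
#' @param ages optional named numeric vector of subject ages.
#' @param exact passed to [spearman_cor()].
#' @return A list with `spearman` and (optionally) `partial_age`
#'   `"correlation_result"` objects, and `subjects`.
#' @export
correlate_rescue_with_clinical <- function(pct_rescued, clinical_gain,
                                           ages = NULL, exact = FALSE) {
  subjects <- intersect(names(pct_rescued), names(clinical_gain))
  keep <- subjects[!is.na(pct_rescued[subjects]) &
                   !is.na(clinical_gain[subjects])]
  x <- pct_rescued[keep]
  y <- clinical_gain[keep]
  out <- list(spearman = spearman_cor(x, y, exact = exact), subjects = keep)
  if (!is.null(ages)) {
    if (length(keep) < 4L || anyNA(ages[keep])) {
      warning("age-controlled partial correlation omitted (need n >= 4 with ages)",
              call. = FALSE)
    } else {
      out$partial_age <- tryCatch(
        partial_spearman(x, y, ages[keep], controlled_for = "age"),
        dmrescue_error = function(e) {
          warning(sprintf("age-controlled partial correlation omitted: %s",
                          conditionMessage(e)), call. = FALSE)
          NULL
        })
    }
  }
  out
}
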