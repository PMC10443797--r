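# End-to-end orchestration: contrasts -> significance -> rescue ->
# dysregulation scores -> overlaps -> clinical change -> correlations, for
# every patient individually and for the grouped (pooled pre / pooled post)
# analysis, plus report writing and a JSON-config driver.

#' Run the full individual-level rescue analysis on a cohort
#'
#' For each patient, contrasts the pre- and post-training samples against the
#' control group (genes: CPM log2 fold change; events: PSI deviation from the
#' control mean), applies the significance filters, computes percent rescue
#' and categories for the pre-significant units, per-subject splicing and
#' gene-expression dysregulation scores (pre and post over the identical unit
#' set), per-unit delta-log2FC, shared-rescue overlaps across subjects, the
#' clinical change table and the molecular-vs-clinical correlations. The same
#' contrasts are also computed grouped (all pre samples pooled vs controls,
#' all post pooled vs controls), which exposes how grouping can mask
#' individually large but discordant changes.
#'
#' @param cohort a [simulate_cohort()] result, or a list with elements
#'   `counts`, `psi` ([psi_matrix()]), `meta` ([sample_meta()]), `clinical`.
#' @param thresholds a [threshold_preset()].
#' @param significance `"welch_bh"` (default; Welch/z surrogate with BH FDR)
#'   or `"external"` (per-contrast tables supplied in
#'   `external_tables`) or `"effect_only"` (units selected by effect-size
#'   threshold alone; for noise-free synthetic checks where the control
#'   group has zero variance and no dispersion-based test is defined).
#' @param include_overrescued count overrescued genes as rescued in the
#'   %DEGs-rescued metric (default FALSE; categories are reported
#'   separately).
#' @param splice_include_overrescued pool rescued and overrescued events for
#'   the splicing-vs-clinical correlation (default TRUE, mirroring the
#'   source analysis).
#' @param panel optional character vector of curated panel event ids for
#'   [panel_classify()].
#' @param semt_values named SEMT per clinical test (test units) used for MDC
#'   and meaningful-change flags; defaults to the literature values for
#'   knee-extensor strength (3.77 Nm) and the 30-second sit-to-stand (0.41
#'   repetitions). No SEMT exists for the 1-RM method.
#' @param external_tables for `significance = "external"`: a list per subject
#'   id (plus `"grouped"`), each with [contrast_table()]s `pre` and `post`
#'   carrying effects, p and FDR.
#' @param pseudocount CPM pseudocount for [estimate_log2fc()].
#' @param eps denominator guard for [percent_rescue()].
#' @return A list of class `"dm_analysis"`; see the package vignette for the
#'   component tables.
#' @export
analyze_cohort <- function(cohort,
                           thresholds = threshold_preset("strength"),
                           significance = c("welch_bh", "external",
                                            "effect_only"),
                           include_overrescued = FALSE,
                           splice_include_overrescued = TRUE,
                           panel = NULL,
                           semt_values = c(knee_extensors = 3.77,
                                           thirty_ssts = 0.41),
                           external_tables = NULL,
                           pseudocount = 0.5, eps = 1e-12) {
  significance <- match.arg(significance)
  th <- thresholds
  meta <- cohort$meta
  ctrl <- meta$sample_id[meta$group == "control"]
  pat_pre <- meta[meta$group == "patient" & meta$timepoint == "pre", ]
  pat_post <- meta[meta$group == "patient" & meta$timepoint == "post", ]
  subjects <- pat_pre$subject_id
  post_of <- setNames(pat_post$sample_id, pat_post$subject_id)
  pre_of <- setNames(pat_pre$sample_id, pat_pre$subject_id)
  subjects <- subjects[subjects %in% names(post_of)]
  if (length(ctrl) < 2L || length(subjects) == 0L) {
    stop_dm("analysis needs >= 2 control samples and >= 1 patient with pre and post samples",
            class = "dmrescue_validation_error")
  }
  log <- list(untestable_genes = 0L, untestable_events = 0L,
              undefined_rescue = 0L, no_reads_events = 0L)

  ## ---- genes -------------------------------------------------------------
  counts <- filter_low_counts(cohort$counts, th$min_gene_count)
  logcpm <- log2(cpm_matrix(counts) + 0.5)

  gene_sig <- function(tbl, values_a, subj) {
    if (significance == "effect_only") {
      tbl$unit_id[abs(tbl$effect) > th$lfc_min]
    } else if (significance == "external") {
      filter_significant(external_tables[[subj]]$pre, th, "gene")
    } else {
      tbl2 <- suppressWarnings(
        attach_significance(tbl, values_a, logcpm[, ctrl, drop = FALSE],
                            method = "welch_bh"))
      log$untestable_genes <<- log$untestable_genes +
        (attr(tbl2, "n_untestable") %||% 0L)
      filter_significant(tbl2, th, "gene")
    }
  }

  gene_records <- list(); gene_scores <- list(); deltas <- list()
  pct_deg_rescued <- setNames(rep(NA_real_, length(subjects)), subjects)
  rescued_gene_sets <- list()
  for (sj in subjects) {
    pre_tbl <- estimate_log2fc(counts, pre_of[sj], ctrl,
                               pseudocount = pseudocount,
                               contrast_label = paste0(sj, ":pre_vs_control"))
    post_tbl <- estimate_log2fc(counts, post_of[sj], ctrl,
                                pseudocount = pseudocount,
                                contrast_label = paste0(sj, ":post_vs_control"))
    sig <- gene_sig(pre_tbl, logcpm[, pre_of[sj], drop = FALSE], sj)
    rec <- rescue_records(pre_tbl, post_tbl, sig, sj, "gene", eps = eps)
    log$undefined_rescue <- log$undefined_rescue + sum(!rec$defined)
    gene_records[[sj]] <- rec
    if (nrow(rec) > 0L && any(rec$defined)) {
      pct_deg_rescued[sj] <- suppressWarnings(
        percent_units_rescued(rec, include_overrescued))
    }
    rescued_gene_sets[[sj]] <- rec$unit_id[rec$defined &
                                             rec$category == "rescued"]
    eff_pre <- setNames(pre_tbl$effect, pre_tbl$unit_id)[sig]
    eff_post <- setNames(post_tbl$effect, post_tbl$unit_id)[sig]
    gene_scores[[sj]] <- data.frame(
      subject_id = sj, modality = "gene",
      pre_score = if (length(sig)) dysregulation_score(eff_pre) else NA_real_,
      post_score = if (length(sig)) dysregulation_score(eff_post) else NA_real_,
      n_significant = length(sig), stringsAsFactors = FALSE)
    deltas[[sj]] <- delta_log2fc(pre_tbl, post_tbl, subject_id = sj)
  }

  # grouped gene contrast (all pre pooled, all post pooled)
  grp_pre <- estimate_log2fc(counts, pre_of[subjects], ctrl,
                             pseudocount = pseudocount,
                             contrast_label = "grouped:pre_vs_control")
  grp_post <- estimate_log2fc(counts, post_of[subjects], ctrl,
                              pseudocount = pseudocount,
                              contrast_label = "grouped:post_vs_control")
  grp_sig <- gene_sig(grp_pre, logcpm[, pre_of[subjects], drop = FALSE],
                      "grouped")
  grp_eff_pre <- setNames(grp_pre$effect, grp_pre$unit_id)[grp_sig]
  grp_eff_post <- setNames(grp_post$effect, grp_post$unit_id)[grp_sig]
  gene_scores[["grouped"]] <- data.frame(
    subject_id = "grouped", modality = "gene",
    pre_score = if (length(grp_sig)) dysregulation_score(grp_eff_pre) else NA_real_,
    post_score = if (length(grp_sig)) dysregulation_score(grp_eff_post) else NA_real_,
    n_significant = length(grp_sig), stringsAsFactors = FALSE)
  deltas[["grouped"]] <- delta_log2fc(grp_pre, grp_post,
                                      subject_id = "grouped")

  ## ---- skipped-exon events ----------------------------------------------
  pm <- mask_low_support(cohort$psi, th$min_event_reads)
  psi <- pm$psi
  ctrl_psi <- psi[, ctrl, drop = FALSE]
  ctrl_n <- rowSums(!is.na(ctrl_psi))
  ctrl_mean <- rowMeans(ctrl_psi, na.rm = TRUE)
  ctrl_mean[ctrl_n < 2L] <- NA_real_

  event_sig <- function(tbl, values_a, subj) {
    if (significance == "effect_only") {
      tbl$unit_id[abs(tbl$effect) > th$dpsi_min]
    } else if (significance == "external") {
      filter_significant(external_tables[[subj]]$pre_events, th, "event")
    } else {
      tbl2 <- suppressWarnings(
        attach_significance(tbl, values_a, ctrl_psi, method = "welch_bh"))
      log$untestable_events <<- log$untestable_events +
        (attr(tbl2, "n_untestable") %||% 0L)
      filter_significant(tbl2, th, "event")
    }
  }

  event_records <- list(); event_scores <- list()
  rescued_event_sets <- list(); splice_rescued_pct <- pct_deg_rescued
  panel_states <- list()
  for (sj in subjects) {
    pre_v <- psi[, pre_of[sj]]
    post_v <- psi[, post_of[sj]]
    eff_pre <- pre_v - ctrl_mean
    eff_post <- post_v - ctrl_mean
    no_reads <- rownames(psi)[is.na(pre_v) | is.na(post_v)]
    log$no_reads_events <- log$no_reads_events + length(no_reads)
    def_pre <- !is.na(eff_pre)
    pre_tbl <- contrast_table(rownames(psi)[def_pre], eff_pre[def_pre],
                              contrast_label = paste0(sj, ":pre_vs_control"))
    def_post <- !is.na(eff_post)
    post_tbl <- contrast_table(rownames(psi)[def_post], eff_post[def_post],
                               contrast_label = paste0(sj, ":post_vs_control"))
    sig <- event_sig(pre_tbl, psi[def_pre, pre_of[sj], drop = FALSE], sj)
    rec <- rescue_records(pre_tbl, post_tbl, sig, sj, "event", eps = eps)
    log$undefined_rescue <- log$undefined_rescue + sum(!rec$defined)
    event_records[[sj]] <- rec
    splice_rescued_pct[sj] <- if (nrow(rec) > 0L && any(rec$defined)) {
      suppressWarnings(percent_units_rescued(rec, splice_include_overrescued))
    } else NA_real_
    rescued_event_sets[[sj]] <- rec$unit_id[rec$defined &
                                              rec$category == "rescued"]
    sig_scored <- intersect(sig, pre_tbl$unit_id)
    ev_pre <- setNames(pre_tbl$effect, pre_tbl$unit_id)[sig_scored]
    ev_post_all <- setNames(post_tbl$effect, post_tbl$unit_id)
    ev_post <- ev_post_all[intersect(sig_scored, names(ev_post_all))]
    event_scores[[sj]] <- data.frame(
      subject_id = sj, modality = "event",
      pre_score = if (length(ev_pre)) dysregulation_score(ev_pre) else NA_real_,
      post_score = if (length(ev_post)) dysregulation_score(ev_post) else NA_real_,
      n_significant = length(sig), stringsAsFactors = FALSE)
    if (!is.null(panel)) {
      ps <- suppressWarnings(
        panel_classify(panel, rec, sig, no_reads_ids = no_reads,
                       universe = rownames(psi)))
      ps$subject_id <- sj
      panel_states[[sj]] <- ps
    }
  }

  # grouped splicing contrast: mean pre / mean post PSI vs control mean
  pre_mat <- psi[, pre_of[subjects], drop = FALSE]
  post_mat <- psi[, post_of[subjects], drop = FALSE]
  grp_eff_pre_e <- rowMeans(pre_mat, na.rm = TRUE) - ctrl_mean
  grp_eff_post_e <- rowMeans(post_mat, na.rm = TRUE) - ctrl_mean
  def <- !is.na(grp_eff_pre_e) & !is.na(grp_eff_post_e)
  grp_pre_tbl <- contrast_table(rownames(psi)[def], grp_eff_pre_e[def],
                                contrast_label = "grouped:pre_vs_control")
  grp_sig_e <- event_sig(grp_pre_tbl, pre_mat[def, , drop = FALSE], "grouped")
  event_scores[["grouped"]] <- data.frame(
    subject_id = "grouped", modality = "event",
    pre_score = if (length(grp_sig_e))
      dysregulation_score(grp_eff_pre_e[grp_sig_e]) else NA_real_,
    post_score = if (length(grp_sig_e))
      dysregulation_score(grp_eff_post_e[grp_sig_e]) else NA_real_,
    n_significant = length(grp_sig_e), stringsAsFactors = FALSE)

  overlaps <- if (length(subjects) >= 2L) {
    shared_rescue_overlaps(rescued_event_sets)
  } else NULL

  ## ---- clinical & correlations ------------------------------------------
  clin <- clinical_table(cohort$clinical, semt_values = semt_values)
  gains <- setNames(rep(NA_real_, length(subjects)), subjects)
  for (sj in subjects) {
    rows <- clin[clin$subject_id == sj, ]
    ch <- setNames(rows$percent_change, rows$test_name)
    if (all(ONE_RM_TESTS %in% names(ch))) {
      gains[sj] <- average_1rm_change(ch)
    }
  }
  ages <- setNames(pat_pre$age, pat_pre$subject_id)[subjects]
  correlations <- list()
  try_corr <- function(x) {
    if (sum(!is.na(x) & !is.na(gains)) < 3L) return(NULL)
    tryCatch(
      suppressWarnings(correlate_rescue_with_clinical(
        x, gains, ages = if (!anyNA(ages)) ages)),
      dmrescue_error = function(e) {
        warning(sprintf("correlation omitted: %s", conditionMessage(e)),
                call. = FALSE)
        NULL
      })
  }
  correlations$expression <- try_corr(pct_deg_rescued)
  correlations$splicing <- try_corr(splice_rescued_pct)
  descending <- if (all(!is.na(gains))) {
    grouped_descending_overlap(rescued_gene_sets, order_by = gains)
  } else NULL

  structure(list(
    subjects = subjects,
    thresholds = th,
    significance = significance,
    rescue_records = do.call(rbind, c(gene_records, event_records,
                                      make.row.names = FALSE)),
    scores = do.call(rbind, c(gene_scores, event_scores,
                              make.row.names = FALSE)),
    pct_deg_rescued = pct_deg_rescued,
    pct_events_rescued = splice_rescued_pct,
    rescued_gene_sets = rescued_gene_sets,
    rescued_event_sets = rescued_event_sets,
    overlaps = overlaps,
    panel = if (length(panel_states))
      do.call(rbind, c(panel_states, make.row.names = FALSE)) else NULL,
    delta_lfc = do.call(rbind, c(deltas, make.row.names = FALSE)),
    clinical = clin,
    clinical_gain = gains,
    ages = ages,
    correlations = correlations,
    descending_overlap = descending,
    log = log
  ), class = "dm_analysis")
}

#' @export
print.dm_analysis <- function(x, ...) {
  cat(sprintf("Individual rescue analysis: %d patients, preset '%s' (%s significance)\n",
              length(x$subjects), x$thresholds$preset, x$significance))
  sc <- x$scores
  for (mod in c("event", "gene")) {
    s <- sc[sc$modality == mod & sc$subject_id != "grouped", ]
    if (nrow(s) && any(!is.na(s$pre_score))) {
      cat(sprintf("  %s dysregulation score: pre %.3f -> post %.3f (cohort mean)\n",
                  if (mod == "event") "splicing" else "expression",
                  mean(s$pre_score, na.rm = TRUE),
                  mean(s$post_score, na.rm = TRUE)))
    }
  }
  if (any(!is.na(x$pct_deg_rescued))) {
    cat(sprintf("  %%DEGs rescued: %s\n",
                paste(sprintf("%s=%.0f%%", names(x$pct_deg_rescued),
                              x$pct_deg_rescued), collapse = " ")))
  }
  if (!is.null(x$correlations$expression)) {
    r <- x$correlations$expression$spearman
    cat(sprintf("  rescue vs 1-RM gain: rho = %.3f (p = %.3g, n = %d)\n",
                r$rho, r$p_value, r$n))
  }
  invisible(x)
}

#' Collect an analysis into report tables
#'
#' @param analysis a [analyze_cohort()] result.
#' @return Named list of data frames suitable for [write_report()].
#' @export
analysis_tables <- function(analysis) {
  tabs <- list(
    rescue_records = analysis$rescue_records,
    dysregulation_scores = analysis$scores,
    pct_rescued = data.frame(
      subject_id = names(analysis$pct_deg_rescued),
      pct_deg_rescued = unname(analysis$pct_deg_rescued),
      pct_events_rescued = unname(analysis$pct_events_rescued),
      clinical_gain = unname(analysis$clinical_gain),
      stringsAsFactors = FALSE),
    delta_lfc = analysis$delta_lfc,
    clinical = analysis$clinical
  )
  if (!is.null(analysis$overlaps)) {
    tabs$overlap_combos <- analysis$overlaps$combos
    tabs$overlap_per_subject <- analysis$overlaps$per_subject
  }
  if (!is.null(analysis$panel)) tabs$panel <- analysis$panel
  if (length(analysis$correlations)) {
    rows <- list()
    for (nm in names(analysis$correlations)) {
      cs <- analysis$correlations[[nm]]
      rows[[paste0(nm, "_spearman")]] <- data.frame(
        metric = nm, type = "spearman", rho = cs$spearman$rho,
        p_value = cs$spearman$p_value, n = cs$spearman$n,
        controlled_for = NA_character_, stringsAsFactors = FALSE)
      if (!is.null(cs$partial_age)) {
        rows[[paste0(nm, "_partial")]] <- data.frame(
          metric = nm, type = "partial_spearman", rho = cs$partial_age$rho,
          p_value = cs$partial_age$p_value, n = cs$partial_age$n,
          controlled_for = "age", stringsAsFactors = FALSE)
      }
    }
    tabs$correlations <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  tabs
}

#' Run the pipeline from a configuration
#'
#' The config is a named list (or path to a JSON file) with keys:
#' `seed`, `out_dir`, `preset` (`"strength"`/`"cycling"`/`"custom"`),
#' `thresholds` (overrides for the preset), `sim` (parameters passed to
#' [sim_params()]) *or* `input_dir` (a directory written by
#' [write_cohort()]), `include_overrescued`, `panel` (path to a one-id-per-
#' line panel file). Unknown keys are rejected. Rerunning with the same
#' config and seed reproduces identical numeric tables.
#'
#' @param config named list or path to a JSON config file.
#' @return A list with `analysis`, `cohort` and the report `manifest`
#'   (invisible NULL manifest when `out_dir` is not set).
#' @export
run_pipeline <- function(config = list()) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("seed", "out_dir", "preset", "thresholds", "sim", "input_dir",
             "include_overrescued", "panel")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    stop_dm("unknown config key(s): %s", paste(unknown, collapse = ", "),
            class = "dmrescue_validation_error")
  }
  seed <- as.integer(config$seed %||% 1L)
  th <- do.call(threshold_preset,
                c(list(preset = config$preset %||% "strength"),
                  config$thresholds %||% list()))
  cohort <- if (!is.null(config$input_dir)) {
    read_cohort(config$input_dir)
  } else {
    sim <- config$sim %||% list()
    sim$seed <- sim$seed %||% seed
    simulate_cohort(do.call(sim_params, sim))
  }
  panel <- if (!is.null(config$panel)) readLines(config$panel)
  analysis <- analyze_cohort(
    cohort, thresholds = th,
    include_overrescued = isTRUE(config$include_overrescued),
    panel = panel)
  manifest <- NULL
  if (!is.null(config$out_dir)) {
    manifest <- write_report(analysis_tables(analysis), config$out_dir,
                             config = config, seed = seed,
                             exclusions = analysis$log)
  }
  list(analysis = analysis, cohort = cohort, manifest = manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir directory containing `counts.tsv`, `psi.tsv`, `support.tsv`,
#'   `samples.tsv`, `clinical.tsv`.
#' @return A list usable by [analyze_cohort()] (without ground truth).
#' @export
read_cohort <- function(dir) {
  list(
    counts = read_count_matrix(file.path(dir, "counts.tsv")),
    psi = read_psi_matrix(file.path(dir, "psi.tsv"),
                          support_path = file.path(dir, "support.tsv")),
    meta = read_sample_meta(file.path(dir, "samples.tsv")),
    clinical = {
      cl <- read.delim(file.path(dir, "clinical.tsv"),
                       stringsAsFactors = FALSE)
      cl
    }
  )
}
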