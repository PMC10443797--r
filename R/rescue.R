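# Percent rescue, rescue categories, dysregulation scores, shared-rescue
# overlaps (upset semantics) and the curated splicing-event panel view.

#' Percent rescue of a unit's pre-training deviation from controls
#'
#' `100 * (pre - post) / (pre - control_ref)`: the fraction of the
#' pre-training deviation from the control reference that was reversed after
#' training, as a percentage. For splicing the three arguments are PSI values
#' (control_ref = average control PSI); for gene expression they are log2
#' fold changes versus controls, so `control_ref = 0` and the numerator
#' equals the pre-vs-post log2FC. 100 means the unit returned exactly to
#' control levels; > 100 overshoots; < 0 moved away from controls.
#'
#' Units whose denominator `|pre - control_ref|` is below `eps` have no
#' defined rescue: the value is NA and callers count the exclusion.
#'
#' @param pre_value,post_value pre-/post-training values (vectorized).
#' @param control_ref control reference (default 0, the log2FC convention).
#' @param eps denominator guard (default 1e-12).
#' @return Numeric percent rescue (NA where undefined).
#' @export
percent_rescue <- function(pre_value, post_value, control_ref = 0,
                           eps = 1e-12) {
  denom <- pre_value - control_ref
  out <- 100 * (pre_value - post_value) / denom
  out[abs(denom) < eps] <- NA_real_
  out
}

#' Classify a percent-rescue value
#'
#' Partition of the real line: rescued for values in (10, 110), overrescued
#' for >= 110, misrescued for < -10, and unchanged for \[-10, 10\]. The
#' "unchanged" band is unnamed in the source analyses, which count only the
#' three named categories; boundary handling follows the printed
#' inequalities (110 is overrescued; 10 and -10 are unchanged).
#'
#' @param percent finite numeric percent-rescue values (vectorized).
#' @return Factor with levels `rescued`, `overrescued`, `misrescued`,
#'   `unchanged`.
#' @export
classify_rescue <- function(percent) {
  if (any(!is.finite(percent))) {
    stop_dm("classify_rescue: non-finite percent-rescue value",
            class = "dmrescue_validation_error")
  }
  out <- rep("unchanged", length(percent))
  out[percent > 10 & percent < 110] <- "rescued"
  out[percent >= 110] <- "overrescued"
  out[percent < -10] <- "misrescued"
  factor(out, levels = c("rescued", "overrescued", "misrescued", "unchanged"))
}

#' Build per-subject rescue records from pre/post contrast effects
#'
#' Takes the pre-vs-control and post-vs-control effects (log2FC or
#' PSI-vs-control deviation — both are deviations whose control reference is
#' 0 on the effect scale), restricts to the units significant pre-training,
#' and computes percent rescue and category per unit. Units failing the
#' denominator guard are kept with NA percent/category and flagged
#' `defined = FALSE` so callers can reconcile counts.
#'
#' @param pre_vs_ctrl,post_vs_ctrl [contrast_table()]s on the effect scale.
#' @param significant_ids unit ids significant in the pre-vs-control
#'   comparison (percent rescue is only defined for these).
#' @param subject_id subject the records belong to.
#' @param modality `"gene"` or `"event"`.
#' @param eps denominator guard passed to [percent_rescue()].
#' @return A `data.frame` with columns `unit_id`, `subject_id`, `modality`,
#'   `pre_effect`, `post_effect`, `percent_rescue`, `category`, `defined`.
#' @export
rescue_records <- function(pre_vs_ctrl, post_vs_ctrl, significant_ids,
                           subject_id, modality = c("gene", "event"),
                           eps = 1e-12) {
  modality <- match.arg(modality)
  ids <- intersect(significant_ids, intersect(pre_vs_ctrl$unit_id,
                                              post_vs_ctrl$unit_id))
  pre <- setNames(pre_vs_ctrl$effect, pre_vs_ctrl$unit_id)[ids]
  post <- setNames(post_vs_ctrl$effect, post_vs_ctrl$unit_id)[ids]
  pr <- percent_rescue(pre, post, control_ref = 0, eps = eps)
  defined <- !is.na(pr)
  category <- factor(rep(NA_character_, length(ids)),
                     levels = levels(classify_rescue(0)))
  category[defined] <- classify_rescue(pr[defined])
  data.frame(unit_id = ids, subject_id = rep_len(subject_id, length(ids)),
             modality = rep_len(modality, length(ids)),
             pre_effect = unname(pre), post_effect = unname(post),
             percent_rescue = unname(pr), category = category,
             defined = defined, row.names = NULL, stringsAsFactors = FALSE)
}

#' Dysregulation score: mean absolute deviation from controls
#'
#' The pre-training score is the average absolute deviation (|dPSI| for
#' splicing, |log2FC| for expression) over the units significant
#' pre-training; the post-training score averages the post-vs-control
#' deviations over that *same* unit set.
#'
#' @param devs numeric deviations over the pre-significant unit set
#'   (non-empty).
#' @return Mean of absolute deviations.
#' @export
dysregulation_score <- function(devs) {
  devs <- devs[!is.na(devs)]
  if (length(devs) == 0L) {
    stop_dm("dysregulation score undefined: empty deviation set",
            class = "dmrescue_validation_error")
  }
  mean(abs(devs))
}

#' Percentage of units rescued for one subject
#'
#' `100 * #rescued / #defined`, where the denominator counts records with a
#' defined percent rescue (denominator-guard failures are excluded from both
#' numerator and denominator). Overrescued units are *not* counted as rescued
#' by default — the source analyses report the categories separately — but
#' `include_overrescued = TRUE` pools them, as done for the
#' splicing-vs-clinical correlation.
#'
#' @param records a [rescue_records()] data frame for one subject and
#'   modality.
#' @param include_overrescued count overrescued units in the numerator.
#' @return Percentage, or NA (with a warning) when no record has a defined
#'   percent rescue.
#' @export
percent_units_rescued <- function(records, include_overrescued = FALSE) {
  defined <- records[records$defined & !is.na(records$category), ,
                     drop = FALSE]
  if (nrow(defined) == 0L) {
    warning("percent_units_rescued: no defined rescue records", call. = FALSE)
    return(NA_real_)
  }
  hit <- defined$category == "rescued"
  if (include_overrescued) hit <- hit | defined$category == "overrescued"
  100 * sum(hit) / nrow(defined)
}

#' Exact set-intersection counts of rescued events across subjects
#'
#' Upset semantics: for every subject combination that actually occurs, the
#' number of events rescued in exactly that subset of subjects; per-k totals
#' (events rescued in exactly k subjects); and per-subject unique counts.
#' Conservation holds by construction: summing the exact counts of the combos
#' containing a subject recovers that subject's rescued-set size.
#'
#' @param rescued_sets named list (>= 2 subjects) of character vectors of
#'   rescued event ids.
#' @return A list with `combos` (`combo`, `k`, `exact_count`; combo members
#'   joined by `"+"` in input order), `per_k` (`k`, `n_events`), and
#'   `per_subject` (`subject_id`, `n_rescued`, `n_unique`, `pct_unique`).
#' @export
shared_rescue_overlaps <- function(rescued_sets) {
  if (length(rescued_sets) < 2L || is.null(names(rescued_sets))) {
    stop_dm("shared_rescue_overlaps needs a named list of >= 2 subjects",
            class = "dmrescue_validation_error")
  }
  subjects <- names(rescued_sets)
  events <- unique(unlist(rescued_sets, use.names = FALSE))
  if (length(events) == 0L) {
    return(list(
      combos = data.frame(combo = character(0), k = integer(0),
                          exact_count = integer(0)),
      per_k = data.frame(k = integer(0), n_events = integer(0)),
      per_subject = data.frame(subject_id = subjects,
                               n_rescued = 0L, n_unique = 0L,
                               pct_unique = NA_real_)
    ))
  }
  membership <- vapply(rescued_sets, function(s) events %in% s,
                       logical(length(events)))
  membership <- matrix(membership, nrow = length(events),
                       dimnames = list(events, subjects))
  signature <- apply(membership, 1L, function(m) {
    paste(subjects[m], collapse = "+")
  })
  counts <- table(signature)
  k <- rowSums(membership)
  combos <- data.frame(combo = names(counts),
                       k = vapply(strsplit(names(counts), "+", fixed = TRUE),
                                  length, integer(1L)),
                       exact_count = as.integer(counts),
                       stringsAsFactors = FALSE)
  combos <- combos[order(combos$k, combos$combo), , drop = FALSE]
  rownames(combos) <- NULL
  per_k <- aggregate(exact_count ~ k, combos, sum)
  names(per_k) <- c("k", "n_events")
  n_rescued <- colSums(membership)
  n_unique <- colSums(membership & k == 1L)
  per_subject <- data.frame(subject_id = subjects,
                            n_rescued = as.integer(n_rescued),
                            n_unique = as.integer(n_unique),
                            pct_unique = ifelse(n_rescued > 0,
                                                100 * n_unique / n_rescued,
                                                NA_real_),
                            stringsAsFactors = FALSE, row.names = NULL)
  list(combos = combos, per_k = per_k, per_subject = per_subject)
}

#' Classify a curated splicing-event panel per subject
#'
#' For a user-supplied panel of informative skipped-exon events (e.g. the
#' published 46-event set predictive of inferred MBNL activity), reports per
#' subject and per event one of: `no_reads` (the event is absent from the PSI
#' universe, or its pre or post sample lacked read support), `not_significant`
#' (not significantly misspliced pre-training, so no percent rescue is
#' computed), `rescued` (category rescued or overrescued, i.e. partially or
#' fully rescued), or `not_rescued`.
#'
#' @param panel character vector of panel event ids.
#' @param records a [rescue_records()] data frame for one subject (event
#'   modality).
#' @param significant_ids event ids significant pre-training for the subject.
#' @param no_reads_ids event ids lacking read support in the subject's pre or
#'   post sample.
#' @param universe all event ids quantified in the dataset; panel events
#'   outside it are reported `no_reads` with a warning.
#' @return A `data.frame` with columns `event_id`, `state`.
#' @export
panel_classify <- function(panel, records, significant_ids,
                           no_reads_ids = character(0), universe = NULL) {
  panel <- as.character(panel)
  state <- rep("not_significant", length(panel))
  if (!is.null(universe)) {
    absent <- !(panel %in% universe)
    if (any(absent)) {
      warning(sprintf("panel_classify: %d panel event(s) absent from the PSI universe",
                      sum(absent)), call. = FALSE)
      state[absent] <- "no_reads"
    }
  }
  state[panel %in% no_reads_ids] <- "no_reads"
  sig <- panel %in% significant_ids & state == "not_significant"
  cat_by_id <- setNames(as.character(records$category), records$unit_id)
  for (i in which(sig)) {
    cat_i <- cat_by_id[panel[i]]
    state[i] <- if (is.na(cat_i)) {
      "no_reads"
    } else if (cat_i %in% c("rescued", "overrescued")) {
      "rescued"
    } else {
      "not_rescued"
    }
  }
  data.frame(event_id = panel, state = state, stringsAsFactors = FALSE)
}
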