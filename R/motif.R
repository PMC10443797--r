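# YGCY (MBNL-binding) motif analysis: strand-aware extraction of the
# regulated exon and its 250-bp flanks, overlapping-window motif counting,
# composition-matched background selection and log2 density enrichment
# stratified by splicing direction. MBNL regulates cassette exons
# position-dependently, so aberrantly *included* exons are expected to carry
# excess YGCY upstream of / within the exon and aberrantly *excluded* exons
# downstream.

YGCY_MOTIFS <- c("TGCT", "TGCC", "CGCT", "CGCC")

#' Count YGCY motif occurrences in a sequence
#'
#' Number of length-4 windows matching YGCY (Y = C or T): TGCT, TGCC, CGCT,
#' CGCC. Overlapping windows are all counted (sliding window); windows
#' containing N never match. Sequences shorter than 4 nt count 0.
#'
#' @param seq a character vector, [Biostrings::DNAString] or
#'   [Biostrings::DNAStringSet].
#' @return Integer count (vector for multiple sequences).
#' @export
count_ygcy <- function(seq) {
  if (is.character(seq)) seq <- Biostrings::DNAStringSet(toupper(seq))
  if (methods::is(seq, "DNAString")) {
    return(Biostrings::countPattern("YGCY", seq, fixed = "subject"))
  }
  # fixed = "subject": ambiguity codes are interpreted in the pattern only,
  # so an N in the subject never matches.
  Biostrings::vcountPattern("YGCY", seq, fixed = "subject")
}

#' Extract exon and flank sequences, transcript-oriented
#'
#' For each annotated event, returns the exon sequence plus `flank` nt
#' upstream and downstream, oriented transcript-relatively: "upstream" is 5'
#' of the exon on the coding strand. On the minus strand the genomic
#' sequences are reverse-complemented and the two flanks swap roles. A flank
#' running off the contig end is truncated and flagged; an exon off the
#' contig is an error.
#'
#' @param events an [event_annotation()] data frame (0-based half-open
#'   coordinates).
#' @param genome named [Biostrings::DNAStringSet] of contigs (names matching
#'   `events$chrom`).
#' @param flank flank length in nt (default 250).
#' @param direction optional per-event direction (`"inclusion"`,
#'   `"exclusion"`, `"background"`) stored in the result.
#' @return A `data.frame` of class `"region_seqs"` with columns `event_id`,
#'   `direction`, `upstream`, `exon`, `downstream` (character sequences) and
#'   `truncated` (logical).
#' @export
extract_regions <- function(events, genome, flank = 250,
                            direction = NULL) {
  assert_number(flank, "flank", lower = 0)
  miss <- setdiff(unique(events$chrom), names(genome))
  if (length(miss)) {
    stop_dm("contig '%s' not present in the genome", miss[1L],
            class = "dmrescue_validation_error")
  }
  n <- nrow(events)
  direction <- direction %||% rep("background", n)
  up <- ex <- dn <- character(n)
  trunc <- logical(n)
  for (i in seq_len(n)) {
    contig <- genome[[events$chrom[i]]]
    len <- length(contig)
    s <- events$exon_start[i]
    e <- events$exon_end[i]
    if (s < 0L || e > len) {
      stop_dm("exon of event '%s' lies outside contig '%s'",
              events$event_id[i], events$chrom[i],
              class = "dmrescue_validation_error")
    }
    left_s <- max(0L, s - flank)
    right_e <- min(len, e + flank)
    trunc[i] <- (s - flank < 0L) || (e + flank > len)
    # 0-based half-open -> subseq's 1-based inclusive
    left <- as.character(Biostrings::subseq(contig, left_s + 1L, s))
    mid <- as.character(Biostrings::subseq(contig, s + 1L, e))
    right <- as.character(Biostrings::subseq(contig, e + 1L, right_e))
    if (events$strand[i] == "+") {
      up[i] <- left; ex[i] <- mid; dn[i] <- right
    } else {
      rc <- function(x) as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
      up[i] <- rc(right); ex[i] <- rc(mid); dn[i] <- rc(left)
    }
  }
  out <- data.frame(event_id = events$event_id, direction = direction,
                    upstream = up, exon = ex, downstream = dn,
                    truncated = trunc, stringsAsFactors = FALSE)
  class(out) <- c("region_seqs", "data.frame")
  out
}

region_composition <- function(regions) {
  concat <- paste0(regions$upstream, regions$exon, regions$downstream)
  freq <- Biostrings::alphabetFrequency(Biostrings::DNAStringSet(concat),
                                        baseOnly = TRUE, as.prob = TRUE)
  freq[, c("A", "C", "G", "T"), drop = FALSE]
}

#' Select composition-matched background events
#'
#' For each foreground (misregulated) event, picks the `k` pool events
#' nearest in Euclidean distance between mononucleotide frequency vectors of
#' the concatenated upstream+exon+downstream sequences. Ties are broken by a
#' seeded shuffle of the pool, then stable event-id order, so selection is
#' deterministic given the seed. Selection is with replacement across
#' foreground events but without replacement within one foreground event's
#' background set.
#'
#' @param fg foreground [extract_regions()] data frame.
#' @param pool background pool (events detected but not misregulated in the
#'   same dataset), same format; must have >= k rows.
#' @param k background events per foreground event (default 5).
#' @param seed integer seed for tie-breaking.
#' @return Named list mapping each foreground event id to its k background
#'   event ids.
#' @export
match_background <- function(fg, pool, k = 5, seed = 1L) {
  k <- assert_count(k, "k")
  if (nrow(pool) < k) {
    stop_dm("background pool (%d) smaller than k = %d", nrow(pool), k,
            class = "dmrescue_validation_error")
  }
  fg_comp <- region_composition(fg)
  pool_comp <- region_composition(pool)
  shuffle <- with_seed(seed, sample.int(nrow(pool)))
  ord_id <- order(pool$event_id)
  sets <- vector("list", nrow(fg))
  names(sets) <- fg$event_id
  for (i in seq_len(nrow(fg))) {
    d <- sqrt(colSums((t(pool_comp) - fg_comp[i, ])^2))
    idx <- order(d, shuffle, ord_id)[seq_len(k)]
    sets[[i]] <- pool$event_id[idx]
  }
  sets
}

#' YGCY density enrichment of foreground events over matched backgrounds
#'
#' Foreground events are stratified by splicing direction (inclusion:
#' significant positive dPSI; exclusion: negative). Per region (upstream,
#' exon, downstream) and direction, the foreground motif density (total YGCY
#' count / total nt across events) is compared with the density across the
#' union of the matched background events, as
#' `log2((fg_density + eps) / (bg_density + eps))` with a pseudo-density
#' guard `eps` (default 0.5 motifs/kb). Densities are per-nucleotide and
#' aggregated across events before the ratio, so variable exon lengths do not
#' confound raw counts; the enrichment is invariant to duplicating every
#' sequence.
#'
#' @param fg foreground [extract_regions()] data frame with `direction` set
#'   to `"inclusion"` / `"exclusion"`.
#' @param bg_sets matched backgrounds from [match_background()].
#' @param pool the pool [extract_regions()] data frame the ids in `bg_sets`
#'   refer to.
#' @param epsilon pseudo-density in motifs per nt (default 5e-4 = 0.5/kb).
#' @return A `data.frame` with columns `direction`, `region`, `fg_count`,
#'   `fg_nt`, `fg_density`, `bg_count`, `bg_nt`, `bg_density`,
#'   `log2_enrichment`. Empty direction strata are omitted with a warning.
#' @export
motif_enrichment <- function(fg, bg_sets, pool, epsilon = 5e-4) {
  regions <- c("upstream", "exon", "downstream")
  out <- list()
  for (dir in c("inclusion", "exclusion")) {
    f <- fg[fg$direction == dir, , drop = FALSE]
    if (nrow(f) == 0L) {
      warning(sprintf("motif_enrichment: no %s events; stratum omitted", dir),
              call. = FALSE)
      next
    }
    bg_ids <- unique(unlist(bg_sets[f$event_id], use.names = FALSE))
    b <- pool[pool$event_id %in% bg_ids, , drop = FALSE]
    for (rg in regions) {
      fg_seq <- f[[rg]]
      bg_seq <- b[[rg]]
      fg_count <- sum(count_ygcy(fg_seq))
      bg_count <- sum(count_ygcy(bg_seq))
      fg_nt <- sum(nchar(fg_seq))
      bg_nt <- sum(nchar(bg_seq))
      fg_d <- if (fg_nt > 0) fg_count / fg_nt else 0
      bg_d <- if (bg_nt > 0) bg_count / bg_nt else 0
      out[[length(out) + 1L]] <- data.frame(
        direction = dir, region = rg,
        fg_count = fg_count, fg_nt = fg_nt, fg_density = fg_d,
        bg_count = bg_count, bg_nt = bg_nt, bg_density = bg_d,
        log2_enrichment = log2((fg_d + epsilon) / (bg_d + epsilon)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' End-to-end YGCY enrichment analysis
#'
#' Classifies events into inclusion / exclusion / background using an event
#' contrast table and thresholds, extracts exon and flank sequences, matches
#' composition-similar backgrounds (k per foreground event) and computes the
#' per-region log2 enrichment by direction.
#'
#' @param events an [event_annotation()] data frame.
#' @param genome named [Biostrings::DNAStringSet] of contigs.
#' @param effect_table event-level [contrast_table()] (effect = dPSI vs
#'   control) with FDR (and p where the preset uses it).
#' @param th a [threshold_preset()].
#' @param flank flank length (default 250).
#' @param k matched backgrounds per foreground event (default 5).
#' @param epsilon pseudo-density per nt (default 5e-4).
#' @param seed tie-break seed for [match_background()].
#' @return A list with `enrichment` (the [motif_enrichment()] table),
#'   `n_inclusion`, `n_exclusion`, `n_background`.
#' @export
ygcy_analysis <- function(events, genome, effect_table, th = threshold_preset(),
                          flank = 250, k = 5, epsilon = 5e-4, seed = 1L) {
  sig <- filter_significant(effect_table, th, modality = "event")
  eff <- setNames(effect_table$effect, effect_table$unit_id)
  events <- events[events$event_id %in% effect_table$unit_id, , drop = FALSE]
  dir <- ifelse(events$event_id %in% sig,
                ifelse(eff[events$event_id] > 0, "inclusion", "exclusion"),
                "background")
  regions <- extract_regions(events, genome, flank = flank, direction = dir)
  fg <- regions[regions$direction != "background", , drop = FALSE]
  pool <- regions[regions$direction == "background", , drop = FALSE]
  if (nrow(fg) == 0L) {
    warning("ygcy_analysis: no significant events; empty enrichment report",
            call. = FALSE)
    return(list(enrichment = NULL, n_inclusion = 0L, n_exclusion = 0L,
                n_background = nrow(pool)))
  }
  bg_sets <- match_background(fg, pool, k = k, seed = seed)
  list(enrichment = motif_enrichment(fg, bg_sets, pool, epsilon = epsilon),
       n_inclusion = sum(fg$direction == "inclusion"),
       n_exclusion = sum(fg$direction == "exclusion"),
       n_background = nrow(pool))
}
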