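# Readers and writers for every external format the pipeline touches.
# Conventions (fixed across the package):
#   * delimited text is tab-separated, "." decimal point, "NA" for missing;
#   * genomic coordinates are 0-based half-open (BED convention) everywhere;
#   * numeric report columns are serialized at 12 significant digits and
#     round-trip bit-exactly at that precision.

#' Construct a validated contrast table
#'
#' A contrast table holds one row per unit (gene or skipped-exon event) for a
#' single comparison against the control group: the effect size (log2 fold
#' change for genes, \eqn{\Delta}PSI for events), a p-value and an FDR.
#'
#' @param unit_id character vector of gene or event identifiers.
#' @param effect numeric effect sizes (log2FC or \eqn{\Delta}PSI).
#' @param p_value,fdr numeric vectors in \[0, 1\] (NA allowed for effect-only
#'   tables, e.g. before [attach_significance()]).
#' @param contrast_label single string naming the comparison, e.g.
#'   `"P01:pre_vs_control"`.
#' @return A `data.frame` of class `"contrast_table"` with columns `unit_id`,
#'   `effect`, `p_value`, `fdr`, `contrast_label`.
#' @export
contrast_table <- function(unit_id, effect, p_value = NA_real_,
                           fdr = NA_real_, contrast_label = "contrast") {
  unit_id <- as.character(unit_id)
  if (anyDuplicated(unit_id)) {
    stop_dm("duplicate unit_id in contrast table: '%s'",
            unit_id[duplicated(unit_id)][1L],
            class = "dmrescue_validation_error")
  }
  effect <- as.numeric(effect)
  p_value <- rep_len(as.numeric(p_value), length(unit_id))
  fdr <- rep_len(as.numeric(fdr), length(unit_id))
  bad_p <- which(!is.na(p_value) & (p_value < 0 | p_value > 1))
  bad_q <- which(!is.na(fdr) & (fdr < 0 | fdr > 1))
  if (length(bad_p)) {
    stop_dm("p_value outside [0, 1] for unit '%s'", unit_id[bad_p[1L]],
            class = "dmrescue_validation_error")
  }
  if (length(bad_q)) {
    stop_dm("fdr outside [0, 1] for unit '%s'", unit_id[bad_q[1L]],
            class = "dmrescue_validation_error")
  }
  out <- data.frame(unit_id = unit_id, effect = effect, p_value = p_value,
                    fdr = fdr, contrast_label = contrast_label,
                    stringsAsFactors = FALSE)
  class(out) <- c("contrast_table", "data.frame")
  out
}

#' Read a per-contrast effect table from delimited text
#'
#' @param path path to a tab-separated file with a header.
#' @param contrast_label label stored in the returned table.
#' @param columns named character vector mapping the canonical names
#'   `unit_id`, `effect`, `p_value`, `fdr` to the column names in the file.
#' @return A [contrast_table()]. Rows whose effect is not interpretable as a
#'   number are dropped with a warning that reports how many were rejected.
#' @export
read_effect_table <- function(path, contrast_label = "contrast",
                              columns = c(unit_id = "unit_id",
                                          effect = "effect",
                                          p_value = "p_value",
                                          fdr = "fdr")) {
  if (!file.exists(path)) {
    stop_dm("effect table not found: %s", path, class = "dmrescue_io_error")
  }
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                   colClasses = "character")
  if (nrow(df) == 0L) {
    stop_dm("effect table is empty: %s", path, class = "dmrescue_format_error")
  }
  needed <- c("unit_id", "effect", "p_value", "fdr")
  columns <- columns[needed]
  missing <- needed[is.na(columns) | !(columns %in% names(df))]
  if (length(missing)) {
    stop_dm("effect table %s is missing required column(s): %s", path,
            paste(columns[missing] %||% missing, collapse = ", "),
            class = "dmrescue_format_error")
  }
  eff <- suppressWarnings(as.numeric(df[[columns[["effect"]]]]))
  bad <- is.na(eff)
  if (any(bad)) {
    warning(sprintf("read_effect_table: rejected %d row(s) with non-numeric effect in %s",
                    sum(bad), path), call. = FALSE)
    df <- df[!bad, , drop = FALSE]
    eff <- eff[!bad]
  }
  if (nrow(df) == 0L) {
    stop_dm("effect table %s has no rows with a numeric effect", path,
            class = "dmrescue_format_error")
  }
  contrast_table(unit_id = df[[columns[["unit_id"]]]],
                 effect = eff,
                 p_value = suppressWarnings(as.numeric(df[[columns[["p_value"]]]])),
                 fdr = suppressWarnings(as.numeric(df[[columns[["fdr"]]]])),
                 contrast_label = contrast_label)
}

#' Construct a PSI matrix object
#'
#' Percent-spliced-in values for skipped-exon events (rows) across samples
#' (columns), with optional per-cell supporting-read counts. Missing PSI (NA)
#' is distinct from PSI = 0: NA marks cells without sufficient read support.
#'
#' @param psi numeric matrix in \[0, 1\] (NA allowed), with event ids as
#'   rownames and sample ids as colnames.
#' @param support optional non-negative matrix of supporting read counts with
#'   identical dimnames.
#' @return A list of class `"psi_matrix"` with elements `psi` and `support`.
#' @export
psi_matrix <- function(psi, support = NULL) {
  psi <- as.matrix(psi)
  if (is.null(rownames(psi)) || is.null(colnames(psi))) {
    stop_dm("psi matrix needs event ids as rownames and sample ids as colnames",
            class = "dmrescue_validation_error")
  }
  bad <- which(!is.na(psi) & (psi < 0 | psi > 1), arr.ind = TRUE)
  if (nrow(bad)) {
    stop_dm("PSI outside [0, 1] for event '%s', sample '%s'",
            rownames(psi)[bad[1L, 1L]], colnames(psi)[bad[1L, 2L]],
            class = "dmrescue_validation_error")
  }
  if (!is.null(support)) {
    support <- as.matrix(support)
    if (!identical(dim(support), dim(psi))) {
      stop_dm("support matrix dimensions do not match the PSI matrix",
              class = "dmrescue_validation_error")
    }
    if (any(!is.na(support) & support < 0)) {
      stop_dm("support reads must be non-negative",
              class = "dmrescue_validation_error")
    }
    dimnames(support) <- dimnames(psi)
  }
  structure(list(psi = psi, support = support), class = "psi_matrix")
}

#' Read a wide PSI table (events x samples)
#'
#' @param path tab-separated file; first column is the event id, remaining
#'   columns are samples. Empty cells or "NA" encode missing PSI.
#' @param support_path optional companion table of supporting-read counts with
#'   the same layout.
#' @return A [psi_matrix()]. Values outside \[0, 1\] raise a validation error
#'   naming the event and sample; they are never silently clamped.
#' @export
read_psi_matrix <- function(path, support_path = NULL) {
  read_wide <- function(p) {
    df <- read.delim(p, stringsAsFactors = FALSE, check.names = FALSE)
    m <- as.matrix(df[, -1L, drop = FALSE])
    storage.mode(m) <- "numeric"
    rownames(m) <- as.character(df[[1L]])
    m
  }
  if (!file.exists(path)) {
    stop_dm("PSI table not found: %s", path, class = "dmrescue_io_error")
  }
  psi <- read_wide(path)
  support <- NULL
  if (!is.null(support_path)) {
    support <- read_wide(support_path)
    support <- support[rownames(psi), colnames(psi), drop = FALSE]
  }
  psi_matrix(psi, support)
}

#' Write a PSI matrix (and optional support matrix) as wide TSVs
#'
#' @param pm a [psi_matrix()].
#' @param path destination for the PSI table.
#' @param support_path optional destination for the supporting-read table.
#' @return `path`, invisibly.
#' @export
write_psi_matrix <- function(pm, path, support_path = NULL) {
  write_wide <- function(m, p, fmt = format_num) {
    df <- data.frame(event_id = rownames(m), apply(m, 2L, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  write_wide(pm$psi, path)
  if (!is.null(support_path) && !is.null(pm$support)) {
    write_wide(pm$support, support_path, fmt = function(x) x)
  }
  invisible(path)
}

#' Read skipped-exon event annotations from BED6
#'
#' Coordinates are kept 0-based half-open exactly as in BED. The strand is
#' required ("." is an error) because upstream/downstream flank orientation is
#' strand-dependent.
#'
#' @param path BED6 file; the name field carries the event id, the score field
#'   is ignored.
#' @return A `data.frame` with columns `event_id`, `chrom`, `exon_start`,
#'   `exon_end`, `strand`.
#' @export
read_event_bed <- function(path) {
  if (!file.exists(path)) {
    stop_dm("BED file not found: %s", path, class = "dmrescue_io_error")
  }
  df <- read.table(path, sep = "\t", stringsAsFactors = FALSE,
                   col.names = c("chrom", "start", "end", "name", "score",
                                 "strand"),
                   colClasses = c("character", "integer", "integer",
                                  "character", "character", "character"))
  event_annotation(event_id = df$name, chrom = df$chrom,
                   exon_start = df$start, exon_end = df$end,
                   strand = df$strand)
}

#' Construct validated event annotations
#'
#' @param event_id,chrom character vectors.
#' @param exon_start,exon_end 0-based half-open exon coordinates.
#' @param strand "+" or "-" per event ("." rejected: flank orientation needs a
#'   strand).
#' @param gene_id optional gene ids.
#' @return A `data.frame` of class `"event_annotation"`.
#' @export
event_annotation <- function(event_id, chrom, exon_start, exon_end, strand,
                             gene_id = NA_character_) {
  event_id <- as.character(event_id)
  if (anyDuplicated(event_id)) {
    stop_dm("duplicate event_id: '%s'", event_id[duplicated(event_id)][1L],
            class = "dmrescue_validation_error")
  }
  bad <- which(exon_start >= exon_end)
  if (length(bad)) {
    stop_dm("exon_start >= exon_end for event '%s'", event_id[bad[1L]],
            class = "dmrescue_validation_error")
  }
  dot <- which(strand == ".")
  if (length(dot)) {
    stop_dm("strand is required (got '.') for event '%s'; flank orientation is strand-dependent",
            event_id[dot[1L]], class = "dmrescue_validation_error")
  }
  bad_strand <- which(!(strand %in% c("+", "-")))
  if (length(bad_strand)) {
    stop_dm("invalid strand '%s' for event '%s'", strand[bad_strand[1L]],
            event_id[bad_strand[1L]], class = "dmrescue_validation_error")
  }
  out <- data.frame(event_id = event_id, chrom = as.character(chrom),
                    exon_start = as.integer(exon_start),
                    exon_end = as.integer(exon_end),
                    strand = strand, gene_id = gene_id,
                    stringsAsFactors = FALSE)
  class(out) <- c("event_annotation", "data.frame")
  out
}

#' Write event annotations as BED6
#'
#' @param events an [event_annotation()] data frame.
#' @param path destination file.
#' @return `path`, invisibly.
#' @export
write_event_bed <- function(events, path) {
  df <- data.frame(events$chrom, events$exon_start, events$exon_end,
                   events$event_id, 0L, events$strand)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read region or genome sequences from FASTA
#'
#' Sequences are uppercased and restricted to the A/C/G/T/N alphabet. Headers
#' are either raw contig names (extraction happens downstream with
#' [extract_regions()]) or pre-extracted region keys such as `"ev1|exon"`.
#'
#' @param path FASTA file.
#' @return A named [Biostrings::DNAStringSet].
#' @export
read_region_fasta <- function(path) {
  if (!file.exists(path)) {
    stop_dm("FASTA not found: %s", path, class = "dmrescue_io_error")
  }
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(names(seqs))) {
    stop_dm("duplicate FASTA header: '%s'",
            names(seqs)[duplicated(names(seqs))][1L],
            class = "dmrescue_validation_error")
  }
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  freq <- Biostrings::alphabetFrequency(seqs)
  extra <- rowSums(freq[, setdiff(colnames(freq), c("A", "C", "G", "T", "N")),
                        drop = FALSE])
  if (any(extra > 0)) {
    stop_dm("non-ACGTN characters in FASTA record '%s'",
            names(seqs)[which(extra > 0)[1L]],
            class = "dmrescue_validation_error")
  }
  seqs
}

#' Read a gene-level count matrix
#'
#' @param path tab-separated file; first column gene id, remaining columns
#'   samples. Counts must be non-negative; negatives are rejected, never
#'   coerced.
#' @return Numeric matrix (genes x samples).
#' @export
read_count_matrix <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "numeric"
  rownames(m) <- as.character(df[[1L]])
  bad <- which(is.na(m) | m < 0, arr.ind = TRUE)
  if (nrow(bad)) {
    stop_dm("invalid count for gene '%s', sample '%s'",
            rownames(m)[bad[1L, 1L]], colnames(m)[bad[1L, 2L]],
            class = "dmrescue_validation_error")
  }
  m
}

#' Construct / validate sample metadata
#'
#' The design is three-arm: untrained controls (timepoint `"baseline"`) and
#' patients sampled before (`"pre"`) and after (`"post"`) the training
#' program. Controls must be at baseline; every patient subject has exactly
#' one pre sample and at most one post sample.
#'
#' @param sample_id,subject_id character vectors.
#' @param group `"control"` or `"patient"` per sample.
#' @param timepoint `"baseline"`, `"pre"` or `"post"` per sample.
#' @param age optional ages in years.
#' @param sex optional sex per sample.
#' @return A `data.frame` of class `"sample_meta"`.
#' @export
sample_meta <- function(sample_id, subject_id, group, timepoint,
                        age = NA_real_, sex = NA_character_) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id)) {
    stop_dm("duplicate sample_id: '%s'", sample_id[duplicated(sample_id)][1L],
            class = "dmrescue_validation_error")
  }
  if (!all(group %in% c("control", "patient"))) {
    stop_dm("group must be 'control' or 'patient'",
            class = "dmrescue_validation_error")
  }
  if (!all(timepoint %in% c("baseline", "pre", "post"))) {
    stop_dm("timepoint must be 'baseline', 'pre' or 'post'",
            class = "dmrescue_validation_error")
  }
  bad <- which(group == "control" & timepoint != "baseline")
  if (length(bad)) {
    stop_dm("control sample '%s' must have timepoint 'baseline'",
            sample_id[bad[1L]], class = "dmrescue_validation_error")
  }
  bad <- which(group == "patient" & timepoint == "baseline")
  if (length(bad)) {
    stop_dm("patient sample '%s' cannot have timepoint 'baseline'",
            sample_id[bad[1L]], class = "dmrescue_validation_error")
  }
  out <- data.frame(sample_id = sample_id,
                    subject_id = as.character(subject_id),
                    group = group, timepoint = timepoint,
                    age = as.numeric(rep_len(age, length(sample_id))),
                    sex = as.character(rep_len(sex, length(sample_id))),
                    stringsAsFactors = FALSE)
  for (sj in unique(out$subject_id[out$group == "patient"])) {
    tp <- out$timepoint[out$subject_id == sj]
    if (sum(tp == "pre") != 1L || sum(tp == "post") > 1L) {
      stop_dm("patient subject '%s' must have exactly one pre and at most one post sample",
              sj, class = "dmrescue_validation_error")
    }
  }
  class(out) <- c("sample_meta", "data.frame")
  out
}

#' Read sample metadata from TSV
#'
#' @param path tab-separated file with columns `sample_id`, `subject_id`,
#'   `group`, `timepoint` and optionally `age`, `sex`.
#' @return A validated [sample_meta()] data frame.
#' @export
read_sample_meta <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("sample_id", "subject_id", "group", "timepoint")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_dm("sample metadata %s is missing column(s): %s", path,
            paste(missing, collapse = ", "), class = "dmrescue_format_error")
  }
  sample_meta(df$sample_id, df$subject_id, df$group, df$timepoint,
              age = df$age %||% NA_real_, sex = df$sex %||% NA_character_)
}

#' Read raw clinical measurements
#'
#' @param path tab-separated file with columns `subject_id`, `test_name`,
#'   `pre_value`, `post_value`.
#' @return A `data.frame` with those columns, numeric pre/post.
#' @export
read_clinical_table <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  needed <- c("subject_id", "test_name", "pre_value", "post_value")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop_dm("clinical table %s is missing column(s): %s", path,
            paste(missing, collapse = ", "), class = "dmrescue_format_error")
  }
  df$pre_value <- as.numeric(df$pre_value)
  df$post_value <- as.numeric(df$post_value)
  df[needed]
}

#' Write a set of result tables plus a JSON run summary
#'
#' One TSV per logical table plus `run_summary.json` carrying the effective
#' configuration, its hash, the seed and the file manifest. Numeric columns
#' are serialized at 12 significant digits, so a rerun with identical inputs
#' and seed produces byte-identical TSVs (only the JSON carries a timestamp).
#'
#' @param tables named list of data frames (may be empty).
#' @param out_dir output directory (created if needed).
#' @param config list of run parameters recorded (and hashed) in the summary.
#' @param seed integer seed recorded in the summary.
#' @param exclusions named list of exclusion counters to record.
#' @return A data frame manifest (`table`, `file`, `n_rows`), invisibly the
#'   same object that is written into the summary.
#' @export
write_report <- function(tables = list(), out_dir, config = list(),
                         seed = NA_integer_, exclusions = list()) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop_dm("cannot create output directory: %s", out_dir,
                     class = "dmrescue_io_error")
  }
  if (file.access(out_dir, 2L) != 0L) {
    stop_dm("output directory is not writable: %s", out_dir,
            class = "dmrescue_io_error")
  }
  files <- character(0)
  rows <- integer(0)
  for (nm in names(tables)) {
    df <- as.data.frame(tables[[nm]])
    num <- vapply(df, is.numeric, logical(1L))
    df[num] <- lapply(df[num], format_num)
    f <- file.path(out_dir, paste0(nm, ".tsv"))
    write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
    files <- c(files, basename(f))
    rows <- c(rows, nrow(df))
  }
  manifest <- data.frame(table = names(tables) %||% character(0),
                         file = files, n_rows = rows,
                         stringsAsFactors = FALSE)
  summary <- list(
    tool = "dmrescue",
    version = as.character(packageVersion("dmrescue")),
    seed = seed,
    config = config,
    config_hash = config_hash(config),
    exclusions = exclusions,
    files = manifest,
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE)
  )
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

# MD5 of the canonical (sorted-key) JSON serialization of the config.
config_hash <- function(config) {
  sort_keys <- function(x) {
    if (is.list(x) && !is.null(names(x))) {
      x <- x[order(names(x))]
      lapply(x, sort_keys)
    } else x
  }
  canon <- jsonlite::toJSON(sort_keys(config), auto_unbox = TRUE, digits = NA)
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(as.character(canon), tf)
  unname(tools::md5sum(tf))
}
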