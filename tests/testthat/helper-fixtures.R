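# Small fixtures built in code; no data files.

tiny_params <- function(...) {
  defaults <- list(n_controls = 4L, n_patients = 4L, n_genes = 300L,
                   n_events = 80L, seed = 42L)
  do.call(sim_params, modifyList(defaults, list(...)))
}

tiny_cohort <- function(...) simulate_cohort(tiny_params(...))

write_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# deliberately different coding style from the package implementation:
# independent brute-force category oracle
oracle_classify <- function(r) {
  if (r < -10) return("misrescued")
  if (r >= 110) return("overrescued")
  if (r <= 10) return("unchanged")
  if (r < 110) return("rescued")
  stop("unreachable")
}

# enumeration oracle for exact subset counts
oracle_exact_counts <- function(sets) {
  subjects <- names(sets)
  events <- unique(unlist(sets))
  out <- list()
  for (m in seq_len(2^length(subjects) - 1L)) {
    members <- subjects[bitwAnd(m, 2^(seq_along(subjects) - 1L)) > 0]
    cnt <- 0L
    for (ev in events) {
      inside <- vapply(subjects, function(s) ev %in% sets[[s]], logical(1))
      if (identical(subjects[inside], members)) cnt <- cnt + 1L
    }
    if (cnt > 0L) out[[paste(members, collapse = "+")]] <- cnt
  }
  out
}

# sliding-window motif oracle
oracle_count_ygcy <- function(s) {
  s <- toupper(s)
  n <- nchar(s)
  if (n < 4L) return(0L)
  hits <- 0L
  for (i in seq_len(n - 3L)) {
    w <- substr(s, i, i + 3L)
    if (grepl("^[CT]GC[CT]$", w)) hits <- hits + 1L
  }
  hits
}
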