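test_that("YGCY counting slides over every window and ignores N", {
  expect_equal(count_ygcy("TGCT"), 1L)
  expect_equal(count_ygcy("AAAA"), 0L)
  expect_equal(count_ygcy("TGCTGCC"), 2L)   # offsets 0 and 3
  expect_equal(count_ygcy("TGCN"), 0L)
  expect_equal(count_ygcy(""), 0L)
  expect_equal(count_ygcy("GC"), 0L)
  expect_equal(count_ygcy(c("TGCT", "CGCC")), c(1L, 1L))

  set.seed(21)
  for (i in 1:15) {
    s <- paste(sample(c("A", "C", "G", "T", "N"), 60, replace = TRUE,
                      prob = c(0.3, 0.25, 0.2, 0.2, 0.05)), collapse = "")
    expect_equal(count_ygcy(s), oracle_count_ygcy(s))
    # position-shift invariance and concatenation additivity up to
    # junction windows
    expect_equal(count_ygcy(paste0("AAAA", s)), count_ygcy(s) +
                   count_ygcy(paste0("AAAA", substr(s, 1, 3))))
  }
})

test_that("region extraction does strand-aware coordinate arithmetic", {
  set.seed(31)
  contig <- paste(sample(c("A", "C", "G", "T"), 600, replace = TRUE),
                  collapse = "")
  genome <- Biostrings::DNAStringSet(c(ctg = contig))
  ev <- event_annotation("ev1", "ctg", 250L, 300L, "+")
  reg <- extract_regions(ev, genome, flank = 250)
  expect_equal(reg$upstream, substr(contig, 1, 250))
  expect_equal(reg$exon, substr(contig, 251, 300))
  expect_equal(reg$downstream, substr(contig, 301, 550))
  expect_false(reg$truncated)

  # minus strand equals plus-strand extraction of the reverse-complemented
  # contig with mirrored coordinates
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(contig)))
  genome_rc <- Biostrings::DNAStringSet(c(ctg = rc))
  ev_minus <- event_annotation("ev1", "ctg", 250L, 300L, "-")
  ev_mirror <- event_annotation("ev1", "ctg", 600L - 300L, 600L - 250L, "+")
  reg_minus <- extract_regions(ev_minus, genome, flank = 250)
  reg_mirror <- extract_regions(ev_mirror, genome_rc, flank = 250)
  expect_equal(reg_minus[c("upstream", "exon", "downstream")],
               reg_mirror[c("upstream", "exon", "downstream")])

  zero <- extract_regions(ev, genome, flank = 0)
  expect_equal(zero$upstream, "")
  expect_equal(zero$exon, reg$exon)

  near_end <- event_annotation("ev2", "ctg", 500L, 590L, "+")
  reg2 <- extract_regions(near_end, genome, flank = 250)
  expect_true(reg2$truncated)
  expect_equal(nchar(reg2$downstream), 10L)

  off <- event_annotation("ev3", "ctg", 550L, 700L, "+")
  expect_error(extract_regions(off, genome),
               class = "dmrescue_validation_error")
})

test_that("background matching is nearest-neighbor on composition with stable ties", {
  mk <- function(id, gc, n = 200) {
    ngc <- round(n * gc)
    s <- paste(c(rep(c("G", "C"), length.out = ngc),
                 rep(c("A", "T"), length.out = n - ngc)), collapse = "")
    data.frame(event_id = id, direction = "background", upstream = s,
               exon = s, downstream = s, truncated = FALSE,
               stringsAsFactors = FALSE)
  }
  fg <- mk("fg", 0.5)
  fg$direction <- "inclusion"
  gcs <- c(0.3, 0.48, 0.5, 0.52, 0.7, 0.9)
  pool <- do.call(rbind, lapply(seq_along(gcs), function(i) {
    mk(paste0("bg", i), gcs[i])
  }))
  sel <- match_background(fg, pool, k = 3, seed = 1)
  expect_setequal(sel$fg, c("bg2", "bg3", "bg4"))

  # deterministic under a fixed seed even with exact composition ties
  pool_tied <- do.call(rbind, lapply(1:6, function(i) mk(paste0("t", i), 0.5)))
  s1 <- match_background(fg, pool_tied, k = 2, seed = 9)
  s2 <- match_background(fg, pool_tied, k = 2, seed = 9)
  expect_identical(s1, s2)

  all6 <- match_background(fg, pool, k = 6, seed = 1)
  expect_setequal(all6$fg, pool$event_id)
  expect_error(match_background(fg, pool, k = 7),
               class = "dmrescue_validation_error")
})

test_that("enrichment is a log2 density ratio with the expected identities", {
  mk_reg <- function(id, seqs, dir = "inclusion") {
    data.frame(event_id = id, direction = dir, upstream = seqs[1],
               exon = seqs[2], downstream = seqs[3], truncated = FALSE,
               stringsAsFactors = FALSE)
  }
  # fg upstream: 2 motifs / 40 nt; bg upstream: 1 motif / 40 nt
  fg <- mk_reg("f1", c(paste0("TGCT", strrep("A", 32), "CGCC"),
                       strrep("A", 40), strrep("A", 40)))
  bg <- mk_reg("b1", c(paste0("TGCT", strrep("A", 36)),
                       strrep("A", 40), strrep("A", 40)), dir = "background")
  enr <- suppressWarnings(
    motif_enrichment(fg, list(f1 = "b1"), bg, epsilon = 0))
  up <- enr[enr$region == "upstream", ]
  expect_equal(up$log2_enrichment, 1)

  # self-comparison is exactly zero
  self <- fg; self$direction <- "background"
  enr0 <- suppressWarnings(
    motif_enrichment(fg, list(f1 = "f1"), self, epsilon = 0))
  expect_equal(enr0$log2_enrichment[enr0$region == "upstream"], 0)

  # duplicating every sequence leaves densities unchanged
  fg2 <- rbind(fg, mk_reg("f2", c(fg$upstream, fg$exon, fg$downstream)))
  bg2 <- rbind(bg, mk_reg("b2", c(bg$upstream, bg$exon, bg$downstream),
                          dir = "background"))
  enr_dup <- suppressWarnings(
    motif_enrichment(fg2, list(f1 = c("b1", "b2"), f2 = c("b1", "b2")),
                     bg2, epsilon = 0))
  expect_equal(enr_dup$log2_enrichment[enr_dup$region == "upstream"], 1)

  expect_warning(motif_enrichment(fg, list(f1 = "b1"), bg),
                 "no exclusion events")
})

test_that("the full motif analysis is invariant to genome strand flipping", {
  sim <- simulate_event_sequences(n_inclusion = 20, n_exclusion = 20,
                                  n_background = 60, density_ratio = 2,
                                  seed = 5)
  flip <- function(genome, events) {
    lens <- setNames(Biostrings::width(genome), names(genome))
    g2 <- Biostrings::reverseComplement(genome)
    e2 <- events
    e2$exon_start <- lens[events$chrom] - events$exon_end
    e2$exon_end <- lens[events$chrom] - events$exon_start
    e2$strand <- ifelse(events$strand == "+", "-", "+")
    list(genome = g2, events = event_annotation(e2$event_id, e2$chrom,
                                                e2$exon_start, e2$exon_end,
                                                e2$strand))
  }
  dir <- unname(sim$direction[sim$events$event_id])
  r1 <- extract_regions(sim$events, sim$genome, flank = 100, direction = dir)
  fl <- flip(sim$genome, sim$events)
  r2 <- extract_regions(fl$events, fl$genome, flank = 100, direction = dir)
  expect_equal(r1[c("upstream", "exon", "downstream")],
               r2[c("upstream", "exon", "downstream")])
})
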