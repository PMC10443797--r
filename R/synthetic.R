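# Synthetic three-arm cohorts (untrained controls / patient pre / patient
# post) with full ground truth, so every downstream stage is testable with no
# access to patient data. The generator emulates the *downstream structure*
# of a DM1 training study: DM1-shifted skipped-exon PSI, negative-binomial
# gene counts with patient-specific dysregulation scaled by disease severity
# (the analogue of the CTG repeat-length spectrum), partial post-training
# rescue heterogeneous across both patients and units, clinical strength
# gains linked to molecular rescue, and exon/flank sequences with
# direction-dependent YGCY density. The source study analyses real data and
# prescribes no generative model; every distributional choice here is an
# artifact decision, documented in the methods vignette.

#' Simulation parameters for a synthetic training cohort
#'
#' Defaults encode the study design being emulated: 6 untrained controls and
#' 9 trained patients, severities spanning the disease spectrum, per-patient
#' expression-rescue fractions spanning weak to strong responders (the
#' observed per-patient average gene rescue ranged roughly from none to
#' ~3/4), and splicing-rescue fractions in a narrower band (most patients
#' rescued a majority of misspliced events, ~63% on average).
#'
#' Per-unit training responsiveness is `rescue = f^k` with a per-unit
#' exponent `k` drawn by stratified uniforms over `gene_resp_range` /
#' `event_resp_range`; `f = 1` gives complete rescue of every unit and
#' `f = 0` gives none, for any exponent.
#'
#' @param n_controls,n_patients cohort sizes (>= 1; defaults 6 and 9).
#' @param n_genes,n_events numbers of simulated genes and skipped-exon
#'   events.
#' @param severity per-patient severity in \[0, 1\] (repeat-length analogue);
#'   scales both effect sizes and how many events a patient missplices.
#' @param rescue_fraction_expr,rescue_fraction_splice per-patient rescue
#'   fractions in \[0, 1\] for gene expression and splicing.
#' @param noise_sd_psi additive Gaussian SD of observed PSI (truncated to
#'   \[0, 1\]); 0 gives noise-free PSI.
#' @param nb_dispersion negative-binomial dispersion of gene counts (> 0).
#' @param frac_dm_genes,frac_dm_events fractions of units carrying a DM1
#'   effect.
#' @param clinical_link_strength in \[0, 1\]: 1 makes clinical gains a
#'   deterministic monotone function of each patient's mean gene rescue; 0
#'   makes them independent noise.
#' @param deterministic_counts emit expected counts (real-valued) instead of
#'   negative-binomial draws; used by noise-free limit checks.
#' @param gene_resp_range,event_resp_range ranges of the per-unit
#'   responsiveness exponent.
#' @param seed integer master seed; sub-streams per component are derived
#'   deterministically from it.
#' @return A validated list of class `"sim_params"`.
#' @export
sim_params <- function(n_controls = 6L, n_patients = 9L,
                       n_genes = 2000L, n_events = 600L,
                       severity = NULL,
                       rescue_fraction_expr = NULL,
                       rescue_fraction_splice = NULL,
                       noise_sd_psi = 0.03, nb_dispersion = 0.1,
                       frac_dm_genes = 0.1, frac_dm_events = 0.3,
                       clinical_link_strength = 0.8,
                       deterministic_counts = FALSE,
                       gene_resp_range = c(0.5, 20),
                       event_resp_range = c(0.25, 4),
                       seed = 1L) {
  n_controls <- assert_count(n_controls, "n_controls")
  n_patients <- assert_count(n_patients, "n_patients")
  n_genes <- assert_count(n_genes, "n_genes")
  n_events <- assert_count(n_events, "n_events")
  severity <- severity %||% seq(0.15, 0.95, length.out = n_patients)
  rescue_fraction_expr <- rescue_fraction_expr %||%
    seq(0.05, 0.85, length.out = n_patients)
  rescue_fraction_splice <- rescue_fraction_splice %||%
    seq(0.25, 0.55, length.out = n_patients)
  assert_number(severity, "severity", 0, 1, len = n_patients)
  assert_number(rescue_fraction_expr, "rescue_fraction_expr", 0, 1,
                len = n_patients)
  assert_number(rescue_fraction_splice, "rescue_fraction_splice", 0, 1,
                len = n_patients)
  assert_number(noise_sd_psi, "noise_sd_psi", lower = 0)
  assert_number(nb_dispersion, "nb_dispersion")
  if (nb_dispersion <= 0) {
    stop_dm("nb_dispersion must be > 0", class = "dmrescue_validation_error")
  }
  assert_number(frac_dm_genes, "frac_dm_genes", 0, 1)
  assert_number(frac_dm_events, "frac_dm_events", 0, 1)
  assert_number(clinical_link_strength, "clinical_link_strength", 0, 1)
  seed <- assert_count(seed, "seed", min = 0L)
  p <- list(n_controls = n_controls, n_patients = n_patients,
            n_genes = n_genes, n_events = n_events, severity = severity,
            rescue_fraction_expr = rescue_fraction_expr,
            rescue_fraction_splice = rescue_fraction_splice,
            noise_sd_psi = noise_sd_psi, nb_dispersion = nb_dispersion,
            frac_dm_genes = frac_dm_genes, frac_dm_events = frac_dm_events,
            clinical_link_strength = clinical_link_strength,
            deterministic_counts = isTRUE(deterministic_counts),
            gene_resp_range = gene_resp_range,
            event_resp_range = event_resp_range, seed = seed)
  class(p) <- "sim_params"
  p
}

# Stratified (Latin-hypercube) uniforms: one draw per equal-probability
# stratum, randomly permuted. Guarantees the sample fills its range with
# spacing <= 2/n, which keeps per-patient rescue summaries strictly ordered.
stratified_runif <- function(n, lo, hi) {
  u <- (seq_len(n) - runif(n)) / n
  lo + (hi - lo) * sample(u)
}

#' Simulate a synthetic training cohort with ground truth
#'
#' Controls are drawn around baseline distributions. Patient pre-training
#' values of DM units are shifted by severity-scaled effects (genes: log2FC
#' of magnitude 2.5 + severity with random sign; events: PSI shifted toward
#' 0 or 1 by event direction, truncated to \[0, 1\]). Post-training values
#' are `pre + rescue * (control - pre)` per unit, with the rescue applied on
#' the log2 scale for genes and the PSI scale for events, plus truncated
#' Gaussian noise on observed PSI. Clinical 1-RM percent gains are a monotone
#' function of each patient's mean gene rescue, mixed with independent noise
#' by `clinical_link_strength`. Identical seeds give bit-identical output.
#'
#' @param params a [sim_params()] list.
#' @return A list of class `"dm_cohort"` with elements `counts` (genes x
#'   samples), `psi` (a [psi_matrix()] with support counts), `meta`
#'   ([sample_meta()]), `clinical` (subject/test/pre/post), `truth` (ground
#'   truth: `dm_gene_ids`, `dm_event_ids`, `event_direction`,
#'   `true_effect_pre` and `true_rescue` matrices for both modalities, the
#'   per-patient `affected` event indicator, noise-free `psi_true` and
#'   `log2_expr` matrices, and `clinical_true_gain`), and `params`.
#' @export
simulate_cohort <- function(params = sim_params()) {
  stopifnot(inherits(params, "sim_params"))
  seeds <- derive_seeds(params$seed, 8L)
  np <- params$n_patients
  nc <- params$n_controls
  patients <- sprintf("P%02d", seq_len(np))
  controls <- sprintf("C%02d", seq_len(nc))
  ctrl_samples <- controls
  pre_samples <- paste0(patients, "_pre")
  post_samples <- paste0(patients, "_post")
  samples <- c(ctrl_samples, pre_samples, post_samples)

  meta <- with_seed(seeds[1L], {
    age_ctrl <- round(runif(nc, 25, 40))
    age_pat <- round(runif(np, 31, 60))
    sample_meta(
      sample_id = samples,
      subject_id = c(controls, patients, patients),
      group = rep(c("control", "patient", "patient"), c(nc, np, np)),
      timepoint = rep(c("baseline", "pre", "post"), c(nc, np, np)),
      age = c(age_ctrl, age_pat, age_pat),
      sex = "M"
    )
  })

  ## ---- genes -------------------------------------------------------------
  genes <- sprintf("g%04d", seq_len(params$n_genes))
  n_dm_g <- max(1L, round(params$frac_dm_genes * params$n_genes))
  gene_str <- with_seed(seeds[2L], {
    mu <- runif(params$n_genes, -2, 10)            # baseline log2 abundance
    dm <- sort(sample(params$n_genes, n_dm_g))
    sign <- sample(c(-1, 1), n_dm_g, replace = TRUE)
    k <- stratified_runif(n_dm_g, params$gene_resp_range[1L],
                          params$gene_resp_range[2L])
    # library-size factors are sampling noise; the deterministic mode is the
    # noise-free world, so they collapse to 1 there
    sf <- if (params$deterministic_counts) rep(1, length(samples))
          else exp(rnorm(length(samples), 0, 0.15))
    list(mu = mu, dm = dm, sign = sign, k = k, sf = sf)
  })
  effect_g <- matrix(0, params$n_genes, np, dimnames = list(genes, patients))
  effect_g[gene_str$dm, ] <- outer(gene_str$sign, 2.5 + params$severity)
  rescue_g <- matrix(NA_real_, params$n_genes, np,
                     dimnames = list(genes, patients))
  rescue_g[gene_str$dm, ] <- t(outer(params$rescue_fraction_expr,
                                     gene_str$k, `^`))
  log2_expr <- matrix(gene_str$mu, params$n_genes, length(samples),
                      dimnames = list(genes, samples))
  log2_expr[, pre_samples] <- gene_str$mu + effect_g
  resid <- effect_g
  resid[gene_str$dm, ] <- effect_g[gene_str$dm, ] *
    (1 - rescue_g[gene_str$dm, ])
  log2_expr[, post_samples] <- gene_str$mu + resid
  depth <- 30
  mu_counts <- sweep(2^log2_expr, 2L, depth * gene_str$sf, `*`)
  counts <- if (params$deterministic_counts) {
    mu_counts
  } else {
    with_seed(seeds[3L], {
      matrix(rnbinom(length(mu_counts), mu = mu_counts,
                     size = 1 / params$nb_dispersion),
             nrow = nrow(mu_counts), dimnames = dimnames(mu_counts))
    })
  }

  ## ---- skipped-exon events ----------------------------------------------
  events <- sprintf("e%04d", seq_len(params$n_events))
  n_dm_e <- max(1L, round(params$frac_dm_events * params$n_events))
  ev_str <- with_seed(seeds[4L], {
    psi0 <- runif(params$n_events, 0.05, 0.95)
    dm <- sort(sample(params$n_events, n_dm_e))
    dir <- sample(c(1, -1), n_dm_e, replace = TRUE)  # +1 incl., -1 excl.
    m <- runif(n_dm_e, 0.25, 0.5)
    k <- stratified_runif(n_dm_e, params$event_resp_range[1L],
                          params$event_resp_range[2L])
    affected <- matrix(runif(n_dm_e * np) < rep(0.3 + 0.6 * params$severity,
                                                each = n_dm_e),
                       n_dm_e, np)
    list(psi0 = psi0, dm = dm, dir = dir, m = m, k = k, affected = affected)
  })
  sev_scale <- 0.5 + 0.5 * params$severity
  shift <- outer(ev_str$dir * ev_str$m, sev_scale) * ev_str$affected
  pre_true_dm <- clamp01(ev_str$psi0[ev_str$dm] + shift)
  effect_e <- matrix(0, params$n_events, np, dimnames = list(events, patients))
  effect_e[ev_str$dm, ] <- pre_true_dm - ev_str$psi0[ev_str$dm]
  rescue_e <- matrix(NA_real_, params$n_events, np,
                     dimnames = list(events, patients))
  rescue_e[ev_str$dm, ] <- t(outer(params$rescue_fraction_splice,
                                   ev_str$k, `^`))
  psi_true <- matrix(ev_str$psi0, params$n_events, length(samples),
                     dimnames = list(events, samples))
  psi_true[, pre_samples] <- ev_str$psi0 + effect_e
  post_resid <- effect_e
  post_resid[ev_str$dm, ] <- effect_e[ev_str$dm, ] *
    (1 - rescue_e[ev_str$dm, ])
  psi_true[, post_samples] <- ev_str$psi0 + post_resid
  psi_obs <- if (params$noise_sd_psi > 0) {
    with_seed(seeds[5L], {
      clamp01(psi_true + matrix(rnorm(length(psi_true), 0,
                                      params$noise_sd_psi),
                                nrow = nrow(psi_true)))
    })
  } else psi_true
  support <- if (params$deterministic_counts) {
    matrix(50, params$n_events, length(samples),
           dimnames = dimnames(psi_obs))
  } else {
    with_seed(seeds[6L], {
      matrix(rnbinom(length(psi_obs), mu = 40, size = 3),
             nrow = nrow(psi_obs), dimnames = dimnames(psi_obs))
    })
  }

  ## ---- clinical ----------------------------------------------------------
  mean_rescue <- colMeans(rescue_g[gene_str$dm, , drop = FALSE])
  true_gain <- 10 + 340 * mean_rescue          # 1-RM percent-change scale
  clinical <- with_seed(seeds[7L], {
    tests_1rm <- ONE_RM_TESTS
    tests_small <- c("knee_extensors", "thirty_ssts")
    pre_ranges <- list(leg_extension = c(20, 60), leg_press = c(50, 150),
                       hip_abduction = c(15, 50), squat = c(30, 100),
                       knee_extensors = c(60, 180), thirty_ssts = c(8, 16))
    link <- params$clinical_link_strength
    rows <- list()
    for (t in c(tests_1rm, tests_small)) {
      pre <- runif(np, pre_ranges[[t]][1L], pre_ranges[[t]][2L])
      if (t %in% tests_1rm) {
        gain <- link * true_gain + (1 - link) * runif(np, 10, 154)
      } else {
        gain <- link * (1 + 32 * mean_rescue) + (1 - link) * runif(np, 1, 33)
      }
      rows[[t]] <- data.frame(subject_id = patients, test_name = t,
                              pre_value = pre,
                              post_value = pre * (1 + gain / 100),
                              stringsAsFactors = FALSE)
    }
    do.call(rbind, c(rows, make.row.names = FALSE))
  })

  truth <- list(
    dm_gene_ids = genes[gene_str$dm],
    dm_event_ids = events[ev_str$dm],
    event_direction = setNames(ifelse(ev_str$dir > 0, "inclusion",
                                      "exclusion"),
                               events[ev_str$dm]),
    true_effect_pre = list(gene = effect_g, event = effect_e),
    true_rescue = list(gene = rescue_g, event = rescue_e),
    affected = matrix(ev_str$affected, n_dm_e, np,
                      dimnames = list(events[ev_str$dm], patients)),
    log2_expr = log2_expr,
    psi_true = psi_true,
    size_factors = setNames(gene_str$sf, samples),
    clinical_true_gain = setNames(true_gain, patients)
  )
  structure(list(counts = counts, psi = psi_matrix(psi_obs, support),
                 meta = meta, clinical = clinical, truth = truth,
                 params = params),
            class = "dm_cohort")
}

#' @export
print.dm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic DM1 training cohort: %d controls, %d patients\n",
              x$params$n_controls, x$params$n_patients))
  cat(sprintf("  %d genes (%d DM), %d skipped-exon events (%d DM), seed %d\n",
              x$params$n_genes, length(x$truth$dm_gene_ids),
              x$params$n_events, length(x$truth$dm_event_ids),
              x$params$seed))
  invisible(x)
}

#' Write a synthetic cohort to disk in the pipeline's input dialects
#'
#' Emits `counts.tsv`, `psi.tsv`, `support.tsv`, `samples.tsv`,
#' `clinical.tsv` and `truth.json` into `dir`.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wide <- function(m, first, path, fmt = format_num) {
    df <- data.frame(first = rownames(m), apply(m, 2L, fmt),
                     check.names = FALSE, stringsAsFactors = FALSE)
    names(df)[1L] <- first
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wide(cohort$counts, "gene_id", file.path(dir, "counts.tsv"))
  write_psi_matrix(cohort$psi, file.path(dir, "psi.tsv"),
                   file.path(dir, "support.tsv"))
  write.table(cohort$meta, file.path(dir, "samples.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(cohort$clinical, file.path(dir, "clinical.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  truth <- cohort$truth
  truth$true_effect_pre <- lapply(truth$true_effect_pre, as.data.frame)
  truth$true_rescue <- lapply(truth$true_rescue, as.data.frame)
  truth$log2_expr <- NULL
  truth$psi_true <- NULL
  truth$affected <- as.data.frame(truth$affected)
  jsonlite::write_json(truth, file.path(dir, "truth.json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(dir)
}

#' Simulate event sequences with planted, direction-dependent YGCY density
#'
#' Generates one contig per event (random strand), with the exon and its
#' flanks embedded, and plants extra YGCY 4-mers (TGCT/TGCC/CGCT/CGCC drawn
#' uniformly) at Poisson-placed positions so the planted regions reach
#' `density_ratio` times the background YGCY density expected under the
#' stated mononucleotide composition. Inclusion-direction events are planted
#' upstream of and within the exon; exclusion-direction events downstream —
#' the positional signature of MBNL binding. Background events are never
#' planted. Coordinates and sequences are mutually consistent:
#' [extract_regions()] on the returned genome and annotation recovers the
#' planted regions.
#'
#' @param n_inclusion,n_exclusion,n_background event counts per direction.
#' @param flank flank length in nt (default 250; must be >= 4 so a motif
#'   fits).
#' @param density_ratio target fold-elevation of planted YGCY density over
#'   background (> 0).
#' @param exon_len_range range of exon lengths (sampled uniformly).
#' @param base_comp named mononucleotide probabilities (A, C, G, T) of the
#'   background sequence.
#' @param margin extra contig sequence beyond each flank.
#' @param seed integer seed.
#' @return A list with `genome` (one contig per event,
#'   [Biostrings::DNAStringSet]), `events` ([event_annotation()]),
#'   `direction` (named per-event), and `expected_density` (the analytic
#'   background YGCY density per nt).
#' @export
simulate_event_sequences <- function(n_inclusion = 100L, n_exclusion = 100L,
                                     n_background = 1000L, flank = 250L,
                                     density_ratio = 2,
                                     exon_len_range = c(80L, 200L),
                                     base_comp = c(A = 0.3, C = 0.2,
                                                   G = 0.2, T = 0.3),
                                     margin = 25L, seed = 1L) {
  if (flank < 4) {
    stop_dm("flank must be >= 4 nt (a YGCY motif cannot fit)",
            class = "dmrescue_validation_error")
  }
  if (density_ratio <= 0) {
    stop_dm("density_ratio must be > 0", class = "dmrescue_validation_error")
  }
  base_comp <- base_comp[c("A", "C", "G", "T")] / sum(base_comp)
  # P(YGCY at a position) under iid composition: Y G C Y
  pY <- base_comp[["C"]] + base_comp[["T"]]
  d0 <- pY * base_comp[["G"]] * base_comp[["C"]] * pY
  # each inserted 4-mer overwrites ~7 windows that carried background motifs
  # at rate d0; correct the insertion rate so the *achieved* density matches
  # the target fold-elevation
  lambda <- max(0, (density_ratio - 1) * d0 / max(1 - 7 * d0, 0.5))
  n <- n_inclusion + n_exclusion + n_background
  direction <- rep(c("inclusion", "exclusion", "background"),
                   c(n_inclusion, n_exclusion, n_background))
  ids <- sprintf("%s_%04d", c("inc", "exc", "bg")[match(direction,
          c("inclusion", "exclusion", "background"))],
          unlist(lapply(c(n_inclusion, n_exclusion, n_background), seq_len)))
  with_seed(seed, {
    exon_len <- round(runif(n, exon_len_range[1L], exon_len_range[2L]))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    contigs <- character(n)
    starts <- ends <- integer(n)
    for (i in seq_len(n)) {
      total <- 2L * margin + 2L * flank + exon_len[i]
      seq_t <- sample(names(base_comp), total, replace = TRUE,
                      prob = base_comp)
      # transcript-orientation coordinates of the plantable regions
      up <- (margin + 1L):(margin + flank)
      ex <- (margin + flank + 1L):(margin + flank + exon_len[i])
      dn <- (margin + flank + exon_len[i] + 1L):(margin + 2L * flank +
                                                   exon_len[i])
      plant_in <- switch(direction[i],
                         inclusion = c(up, ex),
                         exclusion = dn,
                         background = integer(0))
      if (length(plant_in) && lambda > 0) {
        n_ins <- rpois(1L, lambda * length(plant_in))
        ok <- plant_in[plant_in + 3L <= plant_in[length(plant_in)]]
        n_ins <- min(n_ins, length(ok))
        if (n_ins > 0L) {
          pos <- sample(ok, n_ins)
          motifs <- sample(YGCY_MOTIFS, n_ins, replace = TRUE)
          for (j in seq_len(n_ins)) {
            seq_t[pos[j]:(pos[j] + 3L)] <- strsplit(motifs[j], "")[[1L]]
          }
        }
      }
      tx <- paste(seq_t, collapse = "")
      exon_s <- margin + flank            # 0-based
      exon_e <- exon_s + exon_len[i]
      if (strand[i] == "+") {
        contigs[i] <- tx
        starts[i] <- exon_s
        ends[i] <- exon_e
      } else {
        contigs[i] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(tx)))
        starts[i] <- total - exon_e
        ends[i] <- total - exon_s
      }
    }
    genome <- Biostrings::DNAStringSet(setNames(contigs,
                                                paste0("ctg_", ids)))
    events <- event_annotation(event_id = ids, chrom = paste0("ctg_", ids),
                               exon_start = starts, exon_end = ends,
                               strand = strand)
    list(genome = genome, events = events,
         direction = setNames(direction, ids),
         expected_density = unname(d0))
  })
}
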