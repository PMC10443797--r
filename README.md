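# dmrescue

Individual-level transcriptomic rescue analysis for myotonic dystrophy
(DM1) training studies.

## What problem this solves

In DM1, an expanded CUG-repeat RNA sequesters the MBNL splicing factors,
misregulating cassette-exon splicing and gene expression in skeletal muscle.
Exercise partially reverses these defects — but patients are heterogeneous,
and averaging a small cohort can mask large individual changes (two patients
moving in opposite directions cancel exactly in a grouped contrast). This
package analyses each patient separately against an untrained control group,
before and after a training program, and quantifies per gene and per
skipped-exon event how much of the pre-training deviation was *rescued*:

    rescue (%) = 100 × (pre − post) / (pre − mean(control))

with PSI values for splicing and vs-control log2 fold changes for
expression. Units are classified as rescued (10 < r < 110), overrescued
(r ≥ 110) or misrescued (r < −10). Per-subject *dysregulation scores* (mean
|ΔPSI| or |log2FC| over the pre-significant units, recomputed post-training
on the same set) summarize global improvement; shared-rescue set
intersections (upset semantics) expose how individual the response is; YGCY
(MBNL-binding) motif enrichment around regulated exons, against
composition-matched backgrounds, probes MBNL dependence; and Spearman /
age-controlled partial Spearman correlations link the percentage of DEGs
rescued to clinical strength gains (average percent change over four 1-RM
tests). Clinical changes are judged against the minimal detectable change,
MDC = 1.96 × SEMT × √2 with SEMT = SD_baseline × √(1 − ICC).

It is aimed at bioinformaticians analysing pre/post intervention designs in
DM1 (or similar spliceopathies) who already have effect tables (e.g. from
edgeR and rMATS) or PSI/count matrices, and at methodologists who want a
fully ground-truthed synthetic cohort to exercise such pipelines.

## Worked example

```r
library(dmrescue)

co <- simulate_cohort(sim_params(seed = 1))   # 6 controls, 9 patients
an <- analyze_cohort(co)                      # strength-preset thresholds
print(an)
#> Individual rescue analysis: 9 patients, preset 'strength' (welch_bh significance)
#>   splicing dysregulation score: pre 0.299 -> post 0.229 (cohort mean)
#>   expression dysregulation score: pre 3.021 -> post 2.700 (cohort mean)
#>   %DEGs rescued: P01=45% P02=38% P03=36% P04=37% P05=43% P06=54% P07=43% P08=52% P09=70%
#>   rescue vs 1-RM gain: rho = 0.561 (p = 0.116, n = 9)
```

Reading this: every patient's splicing dysregulation score drops after
training (0.299 → 0.229 on average — global splicing improvement), the
percentage of differentially expressed genes rescued varies widely between
patients (36–70%, reflecting the planted rescue spectrum plus the intrinsic
noise floor of n = 1 contrasts), and that percentage correlates positively
with the simulated 1-RM strength gains. `write_report(analysis_tables(an),
"out")` writes the full per-unit/per-subject tables as TSV plus a JSON run
summary with the config hash and seed; reruns are byte-identical.

Motif analysis on planted sequences:

```r
sim <- simulate_event_sequences(n_inclusion = 300, n_background = 1500,
                                density_ratio = 2, seed = 1)
reg <- extract_regions(sim$events, sim$genome, flank = 250,
                       direction = unname(sim$direction[sim$events$event_id]))
fg   <- reg[reg$direction == "inclusion", ]
pool <- reg[reg$direction == "background", ]
motif_enrichment(fg, match_background(fg, pool, k = 5, seed = 1), pool)
#>   direction     region ... log2_enrichment
#> 1 inclusion   upstream ...           0.957
#> 2 inclusion       exon ...           0.818
#> 3 inclusion downstream ...          -0.060
```

The planted 2× YGCY elevation upstream/within inclusion exons is recovered
(log2 ≈ 1) while the unplanted downstream flank stays near 0.

A thin CLI wrapper lives at `inst/cli/dmrescue`
(`dmrescue simulate|run|motif ...`, JSON config, exit codes 0/2/3).

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

recomputes the full pipeline on the default synthetic cohort for the given
seed (simulation → contrasts → significance → rescue → scores → clinical
correlation), prints the run summary, and writes the JSON result map.

## Package tour

| Area | Functions |
|---|---|
| Synthetic cohorts | `sim_params`, `simulate_cohort`, `simulate_event_sequences`, `write_cohort` |
| IO | `read_effect_table`, `read_psi_matrix`, `read_event_bed`, `read_region_fasta`, `read_count_matrix`, `read_sample_meta`, `write_report` |
| Contrasts | `estimate_psi`, `estimate_log2fc`, `attach_significance`, `filter_significant`, `filter_low_counts`, `mask_low_support`, `delta_log2fc`, `threshold_preset` |
| Rescue metrics | `percent_rescue`, `classify_rescue`, `rescue_records`, `dysregulation_score`, `percent_units_rescued`, `shared_rescue_overlaps`, `panel_classify` |
| Motif | `count_ygcy`, `extract_regions`, `match_background`, `motif_enrichment`, `ygcy_analysis` |
| Clinical | `percent_change`, `semt`, `mdc`, `meaningful_change`, `average_1rm_change`, `clinical_table`, `spearman_cor`, `partial_spearman`, `grouped_descending_overlap`, `correlate_rescue_with_clinical` |
| Pipeline | `analyze_cohort`, `analysis_tables`, `run_pipeline`, `read_cohort` |

The methods vignette (`vignettes/individual-rescue-analysis.Rmd`) documents
the model, every tunable parameter with units and defaults, the synthetic
world's assumptions and what a green test does and does not establish.
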