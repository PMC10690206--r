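# bap1sig

Multi-omic detection of **BAP1** tumor-suppressor alterations and their
transcriptional and clinical consequences.

BAP1 is inactivated in uveal melanoma, mesothelioma, clear-cell renal
carcinoma and other cancers not only by point mutations but also by long
indels and gene-level copy-number (CN) loss — alteration modes that
mutation-only analyses miss. `bap1sig` is an R package for analysts who
want to classify tumor samples by a copy-number-aware BAP1 alteration
state and quantify its consequences:

* **Variant harmonization** — merge per-caller MAF-dialect call sets with
  allele normalization (prefix/suffix trimming, optional left alignment);
  filter by `FILTER == PASS`, VAF ≥ 0.2, `t_alt_count` ≥ 2, impactful
  consequence, and low within-tumor-type BAP1 expression; count long
  (≥ 40 bp) indels; compare against a legacy call set
  (new-only / concordant / legacy-only, with near-miss detection).
* **Alteration classification** — gene-level CN < 2 defines loss; samples
  are labeled `Unaltered` / `MutOnly` / `CNOnly` / `CN+Mut`; loss-segment
  widths (merged, per sample) distinguish focal from arm-level loss.
* **Differential expression** — per-gene negative-binomial Wald tests
  (`Var = μ + αμ²`, Cox–Reid-adjusted dispersion MLE, median-of-ratios
  size factors as offsets) with per-type covariates (purity, subtype),
  chromosome-3p masking (BAP1 retained), and Benjamini–Hochberg
  adjustment.
* **Signature scores** — per-sample z-scores of sums of median-centered
  expression over a gene set; sign-weighted (+1 up / −1 down) alteration
  signature scores; cross-cohort Spearman comparison of reference-derived
  vs native signatures; mutation-signature scores classified
  positive/negative by a two-component Gaussian mixture (EM, posterior-
  equality cutoff).
* **Enrichment** — preranked GSEA (weighted Kolmogorov–Smirnov running
  sum) with a gene-sampling permutation null, NES, and a recurrent-
  pathway matrix across cohorts.
* **Survival** — AJCC stage reclassification (0–2 low, 3 high, 4
  excluded), administrative censoring at the within-type median follow-up,
  Kaplan–Meier/logrank, and Cox proportional-hazards models (Efron ties).
* **Synthetic cohorts** — a first-class generator of multi-cancer cohorts
  with planted truth (NB counts, caller noise, decoy calls, loss segments,
  exponential hazards) used throughout the validation suite.

## Worked example

Simulate a 120-sample cohort with known truth, run the analysis chain, and
recover the planted hazard ratio of 3:

```r
library(bap1sig)

cfg <- cohort_config(n_types = 1, samples_per_type = 120, n_genes = 800,
                     n_signature_genes = 80, seed = 42)
sim <- simulate_bap1_cohort(cfg)

## harmonize somatic calls from the two simulated callers
merged <- merge_callsets(sim$calls)
filt   <- apply_quality_filters(merged)
attr(filt, "filter_funnel")
#>               input dropped_filter_flag         dropped_vaf   dropped_alt_count
#>                  44                   7                  17                   0
#>       dropped_class            retained
#>                   6                  14

norm  <- normalize_counts(sim$counts)
types <- setNames(sim$samples$tumor_type, sim$samples$sample_id)
calls <- apply_expression_filter(filt, norm, types)

## classify alteration state from CN + mutations
status <- classify_alteration(call_cn_loss(sim$gene_cn),
                              unique(calls$sample_id), types)
attr(status, "totals")
#> Unaltered   MutOnly    CNOnly    CN+Mut
#>        84         5        22         9

## differential expression (3p masked) and the alteration signature
cd <- data.frame(altered = status$altered[match(colnames(sim$counts),
                                                status$sample_id)],
                 purity = sim$samples$purity)
keep <- sim$genes$arm != "3p" | sim$genes$gene == "BAP1"
de  <- fit_nb_wald(sim$counts[keep, ], cd, ~ altered + purity)
sel <- adjust_and_select(de, sim$genes)
attr(sel, "n_selected")
#>   up down
#>   40   43

sc <- alteration_signature_score(norm, sel$gene[sel$direction == "up"],
                                 sel$gene[sel$direction == "down"])

## survival stratified by signature sign
clin <- merge(sim$clinical, sc[, c("sample_id", "class")], by = "sample_id")
clin <- prepare_survival(clin)
cox_fit(clin, "class")
#>            term      hr  lower95  upper95            p converged
#> 1 classpositive 3.05084 1.885493 4.936441 5.548106e-06  TRUE
```

The filter funnel shows 44 raw merged calls reduced to 14 retained
mutations (the simulated decoys fail the flag/VAF/consequence filters);
36 samples are BAP1-altered, the derived signature separates them
cleanly, and the Cox model on the signature sign estimates HR ≈ 3.05
against a planted truth of 3.

The whole chain can also be run end to end from a config file:

```r
path <- write_cohort(sim, "cohort_dir")   # writes MAF/TSV/SEG/GMT/YAML
run_pipeline(path, "out_dir")             # stage artifacts + manifest
```

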