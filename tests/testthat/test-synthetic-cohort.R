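# Synthetic cohort generators: determinism, planted-truth consistency,
# and distributional contracts of the simulated data.

test_that("cohort generation matches configured fractions and is deterministic", {
  cfg <- cohort_config(n_types = 2, samples_per_type = 50,
                       alteration_fractions = c(MutOnly = 0.05, CNOnly = 0.30,
                                                `CN+Mut` = 0.05),
                       n_genes = 100, n_signature_genes = 10, seed = 3)
  ch <- generate_cohort(cfg)
  expect_equal(nrow(ch$samples), 100)
  # ~40 altered in expectation; allow generous binomial slack
  n_alt <- sum(ch$samples$alteration != "Unaltered")
  expect_gt(n_alt, 20)
  expect_lt(n_alt, 60)
  expect_true(all(ch$samples$purity >= cfg$purity_range[1] &
                    ch$samples$purity <= cfg$purity_range[2]))

  ch2 <- generate_cohort(cfg)
  expect_identical(ch, ch2)

  zero <- cohort_config(alteration_fractions = c(MutOnly = 0, CNOnly = 0,
                                                 `CN+Mut` = 0),
                        samples_per_type = 30, n_genes = 50,
                        n_signature_genes = 5, seed = 1)
  expect_true(all(generate_cohort(zero)$samples$alteration == "Unaltered"))

  expect_error(cohort_config(alteration_fractions = c(MutOnly = 0.5,
                                                      CNOnly = 0.5,
                                                      `CN+Mut` = 0.5)),
               "sum")
  expect_error(cohort_config(n_signature_genes = 100, n_genes = 100), "<")
})

test_that("simulated counts follow the configured NB mean-variance law", {
  # moment check at large n: for NB(mu, alpha), Var = mu + alpha mu^2, so
  # the per-gene moment estimator (var - mean) / mean^2 should concentrate
  # around the configured dispersion
  cfg <- cohort_config(n_types = 1, samples_per_type = 5000, n_genes = 20,
                       n_signature_genes = 2,
                       alteration_fractions = c(MutOnly = 0, CNOnly = 0,
                                                `CN+Mut` = 0),
                       nb_dispersion = 0.1, seed = 8)
  ch <- generate_cohort(cfg)
  ex <- simulate_counts(ch, cfg)
  # undo the per-sample library factor by normalizing first
  norm <- sweep(ex$counts, 2, size_factors(ex$counts), "/")
  m <- rowMeans(norm)
  v <- apply(norm, 1, var)
  alpha_hat <- (v - m) / m^2
  expect_equal(median(alpha_hat), 0.1, tolerance = 0.15)
  # BAP1 population mean is reduced in altered samples by construction
  cfg2 <- cohort_config(n_types = 1, samples_per_type = 500, n_genes = 50,
                        n_signature_genes = 5, seed = 9)
  ch2 <- generate_cohort(cfg2)
  ex2 <- simulate_counts(ch2, cfg2)
  cnmut <- ch2$samples$alteration == "CN+Mut"
  unalt <- ch2$samples$alteration == "Unaltered"
  expect_lt(mean(ex2$counts["BAP1", cnmut]), mean(ex2$counts["BAP1", unalt]))
})

test_that("variant simulation respects detection and decoy settings", {
  cfg <- small_config(seed = 5, p_detect = 1, decoy_rate = 0)
  ch <- generate_cohort(cfg)
  calls <- simulate_variant_calls(ch, cfg)
  mutants <- ch$samples$sample_id[ch$samples$alteration %in%
                                    c("MutOnly", "CN+Mut")]
  for (tab in calls) {
    expect_setequal(unique(tab$sample_id), mutants)
    expect_true(all(tab$filter_flag == "PASS"))
  }
  # determinism of the indel-length histogram
  calls2 <- simulate_variant_calls(ch, cfg)
  il1 <- table(bap1sig:::compute_indel_length(calls[[1]]$ref, calls[[1]]$alt))
  il2 <- table(bap1sig:::compute_indel_length(calls2[[1]]$ref, calls2[[1]]$alt))
  expect_identical(il1, il2)
})

test_that("CN simulation plants loss segments over the locus", {
  cfg <- small_config(seed = 6)
  ch <- generate_cohort(cfg)
  cn <- simulate_segments_and_cn(ch, cfg)
  loc <- bap1_locus()
  lab <- ch$samples$alteration
  ids_mut_only <- ch$samples$sample_id[lab == "MutOnly"]
  got <- cn$gene_cn[cn$gene_cn$gene == "BAP1", ]
  expect_true(all(got$copy_number[got$sample_id %in% ids_mut_only] == 2))
  ids_cn <- ch$samples$sample_id[lab %in% c("CNOnly", "CN+Mut")]
  loss_segs <- cn$segments[cn$segments$copy_number < 2, ]
  for (s in ids_cn) {
    ss <- loss_segs[loss_segs$sample_id == s, ]
    expect_true(any(ss$start <= loc$start & ss$end >= loc$end))
  }
})

test_that("segment widths follow the configured focal/arm mixture", {
  # prob_arm 0.7 puts the mixture median inside the arm-level uniform
  # component, where the quantile is well conditioned
  cfg <- cohort_config(n_types = 1, samples_per_type = 1500,
                       alteration_fractions = c(MutOnly = 0, CNOnly = 0.35,
                                                `CN+Mut` = 0),
                       n_genes = 50, n_signature_genes = 5, prob_arm = 0.7,
                       seed = 12)
  ch <- generate_cohort(cfg)
  cn <- simulate_segments_and_cn(ch, cfg)
  loss <- call_cn_loss(cn$gene_cn)
  st <- setNames(ch$samples$tumor_type, ch$samples$sample_id)
  w <- segment_width_stats(cn$segments, loss, st)
  expect_gt(nrow(w$per_sample), 400)
  # analytic mixture median: root of the mixture CDF = 0.5
  mix <- bap1sig:::segment_width_mixture(cfg)
  med_true <- uniroot(function(q) mix$cdf(q) - 0.5, c(1e5, 9e7))$root
  expect_equal(w$per_type$median_width[1], med_true, tolerance = 0.05)
})

test_that("survival simulation produces the configured hazard structure", {
  cfg <- small_config(seed = 31)
  ch <- generate_cohort(cfg)
  cl <- simulate_survival(ch, cfg)
  expect_true(all(cl$PFI %in% 0:1))
  expect_true(all(cl$PFI.time >= 0))
  expect_true(all(grepl("^Stage ", cl$stage)))
  # altered samples carry the configured hazard multiplier in the truth
  hm <- ch$truth$hazard_multiplier
  expect_true(all(hm[ch$samples$alteration != "Unaltered"] ==
                    cfg$hazard_ratio_truth))
  expect_true(all(hm[ch$samples$alteration == "Unaltered"] == 1))
})

test_that("full simulation is deterministic and round-trips through io", {
  cfg <- small_config(seed = 77)
  sim1 <- simulate_bap1_cohort(cfg)
  sim2 <- simulate_bap1_cohort(cfg)
  expect_identical(sim1$counts, sim2$counts)
  expect_identical(sim1$calls, sim2$calls)
  expect_identical(sim1$clinical, sim2$clinical)

  dir <- withr::local_tempdir()
  write_cohort(sim1, dir)
  expect_equal(read_counts(file.path(dir, "counts.tsv")), sim1$counts)
  expect_equal(read_gene_cn(file.path(dir, "gene_cn.tsv")), sim1$gene_cn)
  segs <- read_seg(file.path(dir, "segments.seg"))
  expect_equal(segs, sim1$segments)
  maf <- read_maf(file.path(dir, "caller1.maf"))
  expect_equal(maf[, c("sample_id", "pos", "ref", "alt", "t_depth")],
               sim1$calls$caller1[, c("sample_id", "pos", "ref", "alt",
                                      "t_depth")])
})
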