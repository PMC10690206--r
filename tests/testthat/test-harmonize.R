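# Variant harmonization: allele normalization, merge semantics, the
# quality/consequence/expression filter chain, summaries, concordance.

test_that("allele normalization collapses padded and minimal representations", {
  # one deletion of AG after an anchor C at pos 100, written three ways;
  # oracle: enumerate the representations and check they all normalize to
  # the same key
  reps <- list(
    list(pos = 100L, ref = "CAG", alt = "C"),
    list(pos = 101L, ref = "AG", alt = "-"),
    list(pos = 100L, ref = "CAGT", alt = "CT")  # extra shared suffix base
  )
  norm <- lapply(reps, function(r) {
    v <- toy_variant(pos = r$pos, ref = r$ref, alt = r$alt)
    normalize_variants(v)[, c("pos", "ref", "alt")]
  })
  expect_equal(norm[[1]], norm[[2]], ignore_attr = TRUE)
  expect_equal(norm[[1]], norm[[3]], ignore_attr = TRUE)
  expect_equal(norm[[1]]$ref, "AG")
  expect_equal(norm[[1]]$alt, "-")
  expect_equal(norm[[1]]$pos, 101L)

  # SNVs are untouched
  snv <- normalize_variants(toy_variant(pos = 50L, ref = "G", alt = "T"))
  expect_equal(snv$pos, 50L)
  expect_equal(snv$ref, "G")

  # left-alignment within a homopolymer context shifts the indel left
  ctx <- "TTAAAAG"  # positions 1..7; deletion of one A
  v <- toy_variant(pos = 6L, ref = "A", alt = "-")
  shifted <- normalize_variants(v, context = ctx, context_start = 1L)
  expect_equal(shifted$pos, 3L)
})

test_that("merge collapses identical calls, unions callers, keeps deepest counts", {
  a <- toy_variant(caller = "A", t_depth = 80L, t_alt_count = 24L)
  b <- toy_variant(caller = "B", t_depth = 120L, t_alt_count = 40L)
  m <- merge_callsets(list(a, b))
  expect_equal(nrow(m), 1)
  expect_equal(m$callers, "A,B")
  expect_equal(m$t_depth, 120L)
  expect_equal(m$vaf, 40 / 120)

  # empty input
  expect_equal(nrow(merge_callsets(list())), 0)

  # idempotent and input-order invariant
  m2 <- merge_callsets(list(b, a))
  expect_equal(m, m2)
  expect_equal(merge_callsets(list(m)), m)

  # classification conflict resolved by severity with a warning
  c1 <- toy_variant(caller = "A", classification = "Missense_Mutation")
  c2 <- toy_variant(caller = "B", classification = "Nonsense_Mutation")
  expect_warning(mc <- merge_callsets(list(c1, c2)), "most deleterious")
  expect_equal(mc$variant_classification, "Nonsense_Mutation")

  # padded vs minimal representation of one deletion collapses
  d1 <- toy_variant(caller = "A", pos = 200L, ref = "CAG", alt = "C")
  d2 <- toy_variant(caller = "B", pos = 201L, ref = "AG", alt = "-")
  md <- merge_callsets(list(d1, d2))
  expect_equal(nrow(md), 1)
  expect_equal(md$callers, "A,B")
})

test_that("quality filters apply inclusive thresholds and drop classes", {
  v <- toy_variants(
    toy_variant(sample_id = "s1", t_alt_count = 19L, t_depth = 100L),
    toy_variant(sample_id = "s2", t_alt_count = 20L, t_depth = 100L),
    toy_variant(sample_id = "s3", t_alt_count = 50L, t_depth = 100L),
    toy_variant(sample_id = "s4", t_alt_count = 1L, t_depth = 2L),
    toy_variant(sample_id = "s5", classification = "Intron"),
    toy_variant(sample_id = "s6", filter_flag = "artifact")
  )
  f <- apply_quality_filters(v)
  # VAF 0.19 dropped, 0.20 kept (boundary inclusive); t_alt_count 1 dropped
  # regardless of VAF; Intron dropped despite PASS + high VAF
  expect_setequal(f$sample_id, c("s2", "s3"))
  funnel <- attr(f, "filter_funnel")
  expect_equal(unname(funnel["input"]), 6)
  expect_equal(unname(funnel["retained"]), 2)
  expect_error(apply_quality_filters(v, vaf_min = 1.5), "vaf_min")
})

test_that("filters commute and are monotone in their thresholds", {
  cfg <- small_config(seed = 19)
  sim <- simulate_bap1_cohort(cfg)
  merged <- merge_callsets(sim$calls)
  # commute: class+flag first then vaf/alt, vs the reverse
  a <- apply_quality_filters(apply_quality_filters(merged, vaf_min = 0,
                                                   alt_min = 0),
                             require_pass = FALSE, drop_classes = character(0))
  b <- apply_quality_filters(apply_quality_filters(merged,
                                                   require_pass = FALSE,
                                                   drop_classes = character(0)),
                             vaf_min = 0, alt_min = 0)
  expect_equal(a[order(a$sample_id, a$pos), c("sample_id", "pos", "ref", "alt")],
               b[order(b$sample_id, b$pos), c("sample_id", "pos", "ref", "alt")],
               ignore_attr = TRUE)
  # monotone: tightening never adds records
  loose <- apply_quality_filters(merged, vaf_min = 0.1)
  tight <- apply_quality_filters(merged, vaf_min = 0.3)
  key_l <- with(loose, paste(sample_id, pos, ref, alt))
  key_t <- with(tight, paste(sample_id, pos, ref, alt))
  expect_true(all(key_t %in% key_l))
})

test_that("expression filter keeps low-expressing mutants within type", {
  # 10 samples, one type; BAP1 expression increases with sample index
  expr <- matrix(seq(1, 10), nrow = 1,
                 dimnames = list("BAP1", paste0("s", 1:10)))
  st <- setNames(rep("T01", 10), paste0("s", 1:10))
  v <- toy_variants(toy_variant(sample_id = "s1"),
                    toy_variant(sample_id = "s9"))
  f <- apply_expression_filter(v, expr, st)
  expect_equal(f$sample_id, "s1")  # rank 1/10 kept, rank 9/10 dropped
  rev <- attr(f, "review_table")
  expect_equal(nrow(rev), 2)
  expect_equal(rev$within_type_rank[rev$sample_id == "s1"], 1L)

  # small types skip the filter with a warning
  st_small <- setNames(c(rep("T01", 3), rep("T02", 7)), paste0("s", 1:10))
  expect_warning(
    fs <- apply_expression_filter(toy_variant(sample_id = "s3"), expr,
                                  st_small),
    "skipped")
  expect_equal(nrow(fs), 1)

  # samples absent from the expression matrix are dropped with a reason
  v2 <- toy_variant(sample_id = "nope")
  f2 <- apply_expression_filter(v2, expr, st)
  expect_equal(nrow(f2), 0)
  expect_equal(attr(f2, "dropped_no_expression"), "nope")
})

test_that("variant summaries count classes, mutant samples, and long indels", {
  empty <- summarize_variants(bap1sig:::new_variant_table())
  expect_equal(empty$n_variants, 0)
  expect_equal(empty$n_long_indels, 0)

  v <- toy_variants(
    toy_variant(sample_id = "s1", classification = "Nonsense_Mutation"),
    toy_variant(sample_id = "s1", pos = 52400100L,
                classification = "Nonsense_Mutation"),
    toy_variant(sample_id = "s2", classification = "Frame_Shift_Del",
                ref = paste(rep("A", 39), collapse = ""), alt = "-"),
    toy_variant(sample_id = "s3", classification = "Frame_Shift_Del",
                ref = paste(rep("A", 40), collapse = ""), alt = "-"),
    toy_variant(sample_id = "s4", classification = "Nonsense_Mutation"),
    toy_variant(sample_id = "s5"),
    toy_variant(sample_id = "s6", classification = "Frame_Shift_Ins",
                ref = "-", alt = "AT"),
    toy_variant(sample_id = "s7"),
    toy_variant(sample_id = "s8"),
    toy_variant(sample_id = "s9")
  )
  v$indel_length <- bap1sig:::compute_indel_length(v$ref, v$alt)
  s <- summarize_variants(v, long_indel_min = 40)
  expect_equal(s$n_variants, 10)
  # 6/10 deleterious nonsense/frameshift calls
  del <- s$by_classification
  frac_del <- sum(del$n[del$classification %in%
                          c("Nonsense_Mutation", "Frame_Shift_Del",
                            "Frame_Shift_Ins")]) / s$n_variants
  expect_equal(frac_del, 0.6)
  # only the 40bp deletion counts as long (39 does not)
  expect_equal(s$n_long_indels, 1)
  expect_equal(s$n_mutant_samples, 9)
})

test_that("concordance partitions the union and flags near-misses", {
  a1 <- toy_variant(sample_id = "s1", pos = 100L)
  a2 <- toy_variant(sample_id = "s2", pos = 200L)
  a3 <- toy_variant(sample_id = "s3", pos = 300L)
  b1 <- toy_variant(sample_id = "s4", pos = 400L)
  b2 <- toy_variant(sample_id = "s5", pos = 500L)

  same <- compare_callsets(toy_variants(a1, a2), toy_variants(a1, a2))
  expect_equal(same$n_concordant, 2)
  expect_equal(same$n_new_only + same$n_legacy_only, 0)

  disj <- compare_callsets(toy_variants(a1, a2, a3), toy_variants(b1, b2))
  expect_equal(c(disj$n_new_only, disj$n_concordant, disj$n_legacy_only),
               c(3, 0, 2))
  # counts partition the union
  expect_equal(disj$n_new_only + disj$n_concordant + disj$n_legacy_only,
               nrow(disj$assignment))

  # same-sample calls 5bp apart: near-miss, not concordant (oracle: pairwise
  # enumeration of same-sample positions within the 10bp window)
  n1 <- toy_variant(sample_id = "s1", pos = 100L, ref = "A", alt = "T")
  l1 <- toy_variant(sample_id = "s1", pos = 105L, ref = "G", alt = "C")
  nm <- compare_callsets(n1, l1)
  expect_equal(nm$n_concordant, 0)
  expect_equal(nrow(nm$near_misses), 1)
  expect_equal(nm$near_misses$distance, 5)
  far <- compare_callsets(n1, toy_variant(sample_id = "s1", pos = 150L))
  expect_equal(nrow(far$near_misses), 0)
})

test_that("full filter chain recovers planted mutants on a synthetic cohort", {
  cfg <- small_config(seed = 23, samples_per_type = 60)
  sim <- simulate_bap1_cohort(cfg)
  merged <- merge_callsets(sim$calls)
  filt <- apply_quality_filters(merged)
  norm <- normalize_counts(sim$counts)
  st <- setNames(sim$samples$tumor_type, sim$samples$sample_id)
  filt2 <- apply_expression_filter(filt, norm, st)
  got <- unique(filt2$sample_id)
  truth_mut <- names(sim$truth$alteration)[sim$truth$alteration %in%
                                             c("MutOnly", "CN+Mut")]
  non_mut <- setdiff(sim$samples$sample_id, truth_mut)
  sens <- mean(truth_mut %in% got)
  spec <- 1 - mean(non_mut %in% got)
  expect_gte(sens, 0.9)
  expect_gte(spec, 0.95)
})
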