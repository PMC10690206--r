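# Gene-set z-scores, sign-weighted signature scores, cross-cohort
# correlation, and Gaussian-mixture classification.

test_that("gene-set z-scores match a hand computation and obey contracts", {
  # worked 4-sample, 2-gene example; oracle: explicit arithmetic
  expr <- matrix(c(1, 2, 3, 10,
                   0, 0, 4, 4), nrow = 2, byrow = TRUE,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  # medians: g1 -> 2.5, g2 -> 2; centered sums: -3.5, -2.5, 2.5, 9.5
  sums <- c(-3.5, -2.5, 2.5, 9.5)
  expected_z <- (sums - mean(sums)) / sd(sums)
  sc <- geneset_zscore(expr, c("g1", "g2"))
  expect_equal(sc$score, expected_z)
  expect_equal(sc$raw_sum, sums)

  # z contract: mean 0, sd 1 to 1e-10
  expect_lt(abs(mean(sc$score)), 1e-10)
  expect_lt(abs(sd(sc$score) - 1), 1e-10)

  # identical samples -> SD guard -> all zeros
  same <- matrix(5, nrow = 2, ncol = 4,
                 dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
  expect_true(all(geneset_zscore(same, c("g1", "g2"))$score == 0))

  # uniformly elevated sample has the maximal score
  up <- expr
  up[, 3] <- up[, 3] + 100
  scu <- geneset_zscore(up, c("g1", "g2"))
  expect_equal(which.max(scu$score), 3L)

  # no member present -> error naming the set
  expect_error(geneset_zscore(expr, c("nope1", "nope2"), "MY_SET"), "MY_SET")

  # gene and sample order invariance
  perm <- expr[2:1, c(3, 1, 4, 2)]
  scp <- geneset_zscore(perm, c("g2", "g1"))
  expect_equal(scp$score[match(sc$sample_id, scp$sample_id)], sc$score)
})

test_that("alteration signature scores are sign-antisymmetric", {
  set.seed(7)
  expr <- matrix(rnorm(200, 8, 2), nrow = 20,
                 dimnames = list(paste0("g", 1:20), paste0("s", 1:10)))
  up <- paste0("g", 1:5)
  down <- paste0("g", 6:10)
  a <- alteration_signature_score(expr, up, down)
  b <- alteration_signature_score(expr, down, up)
  expect_equal(a$score, -b$score)

  # empty down set reduces exactly to the gene-set z-score
  only_up <- alteration_signature_score(expr, up)
  gz <- geneset_zscore(expr, up)
  expect_equal(only_up$score, gz$score)

  expect_error(alteration_signature_score(expr, up, up), "overlap")
})

test_that("truly altered samples score positive on a synthetic cohort", {
  cfg <- small_config(seed = 55, n_types = 1, samples_per_type = 120,
                      n_genes = 400, n_signature_genes = 60)
  ch <- generate_cohort(cfg)
  ex <- simulate_counts(ch, cfg)
  norm <- normalize_counts(ex$counts)
  up <- ex$genes$gene[ex$genes$direction > 0]
  down <- ex$genes$gene[ex$genes$direction < 0]
  sc <- alteration_signature_score(norm, up, down)
  altered <- ch$samples$alteration != "Unaltered"
  expect_gte(mean(sc$score[altered] > 0), 0.9)
})

test_that("cross-cohort correlation tracks shared and flipped truth", {
  base <- list(n_types = 1, samples_per_type = 100, n_genes = 300,
               n_signature_genes = 40)
  cfg_a <- do.call(cohort_config, c(base, seed = 61))
  cfg_b <- do.call(cohort_config, c(base, seed = 62))
  cfg_c <- do.call(cohort_config, c(base, seed = 63,
                                    flip_directions = TRUE))
  sims <- lapply(list(A = cfg_a, B = cfg_b, C = cfg_c), function(cf) {
    ch <- generate_cohort(cf)
    list(cfg = cf, ch = ch, norm = normalize_counts(
      simulate_counts(ch, cf)$counts))
  })
  ref_up <- sims$A$ch$genes$gene[sims$A$ch$genes$direction > 0]
  ref_down <- sims$A$ch$genes$gene[sims$A$ch$genes$direction < 0]
  native <- lapply(sims, function(s) {
    list(up = s$ch$genes$gene[s$ch$genes$direction > 0],
         down = s$ch$genes$gene[s$ch$genes$direction < 0])
  })
  expr_by <- lapply(sims, `[[`, "norm")
  cc <- cross_signature_correlation(expr_by, ref_up, ref_down, native)
  # native vs itself is rho = 1; shared truth strongly positive; flipped
  # truth negative
  expect_equal(cc$rho[cc$cohort == "A"], 1)
  expect_gt(cc$rho[cc$cohort == "B"], 0.8)
  expect_lt(cc$rho[cc$cohort == "C"], 0)

  # sign-flipping the reference sets negates the correlations
  cc_fl <- cross_signature_correlation(expr_by, ref_down, ref_up, native)
  expect_equal(cc_fl$rho, -cc$rho)

  # fewer than 3 complete pairs -> NA
  tiny <- lapply(expr_by["A"], function(m) m[, 1:2])
  cc_t <- cross_signature_correlation(tiny, ref_up, ref_down, native["A"])
  expect_true(is.na(cc_t$rho))
})

test_that("two-component mixture recovers well-separated components", {
  set.seed(11)
  x <- c(rnorm(120, 0, 1), rnorm(120, 10, 1))
  truth <- rep(c(FALSE, TRUE), each = 120)
  fit <- fit_gmm2(x)
  expect_false(fit$degenerate)
  cut <- gmm2_cutoff(fit)
  # Bayes boundary of the known mixture lies near 5; spec window (3, 7)
  expect_gt(cut, 3)
  expect_lt(cut, 7)
  expect_gte(mean((x >= cut) == truth), 0.99)
})

test_that("mixture fit agrees with mclust on the same scores", {
  skip_if_not_installed("mclust")
  suppressPackageStartupMessages(library(mclust))
  set.seed(13)
  x <- c(rnorm(150, 2, 1), rnorm(70, 9, 2))
  fit <- fit_gmm2(x)
  mc <- mclust::Mclust(x, G = 2, modelNames = "V", verbose = FALSE)
  expect_equal(sort(fit$mean), sort(unname(mc$parameters$mean)),
               tolerance = 0.05)
  expect_equal(fit$loglik, mc$loglik, tolerance = 1e-3)
})

test_that("mutation-signature classification handles planted and degenerate input", {
  set.seed(17)
  n <- 60
  expr <- matrix(rnorm(40 * 2 * n, 8, 0.5), nrow = 40,
                 dimnames = list(paste0("g", 1:40),
                                 paste0("s", 1:(2 * n))))
  mut <- seq_len(n)  # first n samples are "mutant": up genes elevated
  expr[1:20, mut] <- expr[1:20, mut] + 4
  expr[21:40, mut] <- expr[21:40, mut] - 4
  cls <- mutation_signature_classify(expr, up = paste0("g", 1:20),
                                     down = paste0("g", 21:40))
  expect_gte(mean((cls$class == "positive") ==
                    (seq_len(2 * n) %in% mut)), 0.95)
  # classification is consistent with the cutoff
  expect_true(all((cls$score >= cls$cutoff) == (cls$class == "positive")))

  # a supplied fixed cutoff overrides the mixture
  fixed <- mutation_signature_classify(expr, paste0("g", 1:20),
                                       paste0("g", 21:40), cutoff = 237)
  expect_true(all((fixed$score >= 237) == (fixed$class == "positive")))

  # all-identical scores: documented fallback, everything negative
  flat <- matrix(5, nrow = 4, ncol = 10,
                 dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  expect_warning(
    dg <- mutation_signature_classify(flat, paste0("g", 1:2),
                                      paste0("g", 3:4)),
    "negative|identical")
  expect_true(all(dg$class == "negative"))
})
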