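# Preranked gene-set enrichment: weighted Kolmogorov-Smirnov running-sum
# enrichment score, gene-sampling permutation null, NES, and the
# cross-cancer recurrent-pathway matrix.

# ES from hit positions only (O(set size) per evaluation); the running sum
# attains its positive extremum at a hit position and its negative extremum
# immediately before one. When the two extrema tie in magnitude (to 1e-9)
# the positive one is returned — a documented deterministic tie rule.
es_from_positions <- function(pos, w, N) {
  k <- length(pos)
  n_miss <- N - k
  if (n_miss == 0) return(list(es = 1, at = N))
  Wsum <- sum(w)
  if (Wsum <= 0) { w <- rep(1, k); Wsum <- k }
  ch <- cumsum(w) / Wsum
  j <- seq_len(k)
  miss_before <- (pos - j) / n_miss
  at_hit <- ch - miss_before                 # running sum at each hit
  before <- c(0, ch[-k]) - miss_before       # just before each hit
  i_pos <- which.max(at_hit)
  i_neg <- which.min(before)
  es_pos <- at_hit[i_pos]
  es_neg <- min(before[i_neg], 0)
  if (abs(es_pos) >= abs(es_neg) - 1e-9) {
    list(es = es_pos, at = pos[i_pos])
  } else {
    list(es = es_neg, at = pos[i_neg] - 1L)
  }
}

#' Preranked enrichment score for one gene set
#'
#' Weighted Kolmogorov-Smirnov running sum over a descending ranking:
#' a hit at rank i increments by `|stat_i|^p / sum_hits |stat|^p`, a miss
#' decrements by `1 / (N - n_set)`; the enrichment score is the extremum of
#' largest absolute value, and the leading edge is the set members up to
#' (positive ES) or from (negative ES) the extremum.
#'
#' @param stats named numeric vector of ranking statistics, sorted
#'   descending, unique gene names, finite values.
#' @param set character vector of set member genes.
#' @param p weight exponent (default 1; `p = 0` gives the unweighted KS
#'   statistic).
#' @return list: `es` (in `[-1, 1]`), `leading_edge` (genes), `at`
#'   (rank of the extremum).
#' @export
#' @examples
#' s <- sort(stats::setNames(rnorm(20), paste0("g", 1:20)), decreasing = TRUE)
#' preranked_es(s, names(s)[1:4])$es
preranked_es <- function(stats, set, p = 1) {
  if (any(!is.finite(stats))) stop("ranking statistics must be finite", call. = FALSE)
  if (anyDuplicated(names(stats))) stop("gene names must be unique", call. = FALSE)
  if (is.unsorted(rev(stats))) stop("stats must be sorted in decreasing order", call. = FALSE)
  hits <- which(names(stats) %in% set)
  if (!length(hits)) stop("gene set has no overlap with the ranking", call. = FALSE)
  w <- abs(stats[hits])^p
  r <- es_from_positions(hits, w, length(stats))
  le <- if (r$es >= 0) hits[hits <= r$at] else hits[hits > r$at]
  list(es = unname(r$es), leading_edge = names(stats)[le], at = r$at)
}

#' Preranked GSEA with a gene-sampling permutation null
#'
#' For every distinct set size, a null distribution of enrichment scores is
#' built from `n_perm` random same-size gene samples of the ranking. The
#' p-value is one-sided by ES sign and computed against the sign-matched
#' portion of the null, `(1 + #{same-side null at least as extreme}) /
#' (1 + #{same-side null})` — the classic permutation-GSEA convention,
#' under which null p-values are uniform; the attainable minimum is
#' therefore about `2 / n_perm` for a sign-balanced null. NES divides ES
#' by the mean magnitude of sign-matched null scores; BH adjustment is
#' applied across sets. Deterministic under a fixed seed.
#'
#' @param stats named statistics as in [preranked_es()] (sorted internally).
#' @param sets named list of gene sets.
#' @param n_perm number of permutations (>= 100).
#' @param seed RNG seed.
#' @param p weight exponent.
#' @return data.frame: `pathway`, `size`, `es`, `nes`, `pvalue`, `padj`,
#'   `leading_edge` (comma-joined).
#' @export
gsea_prerank <- function(stats, sets, n_perm = 1000, seed = 1, p = 1) {
  if (n_perm < 100) stop_config("n_perm must be >= 100")
  stats <- sort(stats, decreasing = TRUE)
  N <- length(stats)
  sizes <- vapply(sets, function(s) length(intersect(s, names(stats))), 0L)
  if (any(sizes == 0)) {
    stop(sprintf("set(s) with no overlap with the ranking: %s",
                 paste(names(sets)[sizes == 0], collapse = ", ")),
         call. = FALSE)
  }
  if (any(sizes > N)) stop("gene set larger than the ranking", call. = FALSE)
  absw <- abs(stats)^p

  nulls <- new.env(parent = emptyenv())
  with_seed(seed, {
    for (k in sort(unique(sizes))) {
      es_null <- vapply(seq_len(n_perm), function(i) {
        idx <- sort(sample.int(N, k))
        es_from_positions(idx, absw[idx], N)$es
      }, 0)
      assign(as.character(k), es_null, envir = nulls)
    }
  })

  rows <- lapply(names(sets), function(nm) {
    obs <- preranked_es(stats, sets[[nm]], p = p)
    null <- get(as.character(sizes[[nm]]), envir = nulls)
    if (obs$es >= 0) {
      side <- null[null >= 0]
      pv <- (1 + sum(side >= obs$es)) / (1 + length(side))
      denom <- mean(side[side > 0])
    } else {
      side <- null[null < 0]
      pv <- (1 + sum(side <= obs$es)) / (1 + length(side))
      denom <- mean(abs(side))
    }
    nes <- if (is.finite(denom) && denom > 0) obs$es / denom else NA_real_
    data.frame(pathway = nm, size = sizes[[nm]], es = obs$es, nes = nes,
               pvalue = pv,
               leading_edge = paste(obs$leading_edge, collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$padj <- stats::p.adjust(out$pvalue, method = "BH")
  out <- out[, c("pathway", "size", "es", "nes", "pvalue", "padj",
                 "leading_edge")]
  rownames(out) <- NULL
  out
}

#' Recurrently enriched pathways across cohorts
#'
#' Retains pathways whose adjusted p-value is below `alpha` in at least
#' `min_types` cohorts, and returns their NES matrix with significance
#' tiers (`padj < 0.05`, `< 0.1`, `>= 0.1`) and an average-linkage
#' hierarchical clustering order of the cohorts (Euclidean distance on NES
#' columns).
#'
#' @param results_by_cohort named list of [gsea_prerank()] result tables.
#' @param min_types minimum number of significant cohorts (default 5).
#' @param alpha significance level on `padj` (default 0.05).
#' @return list: `nes` (pathway x cohort matrix), `tier` (character matrix),
#'   `cohort_order`, `n_significant` per pathway.
#' @export
recurrent_pathway_matrix <- function(results_by_cohort, min_types = 5,
                                     alpha = 0.05) {
  if (length(results_by_cohort) < min_types) {
    stop_config(sprintf("need >= %d cohorts, got %d", min_types,
                        length(results_by_cohort)))
  }
  cohorts <- names(results_by_cohort)
  pathways <- sort(unique(unlist(lapply(results_by_cohort,
                                        function(r) r$pathway))))
  nes <- matrix(NA_real_, length(pathways), length(cohorts),
                dimnames = list(pathways, cohorts))
  padj <- nes
  for (cc in cohorts) {
    r <- results_by_cohort[[cc]]
    nes[r$pathway, cc] <- r$nes
    padj[r$pathway, cc] <- r$padj
  }
  n_sig <- rowSums(padj < alpha, na.rm = TRUE)
  keep <- n_sig >= min_types
  nes <- nes[keep, , drop = FALSE]
  padj <- padj[keep, , drop = FALSE]
  tier <- matrix(ifelse(is.na(padj), "ns",
                        ifelse(padj < 0.05, "padj<0.05",
                               ifelse(padj < 0.1, "padj<0.1", "ns"))),
                 nrow(padj), ncol(padj), dimnames = dimnames(padj))
  ord <- seq_along(cohorts)
  if (nrow(nes) >= 1 && length(cohorts) > 2) {
    m <- nes
    m[is.na(m)] <- 0
    ord <- stats::hclust(stats::dist(t(m)), method = "average")$order
  }
  list(nes = nes, tier = tier, cohort_order = cohorts[ord],
       n_significant = n_sig[keep])
}
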