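# Per-sample gene-set z-scores, sign-weighted alteration/mutation signature
# scores, cross-cohort correlation, and two-component Gaussian-mixture
# classification of mutation scores.

#' Normalize counts for signature scoring
#'
#' `log2(count / size factor + 1)`; sums of raw counts would be dominated
#' by a handful of high-expression genes.
#'
#' @param counts gene-by-sample count matrix.
#' @param sf optional size factors (default [size_factors()]).
#' @return Matrix of log2 normalized expression.
#' @export
normalize_counts <- function(counts, sf = NULL) {
  counts <- as.matrix(counts)
  sf <- sf %||% size_factors(counts)
  log2(sweep(counts, 2, sf, "/") + 1)
}

center_by_median <- function(expr) {
  expr - apply(expr, 1, stats::median)
}

sum_over_set <- function(centered, genes, set_name = "gene set") {
  present <- intersect(genes, rownames(centered))
  if (!length(present)) {
    stop(sprintf("no member of %s present in the expression matrix", set_name),
         call. = FALSE)
  }
  n_drop <- length(genes) - length(present)
  if (n_drop > 0) {
    message(sprintf("%s: %d member gene(s) absent from matrix, dropped",
                    set_name, n_drop))
  }
  colSums(centered[present, , drop = FALSE])
}

zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s < .Machine$double.eps) return(rep(0, length(x)))
  (x - mean(x)) / s
}

#' Per-sample gene-set z-score
#'
#' Within one cohort (tumor type): each gene's expression is centered by
#' its within-cohort median; per sample, the centered values are summed
#' over the set members present in the matrix; the sums are z-transformed
#' across samples. Samples with comparatively high expression of the set
#' therefore get higher scores. A zero-variance guard returns all-zero
#' scores.
#'
#' @param expr normalized expression matrix (genes x samples), one cohort.
#' @param genes character vector of member gene ids.
#' @param set_name label used in messages and the output.
#' @return data.frame `sample_id`, `signature`, `score` (z units), `raw_sum`.
#' @export
#' @examples
#' expr <- matrix(c(1, 2, 1, 2, 5, 6, 1, 2), nrow = 2,
#'                dimnames = list(c("g1", "g2"), paste0("s", 1:4)))
#' geneset_zscore(expr, c("g1", "g2"))
geneset_zscore <- function(expr, genes, set_name = "gene_set") {
  centered <- center_by_median(expr)
  s <- sum_over_set(centered, genes, set_name)
  data.frame(sample_id = colnames(expr), signature = set_name,
             score = zscore(s), raw_sum = unname(s),
             stringsAsFactors = FALSE)
}

#' Sign-weighted alteration signature score
#'
#' Genes upregulated in altered samples contribute with weight +1 and
#' downregulated genes with weight -1: per sample, the median-centered
#' expression is summed over the up set, minus the sum over the down set,
#' and the combined sums are z-transformed within the cohort (or left on
#' the raw-sum scale). A positive score marks a sample whose expression is
#' overall more similar to altered samples.
#'
#' @param expr normalized expression matrix (one cohort).
#' @param up,down disjoint character vectors of up-/down-regulated genes
#'   (`down` may be empty, reducing to [geneset_zscore()]).
#' @param scale `"z"` (default) or `"raw_sum"`.
#' @param set_name signature label.
#' @return data.frame `sample_id`, `signature`, `score`, `raw_sum`,
#'   `class` (`positive` iff score > 0 on z scale).
#' @export
alteration_signature_score <- function(expr, up, down = character(0),
                                       scale = c("z", "raw_sum"),
                                       set_name = "alteration_signature") {
  scale <- match.arg(scale)
  if (length(intersect(up, down))) {
    stop("up and down gene sets overlap", call. = FALSE)
  }
  centered <- center_by_median(expr)
  s <- sum_over_set(centered, up, paste0(set_name, " (up)"))
  if (length(down)) {
    s <- s - sum_over_set(centered, down, paste0(set_name, " (down)"))
  }
  score <- if (scale == "z") zscore(s) else unname(s)
  data.frame(sample_id = colnames(expr), signature = set_name,
             score = score, raw_sum = unname(s),
             class = ifelse(score > 0, "positive", "negative"),
             stringsAsFactors = FALSE)
}

#' Correlate a reference-derived signature with native signatures
#'
#' For each cohort, computes the reference-derived (e.g. UVM-derived) and
#' the cohort's own (native) alteration signature scores on the same
#' samples and reports their Spearman correlation over pairwise-complete
#' observations.
#'
#' @param expr_by_cohort named list of normalized expression matrices.
#' @param ref_up,ref_down reference signature gene sets.
#' @param native_sets named list (per cohort) of lists with `up`, `down`.
#' @return data.frame `cohort`, `rho`, `n` (`rho` is `NA` with fewer than
#'   3 complete pairs).
#' @export
cross_signature_correlation <- function(expr_by_cohort, ref_up, ref_down,
                                        native_sets) {
  out <- lapply(names(expr_by_cohort), function(cc) {
    expr <- expr_by_cohort[[cc]]
    ref <- alteration_signature_score(expr, ref_up, ref_down,
                                      set_name = "reference")
    nat <- alteration_signature_score(expr, native_sets[[cc]]$up,
                                      native_sets[[cc]]$down,
                                      set_name = "native")
    m <- merge(ref[, c("sample_id", "score")],
               nat[, c("sample_id", "score")], by = "sample_id")
    ok <- stats::complete.cases(m$score.x, m$score.y)
    n <- sum(ok)
    rho <- if (n < 3) NA_real_ else
      stats::cor(m$score.x[ok], m$score.y[ok], method = "spearman")
    data.frame(cohort = cc, rho = rho, n = n, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# ---- two-component univariate Gaussian mixture (EM) ----

em_gmm2_once <- function(x, mu, sdv, w, tol, max_iter) {
  n <- length(x)
  ll_old <- -Inf
  var_floor <- max(stats::var(x), .Machine$double.eps) * 1e-8
  for (it in seq_len(max_iter)) {
    d1 <- w[1] * stats::dnorm(x, mu[1], sdv[1])
    d2 <- w[2] * stats::dnorm(x, mu[2], sdv[2])
    tot <- d1 + d2
    if (any(tot <= 0) || any(!is.finite(tot))) return(NULL)
    g <- d1 / tot
    n1 <- sum(g); n2 <- n - n1
    if (n1 < 1e-8 || n2 < 1e-8) {
      return(list(mu = mu, sd = sdv, w = w, loglik = sum(log(tot)),
                  posterior = g, degenerate = TRUE, iter = it))
    }
    mu <- c(sum(g * x) / n1, sum((1 - g) * x) / n2)
    sdv <- sqrt(pmax(c(sum(g * (x - mu[1])^2) / n1,
                       sum((1 - g) * (x - mu[2])^2) / n2), var_floor))
    w <- c(n1, n2) / n
    ll <- sum(log(w[1] * stats::dnorm(x, mu[1], sdv[1]) +
                    w[2] * stats::dnorm(x, mu[2], sdv[2])))
    if (is.finite(ll) && abs(ll - ll_old) < tol) {
      return(list(mu = mu, sd = sdv, w = w, loglik = ll,
                  posterior = g, degenerate = FALSE, iter = it))
    }
    ll_old <- ll
  }
  list(mu = mu, sd = sdv, w = w, loglik = ll_old, posterior = g,
       degenerate = FALSE, iter = max_iter)
}

#' Fit a two-component univariate Gaussian mixture by EM
#'
#' Unequal-variance model, `k = 2`, with multiple random restarts under a
#' fixed seed; the best log-likelihood wins. Components are ordered by
#' mean. Degenerate fits (an effectively empty component, or inputs with
#' no spread) are flagged.
#'
#' @param x numeric scores.
#' @param restarts number of random initializations (default 10).
#' @param seed RNG seed for the restarts (default 17).
#' @param tol log-likelihood convergence tolerance.
#' @param max_iter maximum EM iterations per restart.
#' @return Object of class `gmm2`: `mean`, `sd`, `weight` (each length 2,
#'   ordered by mean), `loglik`, `posterior` (component-1 responsibility),
#'   `degenerate`.
#' @export
fit_gmm2 <- function(x, restarts = 10, seed = 17, tol = 1e-8,
                     max_iter = 500) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4 || stats::sd(x) < .Machine$double.eps) {
    return(structure(list(mean = rep(mean(x), 2), sd = c(0, 0),
                          weight = c(1, 0), loglik = NA_real_,
                          posterior = rep(1, n), degenerate = TRUE),
                     class = "gmm2"))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      init_mu <- sort(sample(x, 2))
      if (diff(init_mu) < 1e-12) init_mu <- init_mu + c(-1, 1) * stats::sd(x) / 4
      fit <- em_gmm2_once(x, mu = init_mu, sdv = rep(stats::sd(x) / 2, 2),
                          w = c(0.5, 0.5), tol = tol, max_iter = max_iter)
      if (!is.null(fit) &&
          (is.null(best) || (is.finite(fit$loglik) && fit$loglik > best$loglik))) {
        best <- fit
      }
    }
  })
  o <- order(best$mu)
  structure(list(mean = best$mu[o], sd = best$sd[o], weight = best$w[o],
                 loglik = best$loglik,
                 posterior = if (o[1] == 1) best$posterior else 1 - best$posterior,
                 degenerate = best$degenerate ||
                   min(best$w) * n < 1 || min(best$sd) < 1e-12),
            class = "gmm2")
}

#' @export
print.gmm2 <- function(x, ...) {
  cat("Two-component Gaussian mixture (EM)\n")
  cat(sprintf("  means:   %.4g, %.4g\n", x$mean[1], x$mean[2]))
  cat(sprintf("  sds:     %.4g, %.4g\n", x$sd[1], x$sd[2]))
  cat(sprintf("  weights: %.3f, %.3f  loglik: %.4g%s\n", x$weight[1],
              x$weight[2], x$loglik,
              if (x$degenerate) "  [degenerate]" else ""))
  invisible(x)
}

#' Decision cutoff of a fitted two-component mixture
#'
#' The score at which the posterior probabilities of the two components are
#' equal, located between the component means by root finding on the
#' weighted log-density difference; if no boundary lies between the means
#' (e.g. one component engulfs the other), the midpoint of the means is
#' used.
#'
#' @param fit a [fit_gmm2()] object.
#' @return Numeric cutoff.
#' @export
gmm2_cutoff <- function(fit) {
  stopifnot(inherits(fit, "gmm2"))
  if (fit$degenerate) return(NA_real_)
  f <- function(x) {
    log(fit$weight[1]) + stats::dnorm(x, fit$mean[1], fit$sd[1], log = TRUE) -
      log(fit$weight[2]) - stats::dnorm(x, fit$mean[2], fit$sd[2], log = TRUE)
  }
  lo <- fit$mean[1]; hi <- fit$mean[2]
  if (!is.finite(f(lo)) || !is.finite(f(hi)) || f(lo) * f(hi) > 0) {
    return(mean(fit$mean))
  }
  stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
}

#' Score and classify samples with a mutation signature
#'
#' Computes the sign-weighted mutation signature score (by default on the
#' raw-sum scale, the scale on which published cutoffs such as 237 and 138
#' live), fits a two-component Gaussian mixture to the scores, sets the
#' cutoff at the posterior-equality boundary, and labels samples
#' `positive` iff score >= cutoff. A degenerate mixture falls back to a
#' median split with a warning (all-identical scores are all `negative`).
#' A fixed `cutoff` may be supplied to reproduce stored classifications.
#'
#' @param expr normalized expression matrix (one cohort or pooled altered
#'   samples).
#' @param up,down disjoint gene sets up-/down-regulated in mutant vs
#'   CN-only samples.
#' @param scale `"raw_sum"` (default) or `"z"`.
#' @param cutoff optional fixed cutoff overriding the mixture fit.
#' @param restarts,seed EM restart settings passed to [fit_gmm2()].
#' @return data.frame `sample_id`, `signature`, `score`, `class`,
#'   `cutoff`; attributes `gmm` (the fit, when used) and `fallback`.
#' @export
mutation_signature_classify <- function(expr, up, down,
                                        scale = c("raw_sum", "z"),
                                        cutoff = NULL, restarts = 10,
                                        seed = 17) {
  scale <- match.arg(scale)
  sc <- alteration_signature_score(expr, up, down, scale = scale,
                                   set_name = "mutation_signature")
  fallback <- FALSE
  fit <- NULL
  if (is.null(cutoff)) {
    fit <- fit_gmm2(sc$score, restarts = restarts, seed = seed)
    cutoff <- gmm2_cutoff(fit)
    if (fit$degenerate || !is.finite(cutoff)) {
      fallback <- TRUE
      if (stats::sd(sc$score) < .Machine$double.eps) {
        warning("all scores identical; assigning every sample negative",
                call. = FALSE)
        cutoff <- Inf
      } else {
        warning("degenerate mixture fit; falling back to median split",
                call. = FALSE)
        cutoff <- stats::median(sc$score) + .Machine$double.eps
      }
    }
  }
  sc$class <- ifelse(sc$score >= cutoff, "positive", "negative")
  sc$cutoff <- cutoff
  attr(sc, "gmm") <- fit
  attr(sc, "fallback") <- fallback
  sc
}
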