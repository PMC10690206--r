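# Covariate-adjusted negative-binomial Wald differential expression with
# median-of-ratios normalization, per-gene Cox-Reid-adjusted dispersion
# estimation, chr3p masking, and BH adjustment.

#' Median-of-ratios size factors
#'
#' Classic RNA-seq normalization: each sample's factor is the median over
#' genes of the ratio of its count to the per-gene geometric mean, using
#' only genes with nonzero counts in every sample as the reference set.
#' Falls back to geometric-mean-scaled library-size ratios (with a warning)
#' when no gene is nonzero everywhere.
#'
#' @param counts gene-by-sample count matrix.
#' @return Positive numeric vector of per-sample factors.
#' @export
#' @examples
#' m <- matrix(c(10, 20, 30, 20, 40, 60), nrow = 3,
#'             dimnames = list(paste0("g", 1:3), c("a", "b")))
#' size_factors(m)  # second sample's factor is twice the first's
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  keep <- rowSums(counts > 0) == ncol(counts)
  if (!any(keep)) {
    warning("no gene with nonzero counts in all samples; using library-size ratios",
            call. = FALSE)
    ls <- colSums(counts)
    return(ls / exp(mean(log(ls))))
  }
  logc <- log(counts[keep, , drop = FALSE])
  ref <- rowMeans(logc)
  sf <- apply(logc, 2, function(x) exp(stats::median(x - ref)))
  sf
}

# Cox-Reid-adjusted NB profile log-likelihood in the dispersion alpha,
# with fitted means held fixed; the adjustment (-0.5 log det X'WX)
# compensates the downward bias of the ML estimate in small samples.
cr_adjusted_ll <- function(alpha, y, mu, X) {
  ll <- sum(stats::dnbinom(y, mu = mu, size = 1 / alpha, log = TRUE))
  W <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * W)
  ll - 0.5 * as.numeric(determinant(xtwx, logarithm = TRUE)$modulus)
}

fit_one_gene <- function(y, X, offset, coef_idx, dispersion_floor,
                         dispersion_init) {
  if (all(y == 0)) {
    return(c(baseMean = 0, log2FoldChange = NA_real_, lfcSE = NA_real_,
             stat = NA_real_, pvalue = 1, dispersion = NA_real_))
  }
  alpha <- dispersion_init
  fit <- NULL
  for (it in 1:3) {
    fam <- MASS::negative.binomial(theta = 1 / alpha)
    fit <- suppressWarnings(
      stats::glm.fit(X, y, family = fam, offset = offset,
                     control = list(maxit = 50)))
    mu <- pmax(fit$fitted.values, 1e-8)
    opt <- stats::optimize(function(la) cr_adjusted_ll(exp(la), y, mu, X),
                           interval = c(log(1e-8), log(20)), maximum = TRUE)
    alpha_new <- max(exp(opt$maximum), dispersion_floor)
    if (abs(log(alpha_new) - log(alpha)) < 1e-4) { alpha <- alpha_new; break }
    alpha <- alpha_new
  }
  fam <- MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = list(maxit = 50)))
  mu <- pmax(fit$fitted.values, 1e-8)
  W <- mu / (1 + alpha * mu)
  xtwx <- crossprod(X, X * W)
  cov <- tryCatch(chol2inv(chol(xtwx)), error = function(e) NULL)
  if (is.null(cov)) {
    return(c(baseMean = mean(y), log2FoldChange = NA_real_, lfcSE = NA_real_,
             stat = NA_real_, pvalue = 1, dispersion = alpha))
  }
  beta <- fit$coefficients[coef_idx]
  se <- sqrt(cov[coef_idx, coef_idx])
  stat <- beta / se
  c(baseMean = mean(y / exp(offset)),
    log2FoldChange = beta / log(2), lfcSE = se / log(2),
    stat = stat, pvalue = 2 * stats::pnorm(-abs(stat)), dispersion = alpha)
}

#' Negative-binomial Wald differential expression
#'
#' Fits, per gene, an NB log-linear model with `log(size factor)` offsets
#' and the supplied design, within one tumor type. The dispersion
#' (`Var = mu + alpha mu^2`) is estimated per gene by maximizing the
#' Cox-Reid-adjusted profile likelihood (floored at `dispersion_floor`),
#' alternating with IRLS coefficient fits. The Wald statistic for the
#' alteration coefficient is LFC/SE with a two-sided normal reference.
#'
#' @param counts gene-by-sample integer count matrix.
#' @param coldata data.frame of per-sample covariates (rows match columns
#'   of `counts`); must contain the variables in `design`.
#' @param design model formula, e.g. `~ altered + purity`.
#' @param coef name of the tested term (default `"altered"`); matched
#'   against the design-matrix column names by prefix.
#' @param sf optional precomputed size factors (default
#'   [size_factors()] of `counts`).
#' @param dispersion_floor lower bound for alpha (default 1e-8).
#' @param dispersion_init starting alpha (default 0.1).
#' @return data.frame (class `nb_de_result`) with `gene`, `baseMean`,
#'   `log2FoldChange`, `lfcSE`, `stat`, `pvalue`, `dispersion`.
#' @export
fit_nb_wald <- function(counts, coldata, design = ~altered, coef = "altered",
                        sf = NULL, dispersion_floor = 1e-8,
                        dispersion_init = 0.1) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == nrow(coldata))
  X <- stats::model.matrix(design, data = coldata)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    bad <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop(sprintf("design matrix is rank deficient; collinear column(s): %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  coef_idx <- which(startsWith(colnames(X), coef))
  if (length(coef_idx) != 1) {
    stop(sprintf("cannot identify a unique coefficient for '%s' among: %s",
                 coef, paste(colnames(X), collapse = ", ")), call. = FALSE)
  }
  sf <- sf %||% size_factors(counts)
  offset <- log(sf)
  res <- t(vapply(seq_len(nrow(counts)), function(i) {
    tryCatch(fit_one_gene(counts[i, ], X, offset, coef_idx,
                          dispersion_floor, dispersion_init),
             error = function(e) c(baseMean = mean(counts[i, ]),
                                   log2FoldChange = NA_real_,
                                   lfcSE = NA_real_, stat = NA_real_,
                                   pvalue = 1, dispersion = NA_real_))
  }, numeric(6)))
  out <- data.frame(gene = rownames(counts), res, stringsAsFactors = FALSE)
  class(out) <- c("nb_de_result", "data.frame")
  out
}

#' Mask chromosome 3p, adjust p-values, and call DE direction
#'
#' Removes non-BAP1 chromosome-3p genes before adjustment (arm-level
#' co-loss would otherwise masquerade as alteration response), applies
#' Benjamini-Hochberg across the remaining genes (optionally a
#' mean-count-binned weighted BH), and assigns `direction`:
#' `up` iff `padj < alpha` and LFC > `lfc_cut`, `down` symmetric, else `ns`.
#'
#' @param res result of [fit_nb_wald()].
#' @param gene_info data.frame with `gene` and `arm` (chromosome arm
#'   annotation, `"3p"` for the masked arm).
#' @param alpha adjusted-p significance level (default 0.05).
#' @param lfc_cut absolute log2-fold-change threshold for direction calls
#'   (default 0; 1.5 is typical for volcano display).
#' @param mask_chr3p apply the 3p mask (default TRUE).
#' @param keep_gene gene retained despite the mask (default `"BAP1"`).
#' @param weight_bins if a positive integer, use a covariate-binned
#'   weighted BH: genes are binned by `baseMean`, per-bin weights are
#'   proportional to the bin's enrichment of small p-values and normalized
#'   to mean 1 (the total test budget is conserved), and BH is applied to
#'   `p / weight`. `NULL` (default) = plain BH.
#' @return `res` restricted to unmasked genes with `padj` and `direction`
#'   columns; attribute `n_selected` = c(up, down).
#' @export
adjust_and_select <- function(res, gene_info, alpha = 0.05, lfc_cut = 0,
                              mask_chr3p = TRUE, keep_gene = "BAP1",
                              weight_bins = NULL) {
  if (alpha <= 0 || alpha >= 1) stop_config("alpha must be in (0, 1)")
  if (mask_chr3p) {
    arm <- stats::setNames(gene_info$arm, gene_info$gene)
    drop <- !is.na(arm[res$gene]) & arm[res$gene] == "3p" &
      res$gene != keep_gene
    res <- res[!drop, , drop = FALSE]
  }
  if (is.null(weight_bins)) {
    res$padj <- stats::p.adjust(res$pvalue, method = "BH")
  } else {
    nb <- as.integer(weight_bins)
    bins <- cut(rank(res$baseMean, ties.method = "first"),
                breaks = nb, labels = FALSE)
    frac <- tapply(res$pvalue, bins, function(p) mean(p < 0.25))
    w <- pmax(frac[as.character(bins)], 0.05)
    w <- w / mean(w)  # budget-normalized: mean weight 1
    res$padj <- stats::p.adjust(pmin(res$pvalue / w, 1), method = "BH")
  }
  res$direction <- ifelse(!is.na(res$padj) & res$padj < alpha &
                            res$log2FoldChange > lfc_cut, "up",
                          ifelse(!is.na(res$padj) & res$padj < alpha &
                                   res$log2FoldChange < -lfc_cut, "down",
                                 "ns"))
  rownames(res) <- NULL
  attr(res, "n_selected") <- c(up = sum(res$direction == "up"),
                               down = sum(res$direction == "down"))
  res
}
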