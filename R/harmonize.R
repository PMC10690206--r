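# Multi-caller somatic call harmonization: allele normalization, merge,
# quality/consequence/expression filters, summaries, legacy concordance.

# most-deleterious-first ranking used to resolve classification conflicts
# between callers on the same variant key
classification_severity <- function() {
  c("Nonsense_Mutation" = 1,
    "Frame_Shift_Del" = 2, "Frame_Shift_Ins" = 2,
    "Splice_Site" = 3,
    "In_Frame_Del" = 4, "In_Frame_Ins" = 4,
    "Missense_Mutation" = 5)
}

# MAF classes treated as non-impactful (synonymous / non-coding)
#' Default non-impactful MAF variant classes
#'
#' Synonymous and non-coding classification labels dropped by
#' [apply_quality_filters()] by default.
#'
#' @return Character vector of MAF `Variant_Classification` values.
#' @export
maf_noncoding_classes <- function() {
  c("Silent", "Intron", "3'UTR", "5'UTR", "3'Flank", "5'Flank", "IGR", "RNA")
}

# Normalize one allele pair: treat "-" as the empty allele, trim the shared
# suffix then the shared prefix (adjusting pos), then left-align indels
# within the reference context when one is supplied. Returns list(pos, ref, alt).
normalize_allele_pair <- function(pos, ref, alt, context = NULL,
                                  context_start = NULL) {
  ref <- if (identical(ref, "-")) "" else ref
  alt <- if (identical(alt, "-")) "" else alt
  r <- strsplit(ref, "")[[1]]
  a <- strsplit(alt, "")[[1]]
  # trim shared suffix
  while (length(r) > 0 && length(a) > 0 && r[length(r)] == a[length(a)] &&
         !(length(r) == 1 && length(a) == 1)) {
    r <- r[-length(r)]; a <- a[-length(a)]
  }
  # trim shared prefix
  while (length(r) > 1 && length(a) > 1 && r[1] == a[1]) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  while (length(r) > 0 && length(a) > 0 && r[1] == a[1] &&
         (length(r) != length(a))) {
    r <- r[-1]; a <- a[-1]; pos <- pos + 1
  }
  # left-align a pure insertion/deletion within the provided context
  if (!is.null(context) && xor(length(r) == 0, length(a) == 0)) {
    indel <- if (length(r)) r else a
    ctx <- strsplit(context, "")[[1]]
    off <- pos - (context_start %||% 1L)
    while (off > 0 && ctx[off] == indel[length(indel)]) {
      indel <- c(ctx[off], indel[-length(indel)])
      off <- off - 1
      pos <- pos - 1
    }
    if (length(r)) r <- indel else a <- indel
  }
  list(pos = as.integer(pos),
       ref = if (length(r)) paste(r, collapse = "") else "-",
       alt = if (length(a)) paste(a, collapse = "") else "-")
}

#' Normalize variant allele representations
#'
#' Collapses padded and minimal representations of the same event onto one
#' canonical form: shared suffix then prefix trimming (with position
#' adjustment), and optional left-alignment of indels within a reference
#' context string. Empty alleles are written `"-"` (MAF convention).
#'
#' @param variants variant data.frame with `pos`, `ref`, `alt`.
#' @param context optional reference sequence string covering the variants.
#' @param context_start 1-based genomic position of the first context base.
#' @return The data.frame with normalized `pos`, `ref`, `alt`.
#' @export
#' @examples
#' v <- data.frame(sample_id = "s1", chrom = "chr3", pos = c(100L, 101L),
#'                 ref = c("CAG", "AG"), alt = c("C", "-"))
#' normalize_variants(v)[, c("pos", "ref", "alt")]
normalize_variants <- function(variants, context = NULL, context_start = NULL) {
  if (!nrow(variants)) return(variants)
  for (i in seq_len(nrow(variants))) {
    nz <- normalize_allele_pair(variants$pos[i], variants$ref[i],
                                variants$alt[i], context, context_start)
    variants$pos[i] <- nz$pos
    variants$ref[i] <- nz$ref
    variants$alt[i] <- nz$alt
  }
  variants
}

# indel length per the MAF padded/minimal conventions; 0 for SNVs
compute_indel_length <- function(ref, alt) {
  r <- nchar(gsub("-", "", ref))
  a <- nchar(gsub("-", "", alt))
  len <- pmax(r, a)
  ifelse(r == 1 & a == 1, 0L,
         ifelse(pmin(r, a) == 0L, as.integer(len), as.integer(len - 1L)))
}

variant_key <- function(v) {
  paste(v$sample_id, v$chrom, v$pos, v$ref, v$alt, sep = "|")
}

#' Merge per-caller somatic call tables into one harmonized call set
#'
#' Variants identical on (sample, chrom, pos, ref, alt) after allele
#' normalization collapse to a single record whose `callers` field is the
#' union of the emitting callers. Read-count fields are taken from the
#' caller with the highest `t_depth`; conflicting classifications are
#' resolved by a documented most-deleterious-first ranking (with a
#' warning). Output rows are sorted by key, so the merge is input-order
#' invariant and idempotent.
#'
#' @param callsets list of MAF-dialect variant data.frames (one caller each).
#' @param context,context_start optional reference context for left-aligning
#'   indels during normalization.
#' @return A single variant data.frame with union `callers`, recomputed
#'   `vaf` and `indel_length`.
#' @export
merge_callsets <- function(callsets, context = NULL, context_start = NULL) {
  callsets <- Filter(function(x) !is.null(x) && nrow(x) > 0, callsets)
  if (!length(callsets)) {
    out <- new_variant_table()
    out$indel_length <- integer()
    return(out)
  }
  all <- do.call(rbind, lapply(callsets, function(x) {
    assert_cols(x, c("sample_id", "chrom", "pos", "ref", "alt",
                     "variant_classification", "t_alt_count", "t_depth",
                     "filter_flag", "callers"), "callset")
    x
  }))
  all <- normalize_variants(all, context, context_start)
  key <- variant_key(all)
  sev <- classification_severity()
  pieces <- lapply(split(seq_along(key), key), function(ii) {
    g <- all[ii, , drop = FALSE]
    best <- which.max(g$t_depth)
    rec <- g[best, , drop = FALSE]
    cls <- unique(g$variant_classification)
    if (length(cls) > 1) {
      rk <- sev[cls]
      rk[is.na(rk)] <- max(sev) + 1
      pick <- cls[which.min(rk)]
      warning(sprintf(
        "conflicting classifications for %s (%s); keeping most deleterious: %s",
        variant_key(rec), paste(cls, collapse = ", "), pick), call. = FALSE)
      rec$variant_classification <- pick
    }
    rec$callers <- paste(sort(unique(unlist(strsplit(g$callers, ",")))),
                         collapse = ",")
    rec
  })
  out <- do.call(rbind, pieces)
  out <- out[order(out$sample_id, out$chrom, out$pos, out$ref, out$alt), ,
             drop = FALSE]
  out$vaf <- out$t_alt_count / out$t_depth
  out$indel_length <- compute_indel_length(out$ref, out$alt)
  rownames(out) <- NULL
  out
}

#' Apply quality and consequence filters to a merged call set
#'
#' Retains exactly the calls with a PASS filter flag (when required),
#' VAF >= `vaf_min`, alternate read count >= `alt_min` (both thresholds
#' inclusive), and a classification outside `drop_classes`. Per-filter drop
#' counts are attached as the `"filter_funnel"` attribute.
#'
#' @param variants merged variant data.frame.
#' @param vaf_min minimum variant allele frequency (default 0.2).
#' @param alt_min minimum `t_alt_count` (default 2).
#' @param require_pass require `filter_flag == "PASS"`.
#' @param drop_classes classifications to drop
#'   (default [maf_noncoding_classes()]).
#' @return Filtered data.frame with a `filter_funnel` attribute of counts.
#' @export
apply_quality_filters <- function(variants, vaf_min = 0.2, alt_min = 2,
                                  require_pass = TRUE,
                                  drop_classes = maf_noncoding_classes()) {
  if (vaf_min < 0 || vaf_min > 1) stop_config("vaf_min must be in [0, 1]")
  v <- variants
  if (is.null(v$vaf)) v$vaf <- v$t_alt_count / v$t_depth
  n0 <- nrow(v)
  keep_pass <- if (require_pass) v$filter_flag == "PASS" else rep(TRUE, n0)
  keep_vaf <- v$vaf >= vaf_min
  keep_alt <- v$t_alt_count >= alt_min
  keep_cls <- !(v$variant_classification %in% drop_classes)
  funnel <- c(input = n0,
              dropped_filter_flag = sum(!keep_pass),
              dropped_vaf = sum(keep_pass & !keep_vaf),
              dropped_alt_count = sum(keep_pass & keep_vaf & !keep_alt),
              dropped_class = sum(keep_pass & keep_vaf & keep_alt & !keep_cls),
              retained = sum(keep_pass & keep_vaf & keep_alt & keep_cls))
  out <- v[keep_pass & keep_vaf & keep_alt & keep_cls, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "filter_funnel") <- funnel
  out
}

#' Filter mutation calls by within-tumor-type target-gene expression
#'
#' Impactful mutations are expected to reduce target-gene expression;
#' calls are retained only when the mutant sample's normalized BAP1
#' expression is at or below the within-tumor-type `quantile_cut` quantile.
#' Mutant samples absent from the expression matrix are dropped with a
#' logged reason; tumor types with fewer than `min_samples` expressed
#' samples skip the filter with a warning. A per-call review table
#' (expression and within-type rank, standing in for manual read review)
#' is attached as the `"review_table"` attribute.
#'
#' @param variants filtered variant data.frame (needs `tumor_type`).
#' @param expr normalized expression matrix (genes x samples).
#' @param sample_types named character vector: tumor type per sample id
#'   (used for samples missing a `tumor_type` in `variants`).
#' @param gene target gene row of `expr` (default `"BAP1"`).
#' @param quantile_cut within-type quantile threshold (default 0.5, the
#'   within-type median).
#' @param min_samples minimum expressed samples per type to apply the
#'   filter (default 5).
#' @return Filtered variants with `review_table` and `dropped_no_expression`
#'   attributes.
#' @export
apply_expression_filter <- function(variants, expr, sample_types = NULL,
                                    gene = "BAP1", quantile_cut = 0.5,
                                    min_samples = 5) {
  if (quantile_cut < 0 || quantile_cut > 1) {
    stop_config("quantile_cut must be in [0, 1]")
  }
  if (!gene %in% rownames(expr)) {
    stop(sprintf("gene '%s' not present in expression matrix", gene),
         call. = FALSE)
  }
  if (!nrow(variants)) {
    attr(variants, "review_table") <- data.frame()
    return(variants)
  }
  gx <- expr[gene, ]
  if (is.null(sample_types)) {
    sample_types <- stats::setNames(variants$tumor_type, variants$sample_id)
  }
  in_expr <- variants$sample_id %in% colnames(expr)
  dropped_abs <- variants[!in_expr, , drop = FALSE]
  v <- variants[in_expr, , drop = FALSE]
  type_of <- stats::setNames(sample_types[colnames(expr)], colnames(expr))

  keep <- logical(nrow(v))
  review <- NULL
  for (tt in unique(v$tumor_type)) {
    type_samples <- colnames(expr)[!is.na(type_of) & type_of == tt]
    vi <- which(v$tumor_type == tt)
    if (length(type_samples) < min_samples) {
      warning(sprintf(
        "tumor type %s has < %d expressed samples; expression filter skipped",
        tt, min_samples), call. = FALSE)
      keep[vi] <- TRUE
      next
    }
    vals <- gx[type_samples]
    cut <- stats::quantile(vals, quantile_cut, names = FALSE)
    sv <- gx[v$sample_id[vi]]
    rk <- vapply(sv, function(x) sum(vals <= x), 0L)
    keep[vi] <- sv <= cut
    review <- rbind(review, data.frame(
      sample_id = v$sample_id[vi], tumor_type = tt, expression = unname(sv),
      within_type_rank = unname(rk), n_type_samples = length(type_samples),
      retained = keep[vi], stringsAsFactors = FALSE))
  }
  out <- v[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "review_table") <- review
  attr(out, "dropped_no_expression") <- dropped_abs$sample_id
  out
}

#' Summarize a filtered variant call set
#'
#' @param variants filtered variant data.frame.
#' @param long_indel_min minimum indel length (bp) counted as "long"
#'   (default 40).
#' @return A list: `by_classification` (counts and fractions),
#'   `by_tumor_type` (mutant-sample counts and frequencies), `n_variants`,
#'   `n_mutant_samples`, `n_long_indels`.
#' @export
summarize_variants <- function(variants, long_indel_min = 40) {
  if (!nrow(variants)) {
    return(list(by_classification = data.frame(classification = character(),
                                               n = integer(), fraction = numeric()),
                by_tumor_type = data.frame(tumor_type = character(),
                                           n_mutant_samples = integer()),
                n_variants = 0L, n_mutant_samples = 0L, n_long_indels = 0L))
  }
  il <- variants$indel_length %||% compute_indel_length(variants$ref, variants$alt)
  cls <- sort(table(variants$variant_classification), decreasing = TRUE)
  by_cls <- data.frame(classification = names(cls), n = as.integer(cls),
                       fraction = as.numeric(cls) / nrow(variants),
                       stringsAsFactors = FALSE)
  ms <- tapply(variants$sample_id, variants$tumor_type,
               function(s) length(unique(s)))
  by_type <- data.frame(tumor_type = names(ms),
                        n_mutant_samples = as.integer(ms),
                        stringsAsFactors = FALSE)
  list(by_classification = by_cls, by_tumor_type = by_type,
       n_variants = nrow(variants),
       n_mutant_samples = length(unique(variants$sample_id)),
       n_long_indels = sum(il >= long_indel_min))
}

#' Compare a harmonized call set with a legacy call set
#'
#' Partitions the union of both (identically filtered) call sets by variant
#' key into new-only, concordant, and legacy-only calls. Same-sample call
#' pairs within `near_window` bp that are not key-identical are listed
#' separately as near-misses.
#'
#' @param new,legacy variant data.frames filtered with the same thresholds.
#' @param near_window maximum position difference (bp) for a near-miss pair
#'   (default 10).
#' @return A `concordance_report`: counts `n_new_only`, `n_concordant`,
#'   `n_legacy_only`, a per-variant `assignment` table, and `near_misses`.
#' @export
compare_callsets <- function(new, legacy, near_window = 10) {
  kn <- variant_key(new)
  kl <- variant_key(legacy)
  u <- union(kn, kl)
  status <- ifelse(u %in% kn & u %in% kl, "concordant",
                   ifelse(u %in% kn, "new_only", "legacy_only"))
  assignment <- data.frame(key = u, status = status, stringsAsFactors = FALSE)

  near <- NULL
  no <- new[kn %in% u[status == "new_only"], , drop = FALSE]
  lo <- legacy[kl %in% u[status == "legacy_only"], , drop = FALSE]
  if (nrow(no) && nrow(lo)) {
    for (i in seq_len(nrow(no))) {
      j <- which(lo$sample_id == no$sample_id[i] & lo$chrom == no$chrom[i] &
                 abs(lo$pos - no$pos[i]) <= near_window)
      if (length(j)) {
        near <- rbind(near, data.frame(
          sample_id = no$sample_id[i], chrom = no$chrom[i],
          new_pos = no$pos[i], legacy_pos = lo$pos[j],
          distance = abs(lo$pos[j] - no$pos[i]), stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(
    n_new_only = sum(status == "new_only"),
    n_concordant = sum(status == "concordant"),
    n_legacy_only = sum(status == "legacy_only"),
    assignment = assignment,
    near_misses = near %||% data.frame()
  ), class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  tot <- x$n_new_only + x$n_concordant + x$n_legacy_only
  cat(sprintf("Call-set concordance over %d variants:\n", tot))
  cat(sprintf("  new only:    %d\n  concordant:  %d\n  legacy only: %d\n",
              x$n_new_only, x$n_concordant, x$n_legacy_only))
  if (nrow(x$near_misses)) {
    cat(sprintf("  near-miss pairs (same sample, close positions): %d\n",
                nrow(x$near_misses)))
  }
  invisible(x)
}
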