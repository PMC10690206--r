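# Copy-number-aware BAP1 alteration classification and loss-segment widths.

#' Call gene-level copy-number loss
#'
#' A sample has copy-number loss when its gene-level integer copy number is
#' less than two. Samples with missing copy number are excluded from
#' CN-based classification (returned in the `excluded` attribute).
#'
#' @param gene_cn data.frame with `sample_id`, `gene`, `copy_number`.
#' @param gene gene to call (default `"BAP1"`).
#' @return data.frame `sample_id`, `copy_number`, `loss` (logical), with
#'   attribute `excluded` listing samples with missing CN.
#' @export
#' @examples
#' cn <- data.frame(sample_id = paste0("s", 1:5), gene = "BAP1",
#'                  copy_number = c(2L, 1L, 1L, 0L, 2L))
#' sum(call_cn_loss(cn)$loss)  # 3 losses
call_cn_loss <- function(gene_cn, gene = "BAP1") {
  assert_cols(gene_cn, c("sample_id", "gene", "copy_number"), "gene CN table")
  g <- gene_cn[gene_cn$gene == gene, , drop = FALSE]
  if (!nrow(g)) stop(sprintf("gene '%s' not in CN table", gene), call. = FALSE)
  if (any(!is.na(g$copy_number) & g$copy_number < 0)) {
    stop("negative copy number in input", call. = FALSE)
  }
  miss <- g$sample_id[is.na(g$copy_number)]
  g <- g[!is.na(g$copy_number), , drop = FALSE]
  out <- data.frame(sample_id = g$sample_id, copy_number = g$copy_number,
                    loss = g$copy_number < 2, stringsAsFactors = FALSE)
  attr(out, "excluded") <- miss
  out
}

# merge overlapping/adjacent intervals; returns total covered width
merged_width <- function(start, end) {
  o <- order(start)
  start <- start[o]; end <- end[o]
  tot <- 0; cs <- start[1]; ce <- end[1]
  for (i in seq_along(start)[-1]) {
    if (start[i] <= ce + 1) {
      ce <- max(ce, end[i])
    } else {
      tot <- tot + (ce - cs + 1)
      cs <- start[i]; ce <- end[i]
    }
  }
  tot + (ce - cs + 1)
}

#' Per-sample and per-type widths of copy-number loss segments
#'
#' For each sample flagged with gene-level loss, selects loss segments
#' (copy number < 2) overlapping the gene locus (closed intervals, any
#' base overlap) and reports one width per sample — the total width of the
#' merged overlapping segments — plus per-tumor-type median and IQR.
#' Samples flagged as lost but lacking any overlapping loss segment are
#' reported as discordant.
#'
#' @param segments SEG-dialect data.frame (`sample_id`, `chrom`, `start`,
#'   `end`, `copy_number`).
#' @param loss_calls output of [call_cn_loss()].
#' @param sample_types named character vector of tumor type per sample.
#' @param locus list with `chrom`, `start`, `end` (default [bap1_locus()]).
#' @return list: `per_sample` (sample, type, width), `per_type` (n, median,
#'   q1, q3), `discordant` sample ids.
#' @export
segment_width_stats <- function(segments, loss_calls, sample_types,
                                locus = bap1_locus()) {
  assert_cols(segments, c("sample_id", "chrom", "start", "end", "copy_number"),
              "segment table")
  if (any(segments$start > segments$end)) {
    stop("segment with start > end", call. = FALSE)
  }
  lost <- loss_calls$sample_id[loss_calls$loss]
  seg <- segments[segments$sample_id %in% lost &
                  segments$copy_number < 2 &
                  segments$chrom == locus$chrom &
                  segments$start <= locus$end &
                  segments$end >= locus$start, , drop = FALSE]
  widths <- vapply(split(seg, seg$sample_id),
                   function(s) merged_width(s$start, s$end), 0)
  per_sample <- data.frame(sample_id = names(widths),
                           tumor_type = unname(sample_types[names(widths)]),
                           width = unname(widths), stringsAsFactors = FALSE)
  per_type <- do.call(rbind, lapply(split(per_sample, per_sample$tumor_type),
    function(d) {
      q <- stats::quantile(d$width, c(0.25, 0.5, 0.75), names = FALSE)
      data.frame(tumor_type = d$tumor_type[1], n = nrow(d),
                 median_width = q[2], q1 = q[1], q3 = q[3],
                 stringsAsFactors = FALSE)
    }))
  rownames(per_type) <- NULL
  list(per_sample = per_sample, per_type = per_type,
       discordant = setdiff(lost, per_sample$sample_id))
}

#' Classify samples by BAP1 alteration state
#'
#' Combines the copy-number loss flag and mutation status into one of
#' `Unaltered`, `MutOnly`, `CNOnly`, `CN+Mut`. Mutant samples missing from
#' the CN table are classified `MutOnly` with a warning. The four labels
#' partition the classified cohort.
#'
#' @param loss_calls output of [call_cn_loss()].
#' @param mutant_samples character vector of sample ids with a retained
#'   somatic mutation.
#' @param sample_types optional named tumor-type vector (adds a
#'   `tumor_type` column and per-type totals).
#' @return data.frame `sample_id`, (`tumor_type`,) `label`, `gene_cn`,
#'   `n_mutations`, `altered`; attribute `totals` = per-label counts.
#' @export
classify_alteration <- function(loss_calls, mutant_samples,
                                sample_types = NULL) {
  mut_n <- table(mutant_samples)
  ids <- union(loss_calls$sample_id, unique(mutant_samples))
  cn <- stats::setNames(loss_calls$copy_number, loss_calls$sample_id)
  loss <- stats::setNames(loss_calls$loss, loss_calls$sample_id)
  missing_cn <- setdiff(unique(mutant_samples), loss_calls$sample_id)
  if (length(missing_cn)) {
    warning(sprintf("%d mutant sample(s) missing from CN table; classified MutOnly",
                    length(missing_cn)), call. = FALSE)
  }
  ids <- sort(ids)
  is_mut <- ids %in% names(mut_n)
  is_loss <- unname(!is.na(loss[ids]) & loss[ids])
  label <- ifelse(is_loss & is_mut, "CN+Mut",
                  ifelse(is_loss, "CNOnly",
                         ifelse(is_mut, "MutOnly", "Unaltered")))
  out <- data.frame(sample_id = ids,
                    label = factor(label, levels = c("Unaltered", "MutOnly",
                                                     "CNOnly", "CN+Mut")),
                    gene_cn = unname(cn[ids]),
                    n_mutations = ifelse(is_mut, as.integer(mut_n[ids]), 0L),
                    stringsAsFactors = FALSE)
  out$n_mutations[is.na(out$n_mutations)] <- 0L
  out$altered <- out$label != "Unaltered"
  if (!is.null(sample_types)) {
    out$tumor_type <- unname(sample_types[out$sample_id])
    out <- out[, c("sample_id", "tumor_type", "label", "gene_cn",
                   "n_mutations", "altered")]
  }
  attr(out, "totals") <- table(out$label)
  out
}
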