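# Umbrella pipeline: harmonize -> alteration -> diffexp -> signatures ->
# enrichment -> survival, per tumor type, with a reproducibility manifest.

stage_try <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline halted at stage '%s': %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full BAP1 alteration pipeline
#'
#' Executes variant harmonization, alteration classification, per-type
#' differential expression (with chr3p masking), alteration signature
#' scoring, preranked GSEA, and progression-free survival stratification,
#' writing every stage artifact plus a manifest (inputs, thresholds, seed,
#' package version) to `outdir`. Rerunning with an identical configuration
#' reproduces byte-identical numeric outputs.
#'
#' @param config a [read_run_config()] object, a path to a YAML run config,
#'   or an equivalent list.
#' @param outdir output directory (created if needed).
#' @return Invisibly, a list of the main in-memory results per stage.
#' @export
run_pipeline <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(outdir, f)
  th <- config$thresholds
  log_lines <- character(0)
  note <- function(...) {
    log_lines <<- c(log_lines, sprintf(...))
  }

  # -- inputs ---------------------------------------------------------------
  inputs <- stage_try("read_inputs", {
    list(calls = lapply(unlist(config$calls), read_maf),
         counts = read_counts(config$counts),
         genes = read_tsv(config$genes),
         meta = read_tsv(config$meta),
         gene_cn = read_gene_cn(config$gene_cn),
         segments = read_seg(config$segments),
         clinical = read_clinical(config$clinical),
         sets = read_gmt(config$gmt),
         legacy = if (!is.null(config$legacy)) read_maf(config$legacy))
  })
  sample_types <- stats::setNames(inputs$meta$tumor_type,
                                  inputs$meta$sample_id)

  # -- harmonize ------------------------------------------------------------
  harmonized <- stage_try("harmonize", {
    merged <- merge_callsets(inputs$calls)
    note("harmonize: %d raw calls merged to %d variants",
         sum(vapply(inputs$calls, nrow, 0L)), nrow(merged))
    filt <- apply_quality_filters(merged, vaf_min = th$vaf_min,
                                  alt_min = th$alt_min)
    fu <- attr(filt, "filter_funnel")
    note("harmonize: quality funnel %s",
         paste(names(fu), fu, sep = "=", collapse = ", "))
    norm <- normalize_counts(inputs$counts)
    filt2 <- apply_expression_filter(filt, norm, sample_types,
                                     quantile_cut = th$quantile_cut)
    note("harmonize: %d -> %d variants after expression filter",
         nrow(filt), nrow(filt2))
    review <- attr(filt2, "review_table")
    if (!is.null(review) && nrow(review)) write_tsv(review, p("review_table.tsv"))
    write_maf(filt2, p("harmonized_calls.maf"))
    summ <- summarize_variants(filt2, long_indel_min = th$long_indel_min)
    write_tsv(summ$by_classification, p("variant_classes.tsv"))
    if (!is.null(inputs$legacy)) {
      legacy_f <- apply_quality_filters(inputs$legacy, vaf_min = th$vaf_min,
                                        alt_min = th$alt_min)
      conc <- compare_callsets(filt2, legacy_f)
      write_tsv(conc$assignment, p("concordance.tsv"))
      note("harmonize: concordance new=%d shared=%d legacy=%d",
           conc$n_new_only, conc$n_concordant, conc$n_legacy_only)
    }
    list(variants = filt2, norm = norm, summary = summ)
  })
  mutants <- unique(harmonized$variants$sample_id)

  # -- alteration -----------------------------------------------------------
  alteration <- stage_try("alteration", {
    loss <- call_cn_loss(inputs$gene_cn)
    status <- classify_alteration(loss, mutants, sample_types)
    widths <- segment_width_stats(inputs$segments, loss, sample_types)
    write_tsv(status, p("alteration_status.tsv"))
    write_tsv(widths$per_type, p("segment_widths_by_type.tsv"))
    tot <- attr(status, "totals")
    note("alteration: %s", paste(names(tot), tot, sep = "=", collapse = ", "))
    list(status = status, widths = widths)
  })

  # -- per-type analyses ----------------------------------------------------
  altered_of <- stats::setNames(alteration$status$altered,
                                alteration$status$sample_id)
  types <- sort(unique(inputs$meta$tumor_type))
  per_type <- list()
  for (tt in types) {
    ids <- inputs$meta$sample_id[inputs$meta$tumor_type == tt]
    ids <- intersect(colnames(inputs$counts), ids)
    altered <- altered_of[ids]
    altered[is.na(altered)] <- FALSE
    if (sum(altered) < 3 || sum(!altered) < 3) {
      note("diffexp: type %s skipped (%d altered / %d unaltered)",
           tt, sum(altered), sum(!altered))
      next
    }
    res_t <- stage_try(paste0("diffexp:", tt), {
      cd <- data.frame(altered = unname(altered),
                       purity = inputs$meta$purity[match(ids, inputs$meta$sample_id)])
      covs <- config$covariates$default %||% character(0)
      covs <- intersect(covs, names(cd))
      design <- stats::as.formula(paste(c("~ altered", covs), collapse = " + "))
      # non-BAP1 3p genes are excluded before normalization and testing:
      # arm-level co-loss breaks the compositional assumption of
      # median-of-ratios factors and would shift every gene's Wald statistic
      keep_genes <- inputs$genes$gene[inputs$genes$arm != "3p" |
                                        inputs$genes$gene == "BAP1"]
      cnt_t <- inputs$counts[intersect(rownames(inputs$counts), keep_genes),
                             ids, drop = FALSE]
      de <- fit_nb_wald(cnt_t, cd, design)
      sel <- adjust_and_select(de, inputs$genes, alpha = th$alpha)
      write_tsv(sel, p(sprintf("diffexp_%s.tsv", tt)))
      sel
    })
    sig_t <- stage_try(paste0("signatures:", tt), {
      up <- res_t$gene[res_t$direction == "up"]
      down <- res_t$gene[res_t$direction == "down"]
      norm_t <- harmonized$norm[, ids, drop = FALSE]
      if (length(up) + length(down) >= 2 && length(up) >= 1) {
        sc <- alteration_signature_score(norm_t, up, down)
        write_tsv(sc, p(sprintf("signature_scores_%s.tsv", tt)))
        sc
      } else {
        note("signatures: type %s skipped (no DE genes)", tt)
        NULL
      }
    })
    gsea_t <- stage_try(paste0("enrichment:", tt), {
      stats_v <- stats::setNames(res_t$stat, res_t$gene)
      stats_v <- stats_v[is.finite(stats_v)]
      sets <- inputs$sets[vapply(inputs$sets, function(s)
        length(intersect(s, names(stats_v))) > 0, TRUE)]
      if (length(sets)) {
        g <- gsea_prerank(stats_v, sets, n_perm = config$n_perm,
                          seed = config$seed)
        write_tsv(g, p(sprintf("gsea_%s.tsv", tt)))
        g
      }
    })
    surv_t <- stage_try(paste0("survival:", tt), {
      if (is.null(sig_t)) NULL else {
        cl <- inputs$clinical[inputs$clinical$tumor_type == tt, , drop = FALSE]
        cl <- merge(cl, sig_t[, c("sample_id", "class")], by = "sample_id")
        cl <- prepare_survival(cl)
        if (length(unique(cl$class)) == 2 && sum(cl$PFI) >= 2) {
          cx <- cox_fit(cl, "class")
          lr <- km_logrank(cl$PFI.time, cl$PFI, cl$class)
          out <- data.frame(tumor_type = tt, cx,
                            logrank_p = lr$p, n = attr(cx, "n"),
                            n_event = attr(cx, "n_event"))
          write_tsv(out, p(sprintf("survival_%s.tsv", tt)))
          out
        }
      }
    })
    per_type[[tt]] <- list(de = res_t, signature = sig_t, gsea = gsea_t,
                           survival = surv_t)
  }

  # -- recurrent pathways ---------------------------------------------------
  gsea_all <- Filter(Negate(is.null), lapply(per_type, `[[`, "gsea"))
  recurrent <- NULL
  if (length(gsea_all) >= th$min_types) {
    recurrent <- recurrent_pathway_matrix(gsea_all, min_types = th$min_types,
                                          alpha = th$alpha)
    write_tsv(data.frame(pathway = rownames(recurrent$nes), recurrent$nes,
                         check.names = FALSE), p("recurrent_pathways.tsv"))
  }

  writeLines(log_lines, p("pipeline_log.txt"))
  manifest <- list(
    inputs = lapply(config[c("calls", "counts", "genes", "meta", "gene_cn",
                             "segments", "clinical", "gmt")],
                    function(x) unname(unlist(x))),
    thresholds = th,
    covariates = config$covariates,
    n_perm = config$n_perm,
    seed = config$seed,
    package_version = as.character(utils::packageVersion("bap1sig")))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(harmonized = harmonized, alteration = alteration,
                 per_type = per_type, recurrent = recurrent,
                 outdir = outdir))
}
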