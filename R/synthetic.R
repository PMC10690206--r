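#' Configuration for a synthetic multi-cancer cohort
#'
#' Defines the study conditions emulated by the synthetic generators: cohort
#' layout, per-type alteration mix, negative-binomial expression model,
#' caller behaviour, copy-number segment geometry, and survival hazards.
#' Downstream stages consume the generated tables through the same readers
#' used for real inputs, so schemas match the MAF / gene-CN / SEG / counts /
#' clinical dialects.
#'
#' @param n_types number of tumor types.
#' @param samples_per_type samples per tumor type.
#' @param alteration_fractions named probabilities for `MutOnly`, `CNOnly`
#'   and `CN+Mut` (per sample, within every type); must sum to at most 1.
#' @param n_genes total number of genes (includes `BAP1`).
#' @param n_signature_genes number of truly alteration-responsive genes
#'   (half shifted up, half down in altered samples).
#' @param effect_lfc log2 fold-change magnitude for responsive genes.
#' @param nb_dispersion negative-binomial dispersion `alpha`
#'   (Var = mu + alpha * mu^2), shared across genes.
#' @param purity_range tumor purity interval; purity scales the observed
#'   expression shift (observed LFC = purity x `effect_lfc`) and centers the
#'   simulated VAF at purity/2.
#' @param hazard_ratio_truth multiplicative hazard for truly altered samples.
#' @param n_callers number of simulated variant callers (>= 2).
#' @param p_detect per-caller probability of emitting a true call.
#' @param decoy_rate expected decoy (artifact) calls per sample per caller;
#'   every decoy carries at least one disqualifying feature (non-PASS flag,
#'   VAF < 0.2, or silent/intronic classification).
#' @param indel_fraction fraction of true calls simulated as long indels
#'   (length >= 40bp).
#' @param chr3p_fraction fraction of genes annotated to chromosome arm 3p
#'   (co-lost with BAP1 in CN-altered samples).
#' @param prob_arm probability that a loss segment is arm-level (long)
#'   rather than focal (short).
#' @param cn0_fraction fraction of CN-loss samples at homozygous (CN = 0)
#'   rather than single-copy loss.
#' @param stage_probs probabilities over AJCC stages 0-4.
#' @param flip_directions flip the true DE direction of every responsive
#'   gene (used to emulate a cohort responding in the opposite direction).
#' @param seed integer seed; all generators are fully deterministic given it.
#'
#' @return An object of class `cohort_config`.
#' @export
#' @examples
#' cfg <- cohort_config(n_types = 2, samples_per_type = 50, seed = 1)
#' cfg$alteration_fractions
cohort_config <- function(n_types = 2L,
                          samples_per_type = 200L,
                          alteration_fractions = c(MutOnly = 0.05,
                                                   CNOnly = 0.30,
                                                   `CN+Mut` = 0.05),
                          n_genes = 2000L,
                          n_signature_genes = 100L,
                          effect_lfc = 2,
                          nb_dispersion = 0.1,
                          purity_range = c(0.7, 0.95),
                          hazard_ratio_truth = 3,
                          n_callers = 2L,
                          p_detect = 0.95,
                          decoy_rate = 0.15,
                          indel_fraction = 0.1,
                          chr3p_fraction = 0.05,
                          prob_arm = 0.5,
                          cn0_fraction = 0.008,
                          stage_probs = c(0.1, 0.3, 0.3, 0.2, 0.1),
                          flip_directions = FALSE,
                          seed = 1L) {
  need <- c("MutOnly", "CNOnly", "CN+Mut")
  if (is.null(names(alteration_fractions)) ||
      !setequal(names(alteration_fractions), need)) {
    stop_config("alteration_fractions must be named MutOnly, CNOnly, CN+Mut")
  }
  alteration_fractions <- alteration_fractions[need]
  if (any(alteration_fractions < 0) || sum(alteration_fractions) > 1) {
    stop_config("alteration fractions must be nonnegative and sum to <= 1")
  }
  if (n_types < 1 || samples_per_type < 1 || n_genes < 2 ||
      n_signature_genes < 1) {
    stop_config("all counts must be positive")
  }
  if (n_signature_genes >= n_genes) {
    stop_config("n_signature_genes must be < n_genes")
  }
  if (length(purity_range) != 2 || any(purity_range < 0) ||
      any(purity_range > 1) || purity_range[1] > purity_range[2]) {
    stop_config("purity_range must be an interval within [0, 1]")
  }
  if (nb_dispersion <= 0 || effect_lfc < 0 || hazard_ratio_truth <= 0) {
    stop_config("nb_dispersion and hazard_ratio_truth must be positive; effect_lfc nonnegative")
  }
  if (abs(sum(stage_probs) - 1) > 1e-8 || length(stage_probs) != 5) {
    stop_config("stage_probs must be 5 probabilities summing to 1")
  }
  if (n_callers < 2) stop_config("n_callers must be >= 2")
  structure(list(
    n_types = as.integer(n_types),
    samples_per_type = as.integer(samples_per_type),
    alteration_fractions = alteration_fractions,
    n_genes = as.integer(n_genes),
    n_signature_genes = as.integer(n_signature_genes),
    effect_lfc = effect_lfc,
    nb_dispersion = nb_dispersion,
    purity_range = purity_range,
    hazard_ratio_truth = hazard_ratio_truth,
    n_callers = as.integer(n_callers),
    p_detect = p_detect,
    decoy_rate = decoy_rate,
    indel_fraction = indel_fraction,
    chr3p_fraction = chr3p_fraction,
    prob_arm = prob_arm,
    cn0_fraction = cn0_fraction,
    stage_probs = stage_probs,
    flip_directions = isTRUE(flip_directions),
    seed = as.integer(seed)
  ), class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat(sprintf("Synthetic cohort config: %d type(s) x %d samples, %d genes (%d responsive)\n",
              x$n_types, x$samples_per_type, x$n_genes, x$n_signature_genes))
  cat(sprintf("  alteration fractions: MutOnly %.3f, CNOnly %.3f, CN+Mut %.3f\n",
              x$alteration_fractions["MutOnly"], x$alteration_fractions["CNOnly"],
              x$alteration_fractions["CN+Mut"]))
  cat(sprintf("  effect LFC %.2f, NB dispersion %.3f, HR truth %.2f, seed %d\n",
              x$effect_lfc, x$nb_dispersion, x$hazard_ratio_truth, x$seed))
  invisible(x)
}

#' Generate sample metadata and planted truth for a synthetic cohort
#'
#' Draws one record per sample (tumor type, purity, subtype, alteration
#' label) together with the gene-level truth used by the other generators:
#' gene identifiers, chromosome-arm annotation (a fixed fraction on 3p,
#' including BAP1 itself), and the true DE direction of the responsive genes.
#'
#' @param config a [cohort_config()].
#' @return A list with elements `samples` (data.frame: `sample_id`,
#'   `tumor_type`, `purity`, `subtype`, `alteration`), `genes` (data.frame:
#'   `gene`, `chrom`, `arm`, `is_signature`, `direction`), and `truth`
#'   (per-sample alteration label, signature class, hazard multiplier, and
#'   the seed used).
#' @export
#' @examples
#' ch <- generate_cohort(cohort_config(samples_per_type = 20, n_genes = 50,
#'                                     n_signature_genes = 10, seed = 7))
#' table(ch$samples$alteration)
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed, {
    n <- config$n_types * config$samples_per_type
    types <- sprintf("T%02d", seq_len(config$n_types))
    samples <- data.frame(
      sample_id = sprintf("S%05d", seq_len(n)),
      tumor_type = rep(types, each = config$samples_per_type),
      purity = round(stats::runif(n, config$purity_range[1],
                                  config$purity_range[2]), 4),
      subtype = sample(c("subtypeA", "subtypeB"), n, replace = TRUE),
      stringsAsFactors = FALSE
    )
    fr <- config$alteration_fractions
    labs <- c(names(fr), "Unaltered")
    probs <- c(unname(fr), 1 - sum(fr))
    samples$alteration <- sample(labs, n, replace = TRUE, prob = probs)

    # gene panel: BAP1 first; a fixed fraction on arm 3p; responsive genes
    # live off 3p so the arm mask never removes planted signal
    ng <- config$n_genes
    gene <- c("BAP1", sprintf("G%05d", seq_len(ng - 1)))
    n3p <- max(1L, ceiling(config$chr3p_fraction * ng))
    arm <- rep("other", ng)
    arm[seq_len(n3p)] <- "3p"
    chrom <- ifelse(arm == "3p", "chr3", "chr1")
    is_sig <- rep(FALSE, ng)
    candidates <- which(arm != "3p")
    sig_idx <- candidates[seq_len(config$n_signature_genes)]
    is_sig[sig_idx] <- TRUE
    direction <- integer(ng)
    direction[sig_idx] <- rep_len(c(1L, -1L), length(sig_idx))
    if (config$flip_directions) direction <- -direction
    genes <- data.frame(gene = gene, chrom = chrom, arm = arm,
                        is_signature = is_sig, direction = direction,
                        stringsAsFactors = FALSE)

    altered <- samples$alteration != "Unaltered"
    truth <- list(
      alteration = stats::setNames(samples$alteration, samples$sample_id),
      signature_class = stats::setNames(ifelse(altered, "positive", "negative"),
                                        samples$sample_id),
      hazard_multiplier = stats::setNames(
        ifelse(altered, config$hazard_ratio_truth, 1), samples$sample_id),
      de_direction = stats::setNames(genes$direction, genes$gene),
      seed = config$seed
    )
    list(samples = samples, genes = genes, truth = truth)
  })
}

#' Simulate a gene-by-sample negative-binomial count matrix
#'
#' Counts are drawn from NB(mu, alpha) with `Var = mu + alpha mu^2`.
#' Responsive genes are mean-shifted by `direction * effect_lfc * purity`
#' (log2 scale) in altered samples; BAP1 itself is reduced multiplicatively
#' (x0.5 per lost copy, x0.25 with a mutation); non-BAP1 3p genes are
#' co-reduced x0.5 in CN-altered samples to emulate arm-level co-loss.
#' Per-sample library-size factors are lognormal so size-factor estimation
#' has real signal to recover.
#'
#' @param cohort result of [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return A list with `counts` (integer matrix, genes x samples), `genes`
#'   (gene annotation as in the cohort), and `samples` (sample metadata).
#' @export
simulate_counts <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 1L, {
    genes <- cohort$genes
    smp <- cohort$samples
    ng <- nrow(genes)
    n <- nrow(smp)
    base_mean <- pmax(stats::rlnorm(ng, meanlog = log(150), sdlog = 0.8), 10)
    lib <- stats::rlnorm(n, 0, 0.15)
    altered <- smp$alteration != "Unaltered"
    cn_lost <- smp$alteration %in% c("CNOnly", "CN+Mut")
    mutant <- smp$alteration %in% c("MutOnly", "CN+Mut")

    shift <- matrix(0, ng, n)  # log2 shifts
    if (any(altered)) {
      sig <- which(genes$is_signature)
      shift[sig, altered] <- outer(genes$direction[sig] * config$effect_lfc,
                                   smp$purity[altered])
    }
    co3p <- which(genes$arm == "3p" & genes$gene != "BAP1")
    shift[co3p, cn_lost] <- shift[co3p, cn_lost] - 1  # one lost copy
    b <- which(genes$gene == "BAP1")
    shift[b, cn_lost] <- shift[b, cn_lost] - 1
    shift[b, mutant] <- shift[b, mutant] - 2           # x0.25

    mu <- (base_mean * 2^shift) * rep(lib, each = ng)
    counts <- matrix(stats::rnbinom(ng * n, mu = mu,
                                    size = 1 / config$nb_dispersion),
                     ng, n, dimnames = list(genes$gene, smp$sample_id))
    list(counts = counts, genes = genes, samples = smp)
  })
}

maf_columns <- function() {
  c("sample_id", "tumor_type", "chrom", "pos", "ref", "alt",
    "variant_classification", "t_alt_count", "t_depth", "vaf",
    "filter_flag", "callers")
}

new_variant_table <- function() {
  df <- data.frame(sample_id = character(), tumor_type = character(),
                   chrom = character(), pos = integer(), ref = character(),
                   alt = character(), variant_classification = character(),
                   t_alt_count = integer(), t_depth = integer(),
                   vaf = numeric(), filter_flag = character(),
                   callers = character(), stringsAsFactors = FALSE)
  df
}

#' Simulate per-caller somatic variant call tables
#'
#' Every truly mutant sample carries one true BAP1 variant; each of the
#' simulated callers emits it independently with probability `p_detect`.
#' True VAFs follow a truncated normal centered at purity/2 (clonal
#' heterozygous model); `t_alt_count` is binomial given depth and VAF.
#' A configurable fraction of true calls are long indels (>= 40bp).
#' Decoy artifact calls are injected at `decoy_rate` per sample per caller,
#' each failing at least one downstream filter (non-PASS flag, VAF below
#' 0.2, or silent/intronic classification).
#'
#' @param cohort result of [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return A named list of MAF-dialect data frames, one per caller.
#' @export
simulate_variant_calls <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 2L, {
    smp <- cohort$samples
    locus <- bap1_locus()
    mutant <- smp$alteration %in% c("MutOnly", "CN+Mut")
    nm <- sum(mutant)
    classes <- c("Nonsense_Mutation", "Frame_Shift_Del", "Frame_Shift_Ins",
                 "Missense_Mutation", "Splice_Site", "In_Frame_Del")
    class_p <- c(0.30, 0.12, 0.08, 0.28, 0.12, 0.10)
    bases <- c("A", "C", "G", "T")

    true_calls <- NULL
    if (nm > 0) {
      idx <- which(mutant)
      pos <- sample(seq(locus$start, locus$end), nm, replace = TRUE)
      is_indel <- stats::runif(nm) < config$indel_fraction
      cls <- sample(classes, nm, replace = TRUE, prob = class_p)
      cls[is_indel] <- sample(c("Frame_Shift_Del", "In_Frame_Del"), sum(is_indel),
                              replace = TRUE, prob = c(0.7, 0.3))
      ref <- character(nm); alt <- character(nm)
      for (i in seq_len(nm)) {
        if (is_indel[i]) {
          len <- sample(40:80, 1)
          ref[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
          alt[i] <- "-"
        } else if (cls[i] %in% c("Frame_Shift_Del", "In_Frame_Del")) {
          len <- sample(1:5, 1)
          ref[i] <- paste(sample(bases, len, replace = TRUE), collapse = "")
          alt[i] <- "-"
        } else {
          ref[i] <- sample(bases, 1)
          alt[i] <- sample(setdiff(bases, ref[i]), 1)
        }
      }
      vaf_true <- rtruncnorm(nm, mean = smp$purity[idx] * 0.5, sd = 0.05,
                             lower = 0.05, upper = 0.95)
      true_calls <- data.frame(sidx = idx, pos = pos, ref = ref, alt = alt,
                               variant_classification = cls, vaf = vaf_true,
                               stringsAsFactors = FALSE)
    }

    out <- vector("list", config$n_callers)
    names(out) <- sprintf("caller%d", seq_len(config$n_callers))
    for (k in seq_len(config$n_callers)) {
      tab <- new_variant_table()
      if (!is.null(true_calls) && nrow(true_calls)) {
        emit <- stats::runif(nrow(true_calls)) < config$p_detect
        tc <- true_calls[emit, , drop = FALSE]
        if (nrow(tc)) {
          depth <- sample(60:120, nrow(tc), replace = TRUE)
          altn <- pmax(1L, stats::rbinom(nrow(tc), depth, tc$vaf))
          tab <- rbind(tab, data.frame(
            sample_id = smp$sample_id[tc$sidx],
            tumor_type = smp$tumor_type[tc$sidx],
            chrom = locus$chrom, pos = tc$pos, ref = tc$ref, alt = tc$alt,
            variant_classification = tc$variant_classification,
            t_alt_count = altn, t_depth = depth, vaf = altn / depth,
            filter_flag = "PASS", callers = names(out)[k],
            stringsAsFactors = FALSE))
        }
      }
      n_decoy <- stats::rpois(1, config$decoy_rate * nrow(smp))
      if (n_decoy > 0) {
        didx <- sample(nrow(smp), n_decoy, replace = TRUE)
        mode <- sample(c("flag", "lowvaf", "class"), n_decoy, replace = TRUE)
        depth <- sample(60:120, n_decoy, replace = TRUE)
        vaf <- ifelse(mode == "lowvaf", stats::runif(n_decoy, 0.02, 0.15),
                      stats::runif(n_decoy, 0.25, 0.6))
        altn <- pmax(1L, round(depth * vaf))
        ref <- sample(bases, n_decoy, replace = TRUE)
        alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1), "")
        tab <- rbind(tab, data.frame(
          sample_id = smp$sample_id[didx],
          tumor_type = smp$tumor_type[didx],
          chrom = locus$chrom,
          pos = sample(seq(locus$start, locus$end), n_decoy, replace = TRUE),
          ref = ref, alt = unname(alt),
          variant_classification = ifelse(mode == "class",
                                          sample(c("Silent", "Intron"), n_decoy, replace = TRUE),
                                          "Missense_Mutation"),
          t_alt_count = altn, t_depth = depth, vaf = altn / depth,
          filter_flag = ifelse(mode == "flag", "artifact", "PASS"),
          callers = names(out)[k], stringsAsFactors = FALSE))
      }
      tab <- tab[order(tab$sample_id, tab$pos), , drop = FALSE]
      rownames(tab) <- NULL
      out[[k]] <- tab
    }
    out
  })
}

# mixture CDF of loss-segment widths; used both to draw widths and as the
# analytic reference for the per-type median in tests
segment_width_mixture <- function(config) {
  focal <- list(meanlog = log(8e6), sdlog = 0.5)
  arm <- list(min = 6e7, max = 8.8e7)
  list(
    prob_arm = config$prob_arm,
    focal = focal, arm = arm,
    rdraw = function(n) {
      is_arm <- stats::runif(n) < config$prob_arm
      w <- numeric(n)
      w[!is_arm] <- stats::rlnorm(sum(!is_arm), focal$meanlog, focal$sdlog)
      w[is_arm] <- stats::runif(sum(is_arm), arm$min, arm$max)
      round(w)
    },
    cdf = function(q) {
      (1 - config$prob_arm) * stats::plnorm(q, focal$meanlog, focal$sdlog) +
        config$prob_arm * stats::punif(q, arm$min, arm$max)
    }
  )
}

#' Simulate gene-level copy number and masked loss segments
#'
#' CN-altered samples (`CNOnly`, `CN+Mut`) receive BAP1 copy number 1 (a
#' small configured fraction at 0) and one loss segment covering the BAP1
#' locus whose width is drawn from a focal/arm-level mixture; all other
#' samples get copy number 2 and no overlapping loss segment.
#'
#' @param cohort result of [generate_cohort()].
#' @param config the same [cohort_config()].
#' @return A list with `gene_cn` (data.frame: `sample_id`, `gene`,
#'   `copy_number`) and `segments` (SEG-dialect data.frame: `sample_id`,
#'   `chrom`, `start`, `end`, `copy_number`).
#' @export
simulate_segments_and_cn <- function(cohort, config) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 3L, {
    smp <- cohort$samples
    locus <- bap1_locus()
    locus_width <- locus$end - locus$start + 1
    cn_lost <- smp$alteration %in% c("CNOnly", "CN+Mut")
    cn <- ifelse(cn_lost, 1L, 2L)
    if (any(cn_lost)) {
      hom <- cn_lost & stats::runif(nrow(smp)) < config$cn0_fraction
      cn[hom] <- 0L
    }
    gene_cn <- data.frame(sample_id = smp$sample_id, gene = "BAP1",
                          copy_number = cn, stringsAsFactors = FALSE)
    # two neutral control genes so the reader sees a multi-gene table
    for (g in c("PBRM1", "SETD2")) {
      gene_cn <- rbind(gene_cn, data.frame(sample_id = smp$sample_id,
                                           gene = g, copy_number = 2L,
                                           stringsAsFactors = FALSE))
    }

    mix <- segment_width_mixture(config)
    idx <- which(cn_lost)
    segs <- NULL
    if (length(idx)) {
      width <- pmax(mix$rdraw(length(idx)), locus_width)
      u <- stats::runif(length(idx))
      start <- pmax(1, round(locus$start - u * (width - locus_width)))
      end <- start + width - 1
      over <- end > 9.0e7  # keep segments on the 3p arm
      start[over] <- pmax(1, 9.0e7 - width[over] + 1)
      end[over] <- start[over] + width[over] - 1
      segs <- data.frame(sample_id = smp$sample_id[idx], chrom = locus$chrom,
                         start = as.integer(start), end = as.integer(end),
                         copy_number = cn[idx], stringsAsFactors = FALSE)
    } else {
      segs <- data.frame(sample_id = character(), chrom = character(),
                         start = integer(), end = integer(),
                         copy_number = integer(), stringsAsFactors = FALSE)
    }
    # neutral background segment per sample (CN = 2, away from the locus)
    neutral <- data.frame(sample_id = smp$sample_id, chrom = locus$chrom,
                          start = 95000000L, end = 180000000L,
                          copy_number = 2L, stringsAsFactors = FALSE)
    segments <- rbind(segs, neutral)
    segments <- segments[order(segments$sample_id, segments$start), ]
    rownames(segments) <- NULL
    list(gene_cn = gene_cn, segments = segments)
  })
}

#' Simulate progression-free-interval survival records
#'
#' Event times are exponential with a baseline rate multiplied by the true
#' hazard ratio for signature-positive (altered) samples; censoring times
#' are uniform and independent; the censoring time is recorded as the
#' follow-up time. AJCC-style stage labels (with roman-numeral substages)
#' are drawn from the configured stage distribution.
#'
#' @param cohort result of [generate_cohort()].
#' @param config the same [cohort_config()].
#' @param baseline_median median event time (days) for hazard-1 samples.
#' @return A clinical data.frame: `sample_id`, `tumor_type`, `PFI.time`,
#'   `PFI` (event 0/1), `stage`, `subtype`, `last_followup`.
#' @export
simulate_survival <- function(cohort, config, baseline_median = 1500) {
  stopifnot(inherits(config, "cohort_config"))
  with_seed(config$seed + 4L, {
    smp <- cohort$samples
    n <- nrow(smp)
    hr <- unname(cohort$truth$hazard_multiplier[smp$sample_id])
    rate <- log(2) / baseline_median * hr
    event_t <- stats::rexp(n, rate)
    cens_t <- stats::runif(n, 365, 3650)
    time <- pmin(event_t, cens_t)
    event <- as.integer(event_t <= cens_t)
    stage_num <- sample(0:4, n, replace = TRUE, prob = config$stage_probs)
    roman <- c("0", "I", "II", "III", "IV")
    sub <- ifelse(stage_num == 0, "",
                  sample(c("", "A", "B"), n, replace = TRUE))
    stage <- paste0("Stage ", roman[stage_num + 1], sub)
    data.frame(sample_id = smp$sample_id, tumor_type = smp$tumor_type,
               PFI.time = round(time, 1), PFI = event, stage = stage,
               subtype = smp$subtype, last_followup = round(cens_t, 1),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a complete synthetic cohort
#'
#' Runs all five generators and returns every table the pipeline consumes,
#' plus the planted truth. Deterministic given `config$seed`.
#'
#' @param config a [cohort_config()].
#' @return A list: `config`, `samples`, `genes`, `truth`, `counts`,
#'   `calls` (per-caller MAF tables), `gene_cn`, `segments`, `clinical`.
#' @export
#' @examples
#' sim <- simulate_bap1_cohort(cohort_config(samples_per_type = 30,
#'   n_genes = 100, n_signature_genes = 20, seed = 3))
#' dim(sim$counts)
simulate_bap1_cohort <- function(config) {
  cohort <- generate_cohort(config)
  expr <- simulate_counts(cohort, config)
  calls <- simulate_variant_calls(cohort, config)
  cnseg <- simulate_segments_and_cn(cohort, config)
  clinical <- simulate_survival(cohort, config)
  list(config = config, samples = cohort$samples, genes = cohort$genes,
       truth = cohort$truth, counts = expr$counts, calls = calls,
       gene_cn = cnseg$gene_cn, segments = cnseg$segments,
       clinical = clinical)
}

#' Write a simulated cohort to disk in the pipeline's file dialects
#'
#' Emits one MAF-dialect TSV per caller, a counts TSV, gene annotation TSV,
#' sample metadata TSV, gene-CN TSV, SEG TSV, clinical TSV, truth TSV, a
#' small GMT of the planted up/down sets plus random sets, and a YAML run
#' configuration pointing at all of them — so [run_pipeline()] can consume
#' the directory directly.
#'
#' @param sim result of [simulate_bap1_cohort()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the path to the written run config YAML.
#' @export
write_cohort <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  call_paths <- character(0)
  for (nm in names(sim$calls)) {
    cp <- p(paste0(nm, ".maf"))
    write_maf(sim$calls[[nm]], cp)
    call_paths <- c(call_paths, cp)
  }
  counts_df <- data.frame(gene = rownames(sim$counts), sim$counts,
                          check.names = FALSE, stringsAsFactors = FALSE)
  write_tsv(counts_df, p("counts.tsv"))
  write_tsv(sim$genes, p("genes.tsv"))
  write_tsv(sim$samples, p("meta.tsv"))
  write_tsv(sim$gene_cn, p("gene_cn.tsv"))
  write_tsv(sim$segments, p("segments.seg"))
  write_tsv(sim$clinical, p("clinical.tsv"))
  truth_df <- data.frame(sample_id = names(sim$truth$alteration),
                         alteration = unname(sim$truth$alteration),
                         signature_class = unname(sim$truth$signature_class),
                         hazard_multiplier = unname(sim$truth$hazard_multiplier),
                         stringsAsFactors = FALSE)
  write_tsv(truth_df, p("truth.tsv"))

  up <- sim$genes$gene[sim$genes$is_signature & sim$genes$direction > 0]
  down <- sim$genes$gene[sim$genes$is_signature & sim$genes$direction < 0]
  other <- setdiff(sim$genes$gene, c(up, down, "BAP1"))
  rnd <- with_seed(sim$config$seed + 5L, {
    lapply(1:3, function(i) sample(other, min(25, length(other))))
  })
  sets <- c(list(TRUE_UP = up, TRUE_DOWN = down),
            stats::setNames(rnd, paste0("RANDOM_", 1:3)))
  write_gmt(sets, p("sets.gmt"))

  cfg <- list(
    calls = as.list(call_paths),
    counts = p("counts.tsv"), genes = p("genes.tsv"), meta = p("meta.tsv"),
    gene_cn = p("gene_cn.tsv"), segments = p("segments.seg"),
    clinical = p("clinical.tsv"), gmt = p("sets.gmt"),
    thresholds = list(vaf_min = 0.2, alt_min = 2, long_indel_min = 40,
                      alpha = 0.05, quantile_cut = 0.5, min_types = 5),
    covariates = list(default = "purity"),
    n_perm = 500,
    seed = sim$config$seed
  )
  yaml::write_yaml(cfg, p("run_config.yaml"))
  invisible(p("run_config.yaml"))
}
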