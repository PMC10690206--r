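# Readers/writers for the pipeline's file dialects (MAF-like TSV, gene-CN
# TSV, SEG TSV, counts TSV, GMT, clinical TSV, YAML run config).
# Coordinates are 1-based inclusive throughout (MAF/SEG convention).

maf_required_cols <- function() {
  c("Tumor_Sample_Barcode", "Chromosome", "Start_Position",
    "Reference_Allele", "Tumor_Seq_Allele2", "Variant_Classification",
    "t_depth", "t_alt_count", "FILTER")
}

#' Read a MAF-dialect variant table
#'
#' Tolerant to column order and extra columns (extras are preserved).
#' Required columns are validated by name; 1-based coordinates are kept
#' as-is. The MAF header names are mapped onto the internal variant
#' schema (`sample_id`, `chrom`, `pos`, `ref`, `alt`,
#' `variant_classification`, `t_depth`, `t_alt_count`, `filter_flag`,
#' `callers`, `tumor_type`), and `vaf`/`indel_length` are recomputed.
#'
#' @param path TSV file path.
#' @return Variant data.frame.
#' @export
read_maf <- function(path) {
  df <- read_tsv(path)
  miss <- setdiff(maf_required_cols(), names(df))
  if (length(miss)) {
    stop(sprintf("MAF file %s is missing required column(s): %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  map <- c(Tumor_Sample_Barcode = "sample_id", Chromosome = "chrom",
           Start_Position = "pos", Reference_Allele = "ref",
           Tumor_Seq_Allele2 = "alt", FILTER = "filter_flag")
  for (nm in names(map)) names(df)[names(df) == nm] <- map[[nm]]
  names(df)[names(df) == "Variant_Classification"] <- "variant_classification"
  if (!"callers" %in% names(df)) df$callers <- "unknown"
  if (!"tumor_type" %in% names(df)) df$tumor_type <- NA_character_
  df$pos <- as.integer(df$pos)
  df$t_depth <- as.integer(df$t_depth)
  df$t_alt_count <- as.integer(df$t_alt_count)
  if (any(df$t_alt_count > df$t_depth, na.rm = TRUE)) {
    stop("t_alt_count exceeds t_depth in input", call. = FALSE)
  }
  df$vaf <- df$t_alt_count / df$t_depth
  df$indel_length <- compute_indel_length(df$ref, df$alt)
  front <- c(maf_columns(), "indel_length")
  df[, c(front, setdiff(names(df), front)), drop = FALSE]
}

#' Write a variant table as MAF-dialect TSV
#'
#' @param variants internal-schema variant data.frame.
#' @param path output TSV path.
#' @param gene value for the `Hugo_Symbol` column (default `"BAP1"`).
#' @return Invisibly, `path`.
#' @export
write_maf <- function(variants, path, gene = "BAP1") {
  out <- data.frame(
    Hugo_Symbol = gene,
    Tumor_Sample_Barcode = variants$sample_id,
    Chromosome = variants$chrom,
    Start_Position = variants$pos,
    Reference_Allele = variants$ref,
    Tumor_Seq_Allele2 = variants$alt,
    Variant_Classification = variants$variant_classification,
    t_depth = variants$t_depth,
    t_alt_count = variants$t_alt_count,
    FILTER = variants$filter_flag,
    callers = variants$callers,
    tumor_type = variants$tumor_type,
    stringsAsFactors = FALSE)
  write_tsv(out, path)
}

#' Read gene sets from a GMT file
#'
#' Tab-separated, one set per line: name, description (ignored), member
#' genes. Duplicate genes within a line are dropped with a warning.
#'
#' @param path GMT file path.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(list())
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      stop(sprintf("GMT line %d has fewer than 3 fields", i), call. = FALSE)
    }
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': duplicate gene(s) dropped", f[1]),
              call. = FALSE)
      genes <- unique(genes)
    }
    sets[[f[1]]] <- genes
  }
  sets
}

#' Write gene sets to a GMT file
#' @param sets named list of character vectors.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    paste(c(nm, "na", sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-level copy-number TSV
#' @param path TSV with `sample_id`, `gene`, `copy_number`.
#' @return data.frame.
#' @export
read_gene_cn <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("sample_id", "gene", "copy_number"), path)
  df$copy_number <- as.integer(df$copy_number)
  df
}

#' Read a SEG-dialect segment TSV
#' @param path TSV with `sample_id`, `chrom`, `start`, `end`, `copy_number`.
#' @return data.frame (1-based inclusive coordinates).
#' @export
read_seg <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("sample_id", "chrom", "start", "end", "copy_number"), path)
  df$start <- as.integer(df$start)
  df$end <- as.integer(df$end)
  df
}

#' Read a gene-by-sample counts TSV
#' @param path TSV whose first column `gene` holds gene ids.
#' @return Integer matrix with gene rownames.
#' @export
read_counts <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, "gene", path)
  m <- as.matrix(df[, setdiff(names(df), "gene"), drop = FALSE])
  rownames(m) <- df$gene
  storage.mode(m) <- "integer"
  m
}

#' Read a clinical TSV
#' @param path TSV with `sample_id`, `PFI.time`, `PFI`, `stage`, `subtype`,
#'   `last_followup`.
#' @return data.frame.
#' @export
read_clinical <- function(path) {
  df <- read_tsv(path)
  assert_cols(df, c("sample_id", "PFI.time", "PFI", "stage", "last_followup"),
              path)
  df
}

#' Read and validate a YAML run configuration
#'
#' Checks that every referenced input path resolves and that thresholds
#' are within their documented ranges.
#'
#' @param path YAML file.
#' @return Named list (class `bap1_run_config`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- c(unlist(cfg$calls), cfg$counts, cfg$genes, cfg$meta, cfg$gene_cn,
             cfg$segments, cfg$clinical, cfg$gmt, cfg$legacy)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop(sprintf("run config references missing file(s): %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  th <- cfg$thresholds %||% list()
  th$vaf_min <- th$vaf_min %||% 0.2
  th$alt_min <- th$alt_min %||% 2
  th$long_indel_min <- th$long_indel_min %||% 40
  th$alpha <- th$alpha %||% 0.05
  th$quantile_cut <- th$quantile_cut %||% 0.5
  th$min_types <- th$min_types %||% 5
  if (th$vaf_min < 0 || th$vaf_min > 1 || th$quantile_cut < 0 ||
      th$quantile_cut > 1 || th$alpha <= 0 || th$alpha >= 1) {
    stop_config("run config thresholds out of range")
  }
  cfg$thresholds <- th
  cfg$n_perm <- cfg$n_perm %||% 1000
  cfg$seed <- cfg$seed %||% 1
  class(cfg) <- c("bap1_run_config", "list")
  cfg
}
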