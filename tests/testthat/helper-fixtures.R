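# Shared fixtures: small cohort configs and toy variant tables built in code.

small_config <- function(seed = 101, ...) {
  args <- list(n_types = 2, samples_per_type = 40, n_genes = 200,
               n_signature_genes = 30, seed = seed)
  override <- list(...)
  args[names(override)] <- override
  do.call(cohort_config, args)
}

# a minimal variant row in the internal schema
toy_variant <- function(sample_id = "s1", chrom = "chr3", pos = 52400000L,
                        ref = "A", alt = "T",
                        classification = "Missense_Mutation",
                        t_alt_count = 30L, t_depth = 100L,
                        filter_flag = "PASS", caller = "callerA",
                        tumor_type = "T01") {
  data.frame(sample_id = sample_id, tumor_type = tumor_type, chrom = chrom,
             pos = as.integer(pos), ref = ref, alt = alt,
             variant_classification = classification,
             t_alt_count = as.integer(t_alt_count),
             t_depth = as.integer(t_depth),
             vaf = t_alt_count / t_depth, filter_flag = filter_flag,
             callers = caller, stringsAsFactors = FALSE)
}

toy_variants <- function(...) do.call(rbind, list(...))

# independent O(N) running-sum enrichment score (loop form), used as the
# oracle against the package's position-based implementation; shares the
# documented tie rule (positive extremum wins magnitude ties to 1e-9)
es_bruteforce <- function(stats, set, p = 1) {
  hit <- names(stats) %in% set
  N <- length(stats)
  w <- abs(stats)^p
  Wh <- sum(w[hit])
  if (Wh == 0) {
    w[] <- 1
    Wh <- sum(w[hit])
  }
  n_miss <- N - sum(hit)
  if (n_miss == 0) return(1)
  run <- 0
  run_max <- -Inf
  run_min <- Inf
  for (i in seq_len(N)) {
    run <- run + if (hit[i]) unname(w[i]) / Wh else -1 / n_miss
    if (run > run_max) run_max <- run
    if (run < run_min) run_min <- run
  }
  if (abs(run_max) >= abs(min(run_min, 0)) - 1e-9) run_max else run_min
}
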