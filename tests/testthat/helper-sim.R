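# Small shared simulation fixture: ~40 study animals, 300 SNPs on a 30-Mb
# chromosome, 2 planted phenocopies. Built once per test run.
small_sim_cfg <- function(seed = 7, ...) {
  args <- utils::modifyList(list(
    n_founders = 30, n_generations = 4, n_snps = 300, n_bg_snps = 500,
    chrom_length_bp = 30e6, disease_bp = 14.5e6,
    study_composition = c(affected = 10, carrier = 8, free = 20),
    phenocopy_count = 2, missing_rate = 0.01, seed = seed), list(...))
  do.call(sim_config, args)
}

.sim_cache <- new.env(parent = emptyenv())
small_sim <- function(seed = 7) {
  key <- paste0("s", seed)
  if (is.null(.sim_cache[[key]]))
    .sim_cache[[key]] <- simulate_population(small_sim_cfg(seed))
  .sim_cache[[key]]
}

# genotypes/map restricted to QC-passed SNPs, plus encoded phenotypes
small_sim_prepared <- function(seed = 7) {
  key <- paste0("p", seed)
  if (is.null(.sim_cache[[key]])) {
    sim <- small_sim(seed)
    geno <- geno_from_panel(sim$haplotypes)
    qc <- suppressWarnings(filter_snps(geno, sim$map, sim$pedigree,
                                       sim$cfg$chrom))
    keep <- match(qc$kept_snps, sim$map$snp)
    panel <- impute_panel(sim$haplotypes)
    panel$alleles <- panel$alleles[, keep, drop = FALSE]
    .sim_cache[[key]] <- list(
      sim = sim, qc = qc, keep = keep, panel = panel,
      geno = geno[, keep, drop = FALSE],
      map = sim$map[keep, , drop = FALSE],
      y = encode_phenotypes(sim$status_records))
  }
  .sim_cache[[key]]
}
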