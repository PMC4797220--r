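#' Run the full mapping analysis on one simulated dataset and score it
#'
#' Convenience wrapper used to evaluate the method against the simulator's
#' exact truth: simulates a population, applies SNP QC to the raw (masked)
#' genotypes, derives genome-wide UAR principal components (count chosen by
#' Horn's parallel analysis), runs the REML likelihood-ratio scan over the
#' target chromosome on the phased haplotypes, determines 2-LOD support
#' intervals, applies the carrier-concordance filter to the simulated variant
#' table over the true shared-haplotype interval, and ranks phenocopy
#' candidates from the case-control homozygosity diagnostics.
#'
#' @param seed Integer seed for the simulation.
#' @param sim_overrides Named list of [sim_config()] overrides.
#' @param n_perm Permutations for [horn_retain()].
#' @param alpha_total Total type-I error for the scan threshold.
#' @param params [ibd_params()] for the locus-IBD estimator.
#' @return List with the simulation truth and per-stage outcomes:
#'   `peak_bp`, `peak_lrt`, `truth_interval`, `peak_in_truth`, `ci`
#'   (primary support interval row or `NULL`), `ci_covers_disease`,
#'   `concordant_ids`, `concordance_exact`, `phenocopy_ids`, `flagged_ids`,
#'   `phenocopies_flagged`, `n_windows`, `k_pcs`, `scan`.
#' @export
evaluate_simulation <- function(seed, sim_overrides = list(), n_perm = 30L,
                                alpha_total = 0.001, params = ibd_params()) {
  cfg <- do.call(sim_config, utils::modifyList(list(seed = as.integer(seed)),
                                               sim_overrides))
  sim <- simulate_population(cfg)
  geno_raw <- geno_from_panel(sim$haplotypes)
  qc <- suppressWarnings(filter_snps(geno_raw, sim$map, sim$pedigree,
                                     cfg$chrom))
  keep <- match(qc$kept_snps, sim$map$snp)
  off <- match(qc$dropped$snp_id[qc$dropped$reason == "off_target_chrom"],
               sim$map$snp)
  rel_idx <- sort(c(keep, off))
  panel <- sim$true_haplotypes
  panel$alleles <- panel$alleles[, keep, drop = FALSE]
  map_k <- sim$map[keep, , drop = FALSE]
  geno <- geno_from_panel(sim$true_haplotypes)

  y <- encode_phenotypes(sim$status_records)
  k <- horn_retain(geno_raw[, rel_idx, drop = FALSE], n_perm = n_perm,
                   seed = as.integer(seed) + 1L)
  X <- matrix(1, length(y), 1L)
  if (k > 0)
    X <- cbind(X, uar_pca(uar_matrix(geno_raw[, rel_idx, drop = FALSE]))$
                 components[, seq_len(k), drop = FALSE])

  scan <- lrt_scan(panel, map_k, y, X, params)
  pk <- which.max(scan$lrt)
  ti <- sim$truth_interval
  dis <- cfg$disease_bp
  thr <- significance_threshold(alpha_total, nrow(scan))
  ci <- lod_ci(scan, thr)

  vt <- sim$variant_table
  carriers <- sim$truth$animal[sim$truth$copies == 1L]
  conc <- concordance_filter(vt, carriers, region = ti)

  st <- sim$status_records
  case_ids <- st$animal_id[st$diagnosis %in% c("affected_path",
                                               "affected_clinical")]
  ctrl_ids <- st$animal_id[st$diagnosis == "free"]
  ph <- sim$truth$animal[sim$truth$is_phenocopy]
  flagged <- drop_incompatible_cases(geno[case_ids, keep, drop = FALSE],
                                     geno[ctrl_ids, keep, drop = FALSE],
                                     map_k, k = max(length(ph), 1L))

  list(seed = seed, peak_bp = scan$midpoint_bp[pk],
       peak_lrt = max(scan$lrt, na.rm = TRUE),
       truth_interval = ti,
       peak_in_truth = ti[1] <= scan$midpoint_bp[pk] &&
         scan$midpoint_bp[pk] <= ti[2],
       ci = if (nrow(ci)) ci[1L, ] else NULL,
       ci_covers_disease = nrow(ci) > 0 && ci$lower_bp[1L] <= dis &&
         dis <= ci$upper_bp[1L],
       concordant_ids = conc$kept$id,
       concordance_exact = identical(conc$kept$id, "var_causal"),
       phenocopy_ids = ph, flagged_ids = flagged$animal_id,
       phenocopies_flagged = setequal(flagged$animal_id, ph),
       n_windows = nrow(scan), k_pcs = k, scan = scan)
}
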