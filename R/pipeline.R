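#' Pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Any field can also be
#' supplied through a YAML file (see `path`); explicit arguments override
#' file keys.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Integer seed for every stochastic stage.
#' @param sim Named list of [sim_config()] overrides.
#' @param target_chrom Chromosome retained by QC; defaults to the simulated
#'   chromosome.
#' @param max_missing,max_conflict_rate,min_het,min_call_rate QC thresholds,
#'   see [filter_snps()].
#' @param Ne,T Locus-IBD prior parameters, see [ibd_params()].
#' @param window_size,step Scan window geometry in SNPs.
#' @param alpha_total Total type-I error for the Bonferroni threshold.
#' @param drop_lod LOD drop for support intervals.
#' @param n_pcs Number of UAR principal components used as fixed covariates;
#'   `NULL` lets [horn_retain()] decide.
#' @param n_perm Permutations for [horn_retain()].
#' @param k_exclusions Budget for [drop_incompatible_cases()].
#' @param path Optional YAML file with any of the above keys.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir = "cldla_out", seed = 1L, sim = list(),
                            target_chrom = NULL, max_missing = 0.05,
                            max_conflict_rate = 0.01, min_het = 0.05,
                            min_call_rate = 0.95, Ne = 100, T = 10,
                            window_size = 40L, step = 1L, alpha_total = 0.001,
                            drop_lod = 2, n_pcs = NULL, n_perm = 50L,
                            k_exclusions = 3L, path = NULL) {
  cfg <- as.list(environment())
  cfg$path <- NULL
  if (!is.null(path)) {
    file_cfg <- yaml::read_yaml(path)
    unknown <- setdiff(names(file_cfg), names(cfg))
    if (length(unknown))
      stop("unknown configuration key(s): ", paste(unknown, collapse = ", "))
    given <- names(as.list(match.call()))
    for (k in setdiff(names(file_cfg), given)) cfg[[k]] <- file_cfg[[k]]
  }
  stopifnot(cfg$alpha_total > 0, cfg$alpha_total < 1, cfg$drop_lod > 0,
            cfg$window_size >= 2L, cfg$step >= 1L,
            cfg$max_missing >= 0, cfg$min_het >= 0)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full mapping pipeline on simulated data
#'
#' Executes, in order: simulation, SNP quality control, relationship matrix
#' and principal components, the REML likelihood-ratio scan, support
#' intervals, homozygosity mapping with phenocopy diagnostics, common
#' haplotype extraction, carrier-concordance variant filtering, and
#' allele-frequency monitoring. All tabular outputs are written as TSV under
#' `out_dir` (support intervals additionally as 0-based half-open BED) and a
#' JSON manifest records the seed, per-stage runtimes, outputs and their
#' checksums.
#'
#' The common-haplotype stage uses pathologically confirmed cases only, and
#' the concordance region is the common-haplotype interval, mirroring the
#' two-stage logic of homozygosity mapping followed by variant filtering.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(seed = config$seed, stages = list())
  outputs <- character(0)
  t_stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    val <- tryCatch(force(expr), error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    manifest$stages[[name]] <<- list(runtime_s = round(proc.time()[["elapsed"]] - t0, 3))
    val
  }
  reg <- function(...) outputs <<- c(outputs, ...)
  fp <- function(...) file.path(config$out_dir, ...)

  # 1. simulate
  sim <- t_stage("simulate", {
    sc <- do.call(sim_config, utils::modifyList(list(seed = config$seed),
                                                config$sim))
    simulate_population(sc)
  })
  write_plink(sim$haplotypes, sim$map, fp("genotypes"), sim$pedigree)
  write_tsv(sim$pedigree, fp("pedigree.tsv"))
  write_tsv(sim$status_records, fp("status.tsv"))
  write_variant_vcf(sim$variant_table, fp("variants.vcf"))
  reg("genotypes.ped", "genotypes.map", "pedigree.tsv", "status.tsv",
      "variants.vcf")

  # 2. qc
  target_chrom <- if (is.null(config$target_chrom)) sim$cfg$chrom else
    config$target_chrom
  geno <- geno_from_panel(sim$haplotypes)
  qc <- t_stage("qc", suppressWarnings(
    filter_snps(geno, sim$map, sim$pedigree, target_chrom,
                max_missing = config$max_missing,
                max_conflict_rate = config$max_conflict_rate,
                min_het = config$min_het,
                min_call_rate = config$min_call_rate)))
  write_tsv(qc$dropped, fp("qc_dropped.tsv"))
  jsonlite::write_json(list(n_kept = length(qc$kept_snps),
                            n_dropped = nrow(qc$dropped),
                            n_flagged_animals = nrow(qc$flagged_animals)),
                       fp("qc_summary.json"), auto_unbox = TRUE)
  reg("qc_dropped.tsv", "qc_summary.json")
  # scan set: QC-passed SNPs on the target chromosome; relationship set:
  # additionally the genome-wide SNPs dropped only for being off-target
  keep_idx <- match(qc$kept_snps, sim$map$snp)
  off_idx <- match(qc$dropped$snp_id[qc$dropped$reason == "off_target_chrom"],
                   sim$map$snp)
  rel_idx <- sort(c(keep_idx, off_idx))
  map_k <- sim$map[keep_idx, , drop = FALSE]
  # downstream stages consume accurately phased, fully imputed haplotypes
  # (the external phasing/imputation step, taken as given); QC above ran on
  # the raw masked genotypes
  panel_k <- sim$true_haplotypes
  panel_k$alleles <- panel_k$alleles[, keep_idx, drop = FALSE]
  geno_k <- geno_from_panel(panel_k)

  # 3. genome-wide relationship matrix + principal components
  rel <- t_stage("relmat", {
    A <- uar_matrix(geno[, rel_idx, drop = FALSE])
    pcs <- uar_pca(A)
    k <- if (is.null(config$n_pcs))
      horn_retain(geno[, rel_idx, drop = FALSE], n_perm = config$n_perm,
                  seed = config$seed + 1L)
    else as.integer(config$n_pcs)
    pcs$k_retained <- k
    list(A = A, pcs = pcs, k = k)
  })
  write_tsv(data.frame(eigenvalue = rel$pcs$eigenvalues), fp("uar_eigenvalues.tsv"),
            comment = sprintf("k_retained = %d", rel$k))
  reg("uar_eigenvalues.tsv")

  # 4. scan
  y <- encode_phenotypes(sim$status_records)
  X <- matrix(1, length(y), 1L)
  if (rel$k > 0)
    X <- cbind(X, rel$pcs$components[, seq_len(rel$k), drop = FALSE])
  params <- ibd_params(Ne = config$Ne, T = config$T)
  scan <- t_stage("scan", lrt_scan(panel_k, map_k, y, X, params,
                                   window_size = config$window_size,
                                   step = config$step))
  write_tsv(scan, fp("scan.tsv"),
            comment = sprintf("seed = %d; windows of %d SNPs, step %d",
                              config$seed, config$window_size, config$step))
  reg("scan.tsv")

  # 5. support intervals
  thr <- significance_threshold(config$alpha_total, nrow(scan))
  ci <- t_stage("ci", lod_ci(scan, thr, config$drop_lod))
  write_tsv(ci, fp("intervals.tsv"),
            comment = sprintf("threshold LRT = %.3f (alpha %g over %d windows)",
                              thr, config$alpha_total, nrow(scan)))
  bed <- if (nrow(ci)) data.frame(chrom = target_chrom,
                                  start = as.integer(ci$lower_bp) - 1L,
                                  end = as.integer(ci$upper_bp))
  else data.frame(chrom = character(0), start = integer(0), end = integer(0))
  write_tsv(bed, fp("intervals.bed"),
            comment = "0-based half-open; internal coordinates are 1-based closed")
  reg("intervals.tsv", "intervals.bed")

  # 6. homozygosity mapping + phenocopy diagnostics
  st <- sim$status_records
  case_ids <- st$animal_id[st$diagnosis %in% c("affected_path", "affected_clinical")]
  ctrl_ids <- st$animal_id[st$diagnosis == "free"]
  hz <- t_stage("homozygosity", {
    runs <- asshom_scan(geno_k[case_ids, , drop = FALSE],
                        geno_k[ctrl_ids, , drop = FALSE], map_k)
    diag_ <- drop_incompatible_cases(geno_k[case_ids, , drop = FALSE],
                                     geno_k[ctrl_ids, , drop = FALSE],
                                     map_k, k = config$k_exclusions)
    list(runs = runs, diagnostics = diag_)
  })
  write_tsv(hz$runs, fp("homozygosity_runs.tsv"))
  write_tsv(hz$diagnostics, fp("phenocopy_candidates.tsv"))
  reg("homozygosity_runs.tsv", "phenocopy_candidates.tsv")

  # 7. common haplotype (pathologically confirmed cases, progeny-tested carriers)
  path_ids <- st$animal_id[st$diagnosis == "affected_path"]
  carrier_ids <- st$animal_id[st$diagnosis == "carrier_progeny"]
  anchor <- if (nrow(ci)) ci$peak_bp[1L] else
    scan$midpoint_bp[which.max(scan$lrt)]
  hap <- t_stage("haplotype", {
    aff_p <- subset_panel(panel_k, path_ids)
    car_p <- subset_panel(panel_k, carrier_ids)
    tryCatch(common_haplotype(aff_p, car_p, map_k, anchor),
             error = function(e) {
               # no shared haplotype at the LRT peak: anchor on the top
               # homozygosity run instead
               run <- hz$runs[1L, ]
               common_haplotype(aff_p, car_p, map_k,
                                (run$start_bp + run$end_bp) / 2)
             })
  })
  write_tsv(data.frame(start_bp = hap$start_bp, end_bp = hap$end_bp,
                       n_snps = hap$n_snps,
                       alleles = paste(hap$alleles, collapse = ",")),
            fp("common_haplotype.tsv"))
  reg("common_haplotype.tsv")

  # 8. variant concordance within the common-haplotype interval
  vt <- sim$variant_table
  conc <- t_stage("variants",
                  concordance_filter(vt, intersect(carrier_ids, vt$animals),
                                     region = c(hap$start_bp, hap$end_bp)))
  keep_vt <- vt
  sel <- vt$variants$id %in% conc$kept$id
  keep_vt$variants <- vt$variants[sel, , drop = FALSE]
  keep_vt$geno <- vt$geno[sel, , drop = FALSE]
  write_variant_vcf(keep_vt, fp("concordant.vcf"))
  write_tsv(conc$near_misses, fp("near_misses.tsv"))
  reg("concordant.vcf", "near_misses.tsv")

  # 9. monitoring: allele frequency of kept variants among table animals
  mon <- t_stage("monitor", {
    if (nrow(conc$kept)) {
      g <- keep_vt$geno[1L, ]
      counts <- data.frame(stratum = "panel",
                           n_genotyped = sum(!is.na(g)),
                           n_het = sum(g == 1L, na.rm = TRUE),
                           n_hom_alt = sum(g == 2L, na.rm = TRUE))
      fr <- allele_frequency(counts)
      q <- fr$allele_freq_percent[fr$stratum == "pooled"] / 100
      list(frequency = fr, risk = mating_risk(q))
    } else list(frequency = NULL, risk = NULL)
  })
  if (!is.null(mon$frequency)) {
    fr <- mon$frequency
    fr$risk_affected_offspring <- mon$risk$risk_affected_offspring
    write_tsv(fr, fp("monitor.tsv"))
    reg("monitor.tsv")
  }

  manifest$outputs <- outputs
  manifest$checksums <- as.list(tools::md5sum(fp(outputs)))
  names(manifest$checksums) <- outputs
  jsonlite::write_json(manifest, fp("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(list(sim = sim, qc = qc, relmat = rel, scan = scan, ci = ci,
                 homozygosity = hz, haplotype = hap, concordance = conc,
                 monitor = mon, manifest = manifest))
}
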