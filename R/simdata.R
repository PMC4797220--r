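#' Configuration for the gene-dropping simulator
#'
#' Defaults emulate a 50K-chip mapping design for a recessive neurodegenerative
#' disorder segregating in a closed cattle population: about 2000 SNPs on one
#' ~120-Mb autosome, a disease allele descending from a single founder
#' haplotype, and a study sample of 43 affected, 31 carrier and 86 free
#' animals plus a few misdiagnosed phenocopies.
#'
#' @param n_founders Number of unrelated founder animals.
#' @param n_generations Gene-dropping depth. Generation 0 is the founders;
#'   the study sample is bred from generation `n_generations - 1`
#'   (with `n_generations = 0` the study sample is drawn from the founders
#'   themselves, so no meiosis occurs).
#' @param n_snps Number of SNPs on the simulated chromosome.
#' @param chrom_length_bp Chromosome length in base pairs.
#' @param cm_per_mb Uniform genetic-map density (cM per Mb); genetic position
#'   is `bp * cm_per_mb / 100 / 1e6` Morgans (Haldane, no interference).
#' @param disease_bp Base-pair position of the planted recessive locus; must
#'   fall strictly between the first and last simulated SNP.
#' @param carrier_founder_count Number of founder haplotypes carrying the
#'   disease allele (one haplotype per founder).
#' @param study_composition Named counts `c(affected=, carrier=, free=)`.
#' @param missing_rate Per animal-by-SNP probability of masking a genotype.
#' @param phenocopy_count Extra animals without the mutation that are labelled
#'   clinically affected in the status records.
#' @param trio_fraction Fraction of affected study animals whose recorded and
#'   genotyped parents are study carriers (producing in-panel trios).
#' @param n_bg_snps Unlinked background SNPs standing in for the rest of the
#'   genome: they feed the genome-wide relationship matrix and exercise the
#'   off-target-chromosome QC rule, and are excluded from the scan.
#' @param chrom Chromosome name used in the map and variant table.
#' @param seed Integer seed; all randomness in [simulate_population()] derives
#'   from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_founders = 60,
                       n_generations = 6,
                       n_snps = 2000,
                       chrom_length_bp = 120e6,
                       cm_per_mb = 1.0,
                       disease_bp = 49878773,
                       carrier_founder_count = 1,
                       study_composition = c(affected = 43, carrier = 31, free = 86),
                       missing_rate = 0.01,
                       phenocopy_count = 3,
                       trio_fraction = 0.25,
                       n_bg_snps = 8000,
                       chrom = "4",
                       seed = 1) {
  sc <- study_composition
  if (!all(c("affected", "carrier", "free") %in% names(sc)))
    stop("study_composition needs counts named affected, carrier, free")
  if (any(sc < 0)) stop("study_composition counts must be >= 0")
  stopifnot(n_founders >= 2, n_generations >= 0, n_snps >= 2,
            chrom_length_bp > n_snps, cm_per_mb >= 0,
            disease_bp > 1, disease_bp < chrom_length_bp,
            carrier_founder_count >= 0, carrier_founder_count <= n_founders,
            missing_rate >= 0, missing_rate < 1,
            phenocopy_count >= 0, trio_fraction >= 0, trio_fraction <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 n_snps = as.integer(n_snps),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 cm_per_mb = cm_per_mb,
                 disease_bp = as.numeric(disease_bp),
                 carrier_founder_count = as.integer(carrier_founder_count),
                 study_composition = sc[c("affected", "carrier", "free")],
                 missing_rate = missing_rate,
                 phenocopy_count = as.integer(phenocopy_count),
                 trio_fraction = trio_fraction,
                 n_bg_snps = as.integer(n_bg_snps),
                 chrom = as.character(chrom),
                 seed = as.integer(seed)),
            class = "sim_config")
}

# One meiosis. Crossovers are a Poisson process on the genetic map; the
# gamete optionally rejected until the disease-locus transmission matches
# `condition` ("any", "carry", "not").
.pick <- function(x, n) x[sample.int(length(x), n)]

.meiosis <- function(alleles, labels, hapdis, parent, morgans, disease_m,
                     len_m, condition = "any", bg = NULL) {
  h1 <- 2L * parent - 1L; h2 <- h1 + 1L
  repeat {
    nco <- stats::rpois(1L, len_m)
    xo <- if (nco > 0L) sort(stats::runif(nco, 0, len_m)) else numeric(0)
    start <- stats::rbinom(1L, 1L, 0.5)
    src <- (start + findInterval(c(morgans, disease_m), xo)) %% 2L
    m <- length(morgans)
    dis <- if (src[m + 1L] == 0L) hapdis[h1] else hapdis[h2]
    if (condition == "any" || (condition == "carry" && dis) ||
        (condition == "not" && !dis)) break
  }
  take2 <- src[seq_len(m)] == 1L
  al <- alleles[h1, ]; al[take2] <- alleles[h2, take2]
  lb <- labels[h1, ]; lb[take2] <- labels[h2, take2]
  bg_al <- NULL
  if (!is.null(bg)) { # unlinked loci segregate independently
    bg_al <- bg[h1, ]
    flip <- stats::runif(ncol(bg)) < 0.5
    bg_al[flip] <- bg[h2, flip]
  }
  list(alleles = al, labels = lb, disease = dis, bg = bg_al)
}

#' Simulate a pedigreed SNP population with a planted recessive locus
#'
#' Founder haplotypes are drawn with independent per-SNP allele frequencies
#' from Uniform(0.05, 0.95); linkage disequilibrium arises from gene dropping.
#' Every transmitted haplotype carries founder-segment labels, so
#' identity-by-descent truth is exact. The disease allele is placed on
#' `carrier_founder_count` founder haplotypes at `disease_bp`; the study
#' sample is bred to match `study_composition` (affected animals receive the
#' allele from both parents, carriers from one), phenocopies are sampled from
#' mutation-free animals and labelled clinically affected, and genotypes are
#' masked at `missing_rate` (full haplotypes are retained as truth).
#'
#' @param cfg A [sim_config()].
#' @return A list of class `sim_output` with elements `haplotypes`
#'   (masked [haplotype_panel()]), `true_haplotypes`, `labels` (founder-segment
#'   label matrix), `hap_disease` (per-haplotype mutation flag), `map`,
#'   `pedigree`, `truth` (animal, copies, is_phenocopy), `status_records`,
#'   `truth_interval` (shared founder segment of affected animals, bp),
#'   `variant_table` (see [make_variant_table()]), `freqs`, and `cfg`.
#' @export
simulate_population <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  m <- cfg$n_snps
  bp <- sort(sample.int(cfg$chrom_length_bp - 2L, m)) + 1
  if (!(bp[1] < cfg$disease_bp && cfg$disease_bp < bp[m]))
    stop("disease_bp must lie strictly between the first and last SNP")
  morgans <- bp * cfg$cm_per_mb / 100 / 1e6
  disease_m <- cfg$disease_bp * cfg$cm_per_mb / 100 / 1e6
  len_m <- cfg$chrom_length_bp * cfg$cm_per_mb / 100 / 1e6
  map <- data.frame(snp = sprintf("snp%04d", seq_len(m)),
                    chrom = cfg$chrom, bp = as.numeric(bp), morgans = morgans,
                    stringsAsFactors = FALSE)
  freq <- stats::runif(m, 0.05, 0.95)

  # unlinked rest-of-genome SNPs spread over the other chromosomes
  mb <- cfg$n_bg_snps
  bg_map <- NULL
  if (mb > 0L) {
    other <- setdiff(as.character(1:29), cfg$chrom)
    bg_chrom <- sort(rep_len(other, mb))
    bg_bp <- unlist(lapply(split(seq_len(mb), bg_chrom), function(i)
      sort(sample.int(1e8, length(i)))), use.names = FALSE)
    bg_map <- data.frame(snp = sprintf("bg%05d", seq_len(mb)),
                         chrom = bg_chrom, bp = as.numeric(bg_bp),
                         morgans = bg_bp * cfg$cm_per_mb / 100 / 1e6,
                         stringsAsFactors = FALSE)
  }
  bg_freq <- stats::runif(mb, 0.05, 0.95)

  nf <- cfg$n_founders
  F_alleles <- matrix(stats::rbinom(2L * nf * m, 1L, rep(freq, each = 2L * nf)),
                      nrow = 2L * nf)
  F_bg <- matrix(stats::rbinom(2L * nf * mb, 1L, rep(bg_freq, each = 2L * nf)),
                 nrow = 2L * nf)
  F_labels <- matrix(rep(seq_len(2L * nf), m), nrow = 2L * nf)
  F_dis <- rep(FALSE, 2L * nf)
  if (cfg$carrier_founder_count > 0)
    F_dis[2L * seq_len(cfg$carrier_founder_count) - 1L] <- TRUE
  mutant_labels <- which(F_dis)

  ped <- list(data.frame(animal_id = sprintf("F%03d", seq_len(nf)),
                         sire_id = "0", dam_id = "0", stringsAsFactors = FALSE))
  pool <- list(ids = sprintf("F%03d", seq_len(nf)), alleles = F_alleles,
               labels = F_labels, hapdis = F_dis, bg = F_bg)

  breed_one <- function(pool, si, di, cond_s = "any", cond_d = "any") {
    gs <- .meiosis(pool$alleles, pool$labels, pool$hapdis, si, morgans,
                   disease_m, len_m, cond_s, pool$bg)
    gd <- .meiosis(pool$alleles, pool$labels, pool$hapdis, di, morgans,
                   disease_m, len_m, cond_d, pool$bg)
    list(alleles = rbind(gs$alleles, gd$alleles),
         labels = rbind(gs$labels, gd$labels),
         hapdis = c(gs$disease, gd$disease),
         bg = rbind(gs$bg, gd$bg))
  }

  # random-mating generations with a carrier quota so the allele persists
  n_gen_random <- max(cfg$n_generations - 1L, 0L)
  for (g in seq_len(n_gen_random)) {
    copies <- pool$hapdis[c(TRUE, FALSE)] + pool$hapdis[c(FALSE, TRUE)]
    parents_ok <- which(copies < 2L)
    hets <- which(copies >= 1L & copies < 2L)
    nons <- setdiff(parents_ok, hets)
    N <- nf
    # few carrier matings per generation: transmission through a handful of
    # prominent sires keeps the mutant founder haplotype largely intact
    quota <- if (length(hets) > 0L && length(nons) > 0L) 4L else 0L
    al <- matrix(0L, 2L * N, m); lb <- matrix(0L, 2L * N, m)
    bgm <- matrix(0L, 2L * N, mb)
    hd <- logical(2L * N)
    ids <- sprintf("G%d_%03d", g, seq_len(N))
    sire <- character(N); dam <- character(N)
    for (i in seq_len(N)) {
      if (i <= quota) {
        si <- .pick(hets, 1L); di <- .pick(nons, 1L)
        off <- breed_one(pool, si, di, "carry", "any")
      } else {
        pr <- .pick(parents_ok, 2L)
        off <- breed_one(pool, pr[1L], pr[2L])
        si <- pr[1L]; di <- pr[2L]
      }
      r <- c(2L * i - 1L, 2L * i)
      al[r, ] <- off$alleles; lb[r, ] <- off$labels; hd[r] <- off$hapdis
      if (mb > 0L) bgm[r, ] <- off$bg
      sire[i] <- pool$ids[si]; dam[i] <- pool$ids[di]
    }
    ped[[length(ped) + 1L]] <- data.frame(animal_id = ids, sire_id = sire,
                                          dam_id = dam, stringsAsFactors = FALSE)
    pool <- list(ids = ids, alleles = al, labels = lb, hapdis = hd, bg = bgm)
  }

  comp <- cfg$study_composition
  n_study <- sum(comp) + cfg$phenocopy_count
  copies_pool <- pool$hapdis[c(TRUE, FALSE)] + pool$hapdis[c(FALSE, TRUE)]

  st_al <- matrix(0L, 2L * n_study, m)
  st_lb <- matrix(0L, 2L * n_study, m)
  st_bg <- matrix(0L, 2L * n_study, mb)
  st_hd <- logical(2L * n_study)
  st_ids <- sprintf("S%03d", seq_len(n_study))
  st_sire <- character(n_study); st_dam <- character(n_study)
  classes <- rep(c("affected", "carrier", "free", "phenocopy"),
                 times = c(comp["affected"], comp["carrier"], comp["free"],
                           cfg$phenocopy_count))

  if (cfg$n_generations == 0L) {
    # study animals are founders themselves
    need <- c(affected = sum(classes == "affected"),
              carrier = sum(classes == "carrier"),
              free = sum(classes %in% c("free", "phenocopy")))
    have <- c(affected = sum(copies_pool == 2L),
              carrier = sum(copies_pool == 1L),
              free = sum(copies_pool == 0L))
    for (cl in names(need))
      if (need[cl] > have[cl])
        stop(sprintf("study composition unreachable: class '%s' needs %d, only %d available",
                     cl, need[cl], have[cl]))
    pick_from <- function(idx, n)
      if (n > 0L) idx[sample.int(length(idx), n)] else integer(0)
    ord <- c(pick_from(which(copies_pool == 2L), need[["affected"]]),
             pick_from(which(copies_pool == 1L), need[["carrier"]]),
             pick_from(which(copies_pool == 0L), need[["free"]]))
    for (i in seq_len(n_study)) {
      src <- ord[i]; r <- c(2L * i - 1L, 2L * i); rs <- c(2L * src - 1L, 2L * src)
      st_al[r, ] <- pool$alleles[rs, ]; st_lb[r, ] <- pool$labels[rs, ]
      if (mb > 0L) st_bg[r, ] <- pool$bg[rs, ]
      st_hd[r] <- pool$hapdis[rs]
      st_sire[i] <- "0"; st_dam[i] <- "0"
    }
  } else {
    hets <- which(copies_pool == 1L)
    nons <- which(copies_pool == 0L)
    if (comp["affected"] > 0L && length(hets) < 2L)
      stop("study composition unreachable: class 'affected' requires >= 2 carrier parents")
    if (comp["carrier"] > 0L && (length(hets) < 1L || length(nons) < 1L))
      stop("study composition unreachable: class 'carrier' requires carrier and non-carrier parents")
    if ((comp["free"] > 0L || cfg$phenocopy_count > 0L) && length(nons) < 2L)
      stop("study composition unreachable: class 'free' requires >= 2 non-carrier parents")

    # carriers first so affected trios can use them as genotyped parents
    order_idx <- order(match(classes, c("carrier", "affected", "free", "phenocopy")))
    carrier_rows <- integer(0) # study indices of generated carriers
    for (i in order_idx) {
      cl <- classes[i]
      r <- c(2L * i - 1L, 2L * i)
      if (cl == "carrier") {
        si <- .pick(hets, 1L); di <- .pick(nons, 1L)
        off <- breed_one(pool, si, di, "carry", "not")
        st_sire[i] <- pool$ids[si]; st_dam[i] <- pool$ids[di]
        carrier_rows <- c(carrier_rows, i)
      } else if (cl == "affected") {
        if (length(carrier_rows) >= 2L && stats::runif(1) < cfg$trio_fraction) {
          pr <- .pick(carrier_rows, 2L)
          fam <- list(ids = st_ids, alleles = st_al, labels = st_lb,
                      hapdis = st_hd, bg = st_bg)
          off <- breed_one(fam, pr[1L], pr[2L], "carry", "carry")
          st_sire[i] <- st_ids[pr[1L]]; st_dam[i] <- st_ids[pr[2L]]
        } else {
          pr <- .pick(hets, 2L)
          off <- breed_one(pool, pr[1L], pr[2L], "carry", "carry")
          st_sire[i] <- pool$ids[pr[1L]]; st_dam[i] <- pool$ids[pr[2L]]
        }
      } else { # free or phenocopy
        pr <- .pick(nons, 2L)
        off <- breed_one(pool, pr[1L], pr[2L], "not", "not")
        st_sire[i] <- pool$ids[pr[1L]]; st_dam[i] <- pool$ids[pr[2L]]
      }
      st_al[r, ] <- off$alleles; st_lb[r, ] <- off$labels; st_hd[r] <- off$hapdis
      if (mb > 0L) st_bg[r, ] <- off$bg
    }
  }

  ped[[length(ped) + 1L]] <- data.frame(animal_id = st_ids, sire_id = st_sire,
                                        dam_id = st_dam, stringsAsFactors = FALSE)
  pedigree <- do.call(rbind, ped)

  copies <- st_hd[c(TRUE, FALSE)] + st_hd[c(FALSE, TRUE)]
  is_pheno <- classes == "phenocopy"
  truth <- data.frame(animal = st_ids, copies = as.integer(copies),
                      is_phenocopy = is_pheno, stringsAsFactors = FALSE)

  diagnosis <- ifelse(classes == "affected", "affected_path",
                      ifelse(classes == "carrier", "carrier_progeny",
                             ifelse(classes == "free", "free", "affected_clinical")))
  evidence <- ifelse(diagnosis == "affected_clinical", "single_official_carrier",
                     NA_character_)
  status <- data.frame(animal_id = st_ids, diagnosis = diagnosis,
                       carrier_ancestor_evidence = evidence,
                       stringsAsFactors = FALSE)

  full_map <- if (mb > 0L) rbind(map, bg_map) else map
  all_al <- if (mb > 0L) cbind(st_al, st_bg) else st_al
  colnames(all_al) <- full_map$snp
  true_panel <- haplotype_panel(st_ids, all_al, phased = TRUE)
  masked <- all_al
  if (cfg$missing_rate > 0) {
    mtot <- ncol(all_al)
    mask <- matrix(stats::runif(n_study * mtot) < cfg$missing_rate, n_study, mtot)
    rows <- which(mask, arr.ind = TRUE)
    if (nrow(rows)) {
      masked[cbind(2L * rows[, 1L] - 1L, rows[, 2L])] <- NA_integer_
      masked[cbind(2L * rows[, 1L], rows[, 2L])] <- NA_integer_
    }
  }
  panel <- haplotype_panel(st_ids, masked, phased = TRUE)

  sim <- structure(list(haplotypes = panel, true_haplotypes = true_panel,
                        labels = st_lb, hap_disease = st_hd, map = full_map,
                        target_map = map, n_target_snps = m,
                        pedigree = pedigree, truth = truth,
                        status_records = status, freqs = freq,
                        mutant_labels = mutant_labels, cfg = cfg),
                   class = "sim_output")
  sim$truth_interval <- .ibs_shared_interval(sim)
  if (!is.null(sim$truth_interval)) {
    sim$variant_table <- make_variant_table(sim, region = sim$truth_interval,
                                            n_background = 500L,
                                            n_outside_concordant = 1L,
                                            seed = cfg$seed + 101L)
  }
  sim
}

#' @export
print.sim_output <- function(x, ...) {
  cat(sprintf("sim_output: %d study animals, %d SNPs (%d on the target chromosome), disease locus at %.0f bp\n",
              length(x$haplotypes$animals), nrow(x$map), x$n_target_snps,
              x$cfg$disease_bp))
  if (!is.null(x$truth_interval))
    cat(sprintf("  true shared segment: %.0f-%.0f bp\n",
                x$truth_interval[1], x$truth_interval[2]))
  invisible(x)
}

# The shared-haplotype interval as it would be OBSERVED: the maximal run of
# SNPs around the disease locus at which every non-phenocopy affected animal
# is homozygous and all carry the same allele (computed on the unmasked
# haplotypes). This is the simulated analogue of the manually identified
# shared disease haplotype, and is what mapping output is scored against.
.ibs_shared_interval <- function(sim) {
  aff <- sim$truth$animal[sim$truth$copies == 2L & !sim$truth$is_phenocopy]
  if (!length(aff)) return(NULL)
  j <- match(aff, sim$true_haplotypes$animals)
  H <- sim$true_haplotypes$alleles
  H <- H[, seq_len(sim$n_target_snps), drop = FALSE]
  h1 <- H[2L * j - 1L, , drop = FALSE]
  h2 <- H[2L * j, , drop = FALSE]
  shared <- colSums(h1 == h2) == length(aff) &
    .col_all_equal(h1)
  bp <- sim$target_map$bp
  jL <- findInterval(sim$cfg$disease_bp, bp)
  l <- jL
  while (l >= 1L && shared[l]) l <- l - 1L
  r <- jL + 1L
  while (r <= length(bp) && shared[r]) r <- r + 1L
  c(start_bp = if (l < jL) bp[l + 1L] else sim$cfg$disease_bp,
    end_bp = if (r > jL + 1L) bp[r - 1L] else sim$cfg$disease_bp)
}

# all rows equal within each column
.col_all_equal <- function(x) {
  if (nrow(x) == 1L) return(rep(TRUE, ncol(x)))
  colSums(x == rep(x[1L, ], each = nrow(x))) == nrow(x)
}

#' True shared founder segment around the disease locus
#'
#' Intersects, over all disease-carrying haplotypes of the given animals, the
#' run of SNPs whose founder-segment label equals a mutant founder label.
#' This is the exact identity-by-descent analogue of the shared disease
#' haplotype and is the truth against which mapping output is scored.
#'
#' @param sim A `sim_output`.
#' @param animals Animal ids; defaults to non-phenocopy affected animals.
#' @return `c(start_bp, end_bp)` or `NULL` when no disease haplotype exists
#'   among `animals`.
#' @export
true_shared_interval <- function(sim, animals = NULL) {
  stopifnot(inherits(sim, "sim_output"))
  if (is.null(animals))
    animals <- sim$truth$animal[sim$truth$copies == 2L & !sim$truth$is_phenocopy]
  j <- match(animals, sim$haplotypes$animals)
  if (anyNA(j)) stop("unknown animal id(s)")
  rows <- as.vector(rbind(2L * j - 1L, 2L * j))
  rows <- rows[sim$hap_disease[rows]]
  if (!length(rows)) return(NULL)
  bp <- sim$target_map$bp
  jL <- findInterval(sim$cfg$disease_bp, bp) # last SNP with bp <= disease_bp
  lo <- sim$cfg$disease_bp; hi <- sim$cfg$disease_bp
  lo_all <- hi_all <- numeric(length(rows))
  for (k in seq_along(rows)) {
    lab <- sim$labels[rows[k], ]
    mut <- lab %in% sim$mutant_labels
    l <- jL
    while (l >= 1L && mut[l]) l <- l - 1L
    r <- jL + 1L
    while (r <= length(bp) && mut[r]) r <- r + 1L
    lo_all[k] <- if (l < jL) bp[l + 1L] else sim$cfg$disease_bp
    hi_all[k] <- if (r > jL + 1L) bp[r - 1L] else sim$cfg$disease_bp
  }
  c(start_bp = max(lo_all), end_bp = min(hi_all))
}

#' Build a region-restricted sequence-variant table
#'
#' Emulates a resequencing panel over a mapped interval: the study carriers
#' and mutation-free study animals are "sequenced" (affected animals are not,
#' matching a monitoring design where cases are long dead), together with the
#' mutation-free founder generation, which stands in for the broad reference
#' panel of a population-scale sequencing project -- it carries every
#' ancestral haplotype, so region variants that merely ride on the mutant
#' haplotype's ancestral background are seen in non-carriers and rejected by
#' concordance filtering, exactly as a diverse control panel rejects them.
#' The table contains one causal variant at the disease position whose
#' alternative allele tracks the disease haplotypes exactly, `n_background`
#' variants whose alleles ride on the simulated founder-haplotype mosaic (in
#' LD with local SNPs but concordant with carrier status only by chance), and
#' `n_outside_concordant` variants outside `region` that are perfectly
#' concordant with carrier status.
#'
#' @param sim A `sim_output`.
#' @param region Numeric `c(start_bp, end_bp)`; must overlap the chromosome
#'   and contain at least one SNP anchor.
#' @param n_background Number of mosaic-derived background variants.
#' @param n_outside_concordant Number of planted concordant variants outside
#'   `region`.
#' @param seed Integer seed for this operation.
#' @return A list of class `variant_table`: `variants` data frame (id, chrom,
#'   pos, ref, alt, type), `geno` matrix (variants x animals, 0/1/2 copies of
#'   the alternative allele) and `animals`.
#' @export
make_variant_table <- function(sim, region, n_background = 500L,
                               n_outside_concordant = 1L, seed = 1L) {
  stopifnot(inherits(sim, "sim_output"), length(region) == 2L,
            region[1] <= region[2])
  set.seed(as.integer(seed))
  bp <- sim$target_map$bp
  anchors <- which(bp >= region[1] & bp <= region[2])
  if (!length(anchors)) stop("region contains no SNP anchors")
  tr <- sim$truth
  carriers <- tr$animal[tr$copies == 1L]
  if (length(carriers) < 2L) stop("need at least 2 carriers in the simulation")
  controls <- tr$animal[tr$copies == 0L & !tr$is_phenocopy]
  nf <- sim$cfg$n_founders
  founder_ctrl <- setdiff(sprintf("F%03d", seq_len(nf)),
                          sprintf("F%03d", seq_len(sim$cfg$carrier_founder_count)))
  vt_animals <- c(carriers, controls, founder_ctrl)
  n_study_vt <- length(carriers) + length(controls)
  j <- match(vt_animals[seq_len(n_study_vt)], sim$haplotypes$animals)
  hap_rows <- as.vector(rbind(2L * j - 1L, 2L * j))
  # founder-segment labels of the panel haplotypes: study animals by descent,
  # founders trivially carry their own two labels everywhere
  fidx <- match(founder_ctrl, sprintf("F%03d", seq_len(nf)))
  founder_lab <- as.vector(rbind(2L * fidx - 1L, 2L * fidx))

  n_var <- 1L + n_background + n_outside_concordant
  pos <- numeric(n_var); geno <- matrix(0L, n_var, length(vt_animals))
  ref <- character(n_var); alt <- character(n_var); vid <- character(n_var)
  bases <- c("A", "C", "G", "T")

  # causal variant: copies of the disease allele (founder controls carry none)
  pos[1L] <- sim$cfg$disease_bp
  cp <- tr$copies[match(vt_animals, tr$animal)]
  cp[is.na(cp)] <- 0L
  geno[1L, ] <- cp
  ref[1L] <- "C"; alt[1L] <- "T"; vid[1L] <- "var_causal"

  if (n_background > 0L) {
    cand <- setdiff(seq(ceiling(region[1]), floor(region[2])), sim$cfg$disease_bp)
    bg_pos <- sort(sample(cand, n_background))
    lab_rows <- sim$labels[hap_rows, , drop = FALSE]
    for (v in seq_len(n_background)) {
      p <- bg_pos[v]
      anchor <- anchors[which.min(abs(bp[anchors] - p))]
      falt <- stats::runif(1, 0.05, 0.5)
      alt_founders <- which(stats::rbinom(2L * nf, 1L, falt) == 1L)
      hap_alt <- c(lab_rows[, anchor], founder_lab) %in% alt_founders
      g <- hap_alt[c(TRUE, FALSE)] + hap_alt[c(FALSE, TRUE)]
      i <- 1L + v
      pos[i] <- p; geno[i, ] <- g
      rr <- sample(bases, 2L)
      ref[i] <- rr[1L]; alt[i] <- rr[2L]; vid[i] <- sprintf("var_bg%04d", v)
    }
  }

  n_out_placed <- 0L
  if (n_outside_concordant > 0L) {
    gap <- 0.01 * sim$cfg$chrom_length_bp
    right <- seq(floor(region[2] + gap),
                 length.out = max(0, floor(sim$cfg$chrom_length_bp - region[2] - gap)))
    left <- seq_len(max(0, floor(region[1] - gap)))
    out_pool <- if (length(right) >= n_outside_concordant) right else left
    if (length(out_pool) < n_outside_concordant) {
      warning("no room outside the region: concordant outside variants skipped")
    } else {
      out_pos <- sort(sample(out_pool, n_outside_concordant))
      for (v in seq_len(n_outside_concordant)) {
        i <- 1L + n_background + v
        pos[i] <- out_pos[v]; geno[i, ] <- cp
        ref[i] <- "G"; alt[i] <- "A"; vid[i] <- sprintf("var_out%02d", v)
      }
      n_out_placed <- n_outside_concordant
    }
  }
  filled <- seq_len(1L + n_background + n_out_placed)
  pos <- pos[filled]; geno <- geno[filled, , drop = FALSE]
  ref <- ref[filled]; alt <- alt[filled]; vid <- vid[filled]

  ord <- order(pos)
  variants <- data.frame(id = vid[ord], chrom = sim$cfg$chrom, pos = pos[ord],
                         ref = ref[ord], alt = alt[ord], type = "SNP",
                         stringsAsFactors = FALSE)
  geno <- geno[ord, , drop = FALSE]
  rownames(geno) <- variants$id; colnames(geno) <- vt_animals
  structure(list(variants = variants, geno = geno, animals = vt_animals),
            class = "variant_table")
}

#' @export
print.variant_table <- function(x, ...) {
  cat(sprintf("variant_table: %d variants x %d animals\n",
              nrow(x$variants), length(x$animals)))
  invisible(x)
}
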