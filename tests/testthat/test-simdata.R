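test_that("study composition and phenocopy labelling match the configuration", {
  sim <- small_sim(seed = 7)
  tr <- sim$truth
  st <- sim$status_records
  expect_equal(sum(tr$copies == 2 & !tr$is_phenocopy), 10)
  expect_equal(sum(tr$copies == 1), 8)
  expect_equal(sum(tr$copies == 0 & !tr$is_phenocopy), 20)
  # phenocopies are labelled affected but carry no mutation
  affected_status <- st$animal_id[st$diagnosis %in% c("affected_path",
                                                      "affected_clinical")]
  expect_length(affected_status, 12)
  expect_equal(sum(tr$copies[match(affected_status, tr$animal)] != 2), 2)
  expect_true(all(tr$copies[tr$is_phenocopy] == 0))
})

test_that("no gene dropping means founder haplotypes pass through unchanged", {
  cfg <- small_sim_cfg(seed = 11, n_generations = 0,
                       study_composition = c(affected = 0, carrier = 0, free = 15),
                       phenocopy_count = 0, missing_rate = 0)
  sim <- simulate_population(cfg)
  # single founder label per haplotype row
  expect_true(all(apply(sim$labels, 1L, function(r) length(unique(r))) == 1L))
})

test_that("zero recombination rate copies one parental haplotype per gamete", {
  cfg <- small_sim_cfg(seed = 12, cm_per_mb = 0, missing_rate = 0)
  sim <- suppressWarnings(simulate_population(cfg))
  expect_true(all(apply(sim$labels, 1L, function(r) length(unique(r))) == 1L))
})

test_that("identical founder-segment labels imply identical alleles", {
  sim <- small_sim(seed = 7)
  H <- sim$true_haplotypes$alleles[, seq_len(sim$n_target_snps)]
  set.seed(1)
  for (j in sample.int(sim$n_target_snps, 25)) {
    split_alleles <- split(H[, j], sim$labels[, j])
    expect_true(all(vapply(split_alleles, function(a) length(unique(a)) == 1L,
                           logical(1))))
  }
})

test_that("offspring genotypes are Mendelian-consistent with genotyped parents", {
  sim <- small_sim(seed = 7)
  g <- geno_from_panel(sim$true_haplotypes)
  ped <- sim$pedigree[sim$pedigree$animal_id %in% rownames(g), ]
  for (par in c("sire_id", "dam_id")) {
    pp <- ped[ped[[par]] %in% rownames(g), ]
    if (!nrow(pp)) next
    conflict <- abs(g[pp$animal_id, , drop = FALSE] -
                      g[pp[[par]], , drop = FALSE]) == 2L
    expect_equal(sum(conflict), 0)
  }
})

test_that("affected animals are homozygous for one shared haplotype around the locus", {
  sim <- small_sim(seed = 7)
  ti <- sim$truth_interval
  expect_true(ti[1] <= sim$cfg$disease_bp && sim$cfg$disease_bp <= ti[2])
  idx <- which(sim$map$bp >= ti[1] & sim$map$bp <= ti[2] &
                 sim$map$chrom == sim$cfg$chrom)
  aff <- sim$truth$animal[sim$truth$copies == 2 & !sim$truth$is_phenocopy]
  H <- subset_panel(sim$true_haplotypes, aff)$alleles[, idx, drop = FALSE]
  expect_true(all(H == rep(H[1, ], each = nrow(H))))
  # and the founder-segment truth interval is contained in the observed one
  ibd <- true_shared_interval(sim)
  expect_true(ibd[1] >= ti[1] && ibd[2] <= ti[2])
})

test_that("simulation is reproducible for a seed and sensitive to it", {
  a <- simulate_population(small_sim_cfg(seed = 3))
  b <- simulate_population(small_sim_cfg(seed = 3))
  expect_identical(a$haplotypes$alleles, b$haplotypes$alleles)
  expect_identical(a$variant_table$geno, b$variant_table$geno)
  c_ <- simulate_population(small_sim_cfg(seed = 4))
  expect_false(identical(a$haplotypes$alleles, c_$haplotypes$alleles))
})

test_that("unreachable compositions fail with the deficient class named", {
  cfg <- small_sim_cfg(seed = 5, n_generations = 0,
                       study_composition = c(affected = 3, carrier = 0, free = 5),
                       phenocopy_count = 0)
  expect_error(simulate_population(cfg), "affected")
})

test_that("variant table plants exactly one causal and requested extras", {
  sim <- small_sim(seed = 7)
  vt0 <- make_variant_table(sim, region = sim$truth_interval,
                            n_background = 0, n_outside_concordant = 0,
                            seed = 2)
  expect_equal(nrow(vt0$variants), 1L)
  tr <- sim$truth
  carr <- tr$animal[tr$copies == 1]
  free <- tr$animal[tr$copies == 0]
  g <- vt0$geno[1L, ]
  expect_true(all(g[carr] == 1L))
  expect_true(all(g[intersect(free, vt0$animals)] == 0L))

  vt1 <- make_variant_table(sim, region = sim$truth_interval,
                            n_background = 50, n_outside_concordant = 1,
                            seed = 2)
  expect_equal(nrow(vt1$variants), 52L)
  out_id <- vt1$variants$id[grepl("out", vt1$variants$id)]
  expect_true(vt1$variants$pos[vt1$variants$id == out_id] > sim$truth_interval[2] ||
                vt1$variants$pos[vt1$variants$id == out_id] < sim$truth_interval[1])
  # determinism under a fixed seed
  vt2 <- make_variant_table(sim, region = sim$truth_interval,
                            n_background = 50, n_outside_concordant = 1,
                            seed = 2)
  expect_identical(vt1$geno, vt2$geno)
  expect_identical(vt1$variants, vt2$variants)
})
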