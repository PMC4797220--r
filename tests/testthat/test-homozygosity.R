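toy_map <- function(m, chrom = "4") {
  data.frame(snp = paste0("s", seq_len(m)), chrom = chrom,
             bp = as.numeric(seq_len(m) * 1e5), morgans = seq_len(m) * 1e-5)
}

test_that("run scoring matches the hand-computed control-frequency score", {
  # 3 cases homozygous for allele A (=0) at SNPs 2-4; broken at SNPs 1 and 5
  cases <- rbind(c(1, 0, 0, 0, 1),
                 c(0, 0, 0, 0, 2),
                 c(2, 0, 0, 0, 0))
  rownames(cases) <- paste0("c", 1:3)
  # 5 controls with allele-0 frequencies 0.5, 0.1, 0.5 at SNPs 2-4
  controls <- rbind(c(0, 1, 2, 1, 0),
                    c(0, 1, 2, 1, 0),
                    c(0, 1, 2, 1, 0),
                    c(0, 2, 1, 2, 0),
                    c(0, 0, 2, 0, 0))
  rownames(controls) <- paste0("k", 1:5)
  p0 <- 1 - colMeans(controls) / 2
  stopifnot(all(abs(p0[2:4] - c(0.5, 0.1, 0.5)) < 1e-12))
  runs <- asshom_scan(cases, controls, toy_map(5))
  expect_equal(nrow(runs), 1L)
  expect_equal(runs$first_snp, 2L)
  expect_equal(runs$last_snp, 4L)
  expect_equal(runs$score, -log10(0.5) - log10(0.1) - log10(0.5),
               tolerance = 1e-12)
  expect_equal(attr(runs, "alleles")[[1]], rep(0L, 3))
})

test_that("absent shared allele is clamped to a finite contribution", {
  cases <- rbind(c(0, 0), c(0, 0)); rownames(cases) <- c("a", "b")
  controls <- rbind(c(2, 2), c(2, 2)); rownames(controls) <- c("x", "y")
  runs <- asshom_scan(cases, controls, toy_map(2))
  eps <- 1 / (2 * 2 + 2)
  expect_equal(runs$score[1], -2 * log10(eps), tolerance = 1e-12)
})

test_that("no universally homozygous SNP yields an empty run list", {
  cases <- rbind(c(1, 0), c(0, 1)); rownames(cases) <- c("a", "b")
  controls <- rbind(c(0, 0), c(0, 0)); rownames(controls) <- c("x", "y")
  expect_equal(nrow(asshom_scan(cases, controls, toy_map(2))), 0L)
  # missing case genotype terminates a run
  cases2 <- rbind(c(0, NA, 0), c(0, 0, 0)); rownames(cases2) <- c("a", "b")
  runs2 <- asshom_scan(cases2, matrix(1, 1, 3,
                                      dimnames = list("x", NULL)), toy_map(3))
  expect_true(all(runs2$n_snps == 1))
})

test_that("run scores are invariant to case and control ordering", {
  sim <- small_sim(seed = 7)
  g <- geno_from_panel(impute_panel(sim$haplotypes))[, seq_len(sim$n_target_snps)]
  tr <- sim$truth
  cases <- g[tr$animal[tr$copies == 2], , drop = FALSE]
  ctrl <- g[tr$animal[tr$copies == 0 & !tr$is_phenocopy], , drop = FALSE]
  a <- asshom_scan(cases, ctrl, sim$target_map)
  b <- asshom_scan(cases[sample(nrow(cases)), ], ctrl[sample(nrow(ctrl)), ],
                   sim$target_map)
  expect_equal(a$score, b$score, tolerance = 1e-12)
})

test_that("the top run and common haplotype overlap the disease locus on simulated data", {
  hits_run <- 0L; hits_hap <- 0L
  for (s in c(7, 8, 9)) {
    sim <- small_sim(s)
    g <- geno_from_panel(impute_panel(sim$haplotypes))[, seq_len(sim$n_target_snps)]
    tr <- sim$truth
    cases <- g[tr$animal[tr$copies == 2], , drop = FALSE]
    ctrl <- g[tr$animal[tr$copies == 0 & !tr$is_phenocopy], , drop = FALSE]
    runs <- asshom_scan(cases, ctrl, sim$target_map)
    top3 <- runs[seq_len(min(3L, nrow(runs))), ]
    if (any(top3$start_bp <= sim$cfg$disease_bp &
            sim$cfg$disease_bp <= top3$end_bp)) hits_run <- hits_run + 1L

    true_target <- sim$true_haplotypes
    true_target$alleles <- true_target$alleles[, seq_len(sim$n_target_snps)]
    aff <- subset_panel(true_target, tr$animal[tr$copies == 2])
    car <- subset_panel(true_target, tr$animal[tr$copies == 1])
    ch <- common_haplotype(aff, car, sim$target_map, sim$cfg$disease_bp)
    if (ch$start_bp <= sim$cfg$disease_bp &&
        sim$cfg$disease_bp <= ch$end_bp) hits_hap <- hits_hap + 1L
    # the haplotype covers the whole founder-segment overlap of the disease
    # haplotypes (inside it the conditions hold by construction)
    ibd <- true_shared_interval(sim, tr$animal[tr$copies >= 1 & !tr$is_phenocopy])
    expect_lte(ch$start_bp, ibd[1])
    expect_gte(ch$end_bp, ibd[2])
  }
  expect_gte(hits_run, 2L)
  expect_equal(hits_hap, 3L)
})

test_that("planted phenocopies are flagged as the incompatible cases", {
  for (s in c(7, 9)) {
    sim <- small_sim(s)
    g <- geno_from_panel(impute_panel(sim$haplotypes))[, seq_len(sim$n_target_snps)]
    st <- sim$status_records
    cases <- g[st$animal_id[st$diagnosis %in% c("affected_path",
                                                "affected_clinical")], ,
               drop = FALSE]
    ctrl <- g[st$animal_id[st$diagnosis == "free"], , drop = FALSE]
    dd <- drop_incompatible_cases(cases, ctrl, sim$target_map, k = 2)
    ph <- sim$truth$animal[sim$truth$is_phenocopy]
    expect_setequal(dd$animal_id, ph)
    expect_true(all(dd$gain >= 0))
  }
  # k = 0 reports nothing
  sim <- small_sim(7)
  g <- geno_from_panel(impute_panel(sim$haplotypes))[, seq_len(sim$n_target_snps)]
  st <- sim$status_records
  cases <- g[st$animal_id[st$diagnosis != "free"], , drop = FALSE]
  ctrl <- g[st$animal_id[st$diagnosis == "free"], , drop = FALSE]
  expect_equal(nrow(drop_incompatible_cases(cases, ctrl, sim$target_map, k = 0)),
               0L)
})

test_that("with clean cases no animal is strongly incompatible", {
  sim <- small_sim(seed = 8)
  g <- geno_from_panel(impute_panel(sim$haplotypes))[, seq_len(sim$n_target_snps)]
  tr <- sim$truth
  cases <- g[tr$animal[tr$copies == 2 & !tr$is_phenocopy], , drop = FALSE]
  ctrl <- g[tr$animal[tr$copies == 0 & !tr$is_phenocopy], , drop = FALSE]
  dd <- drop_incompatible_cases(cases, ctrl, sim$target_map, k = 2)
  expect_lte(nrow(dd), 2L)
  if (nrow(dd)) {
    expect_true(all(dd$n_mismatch >= 1))
    expect_true(all(is.finite(dd$gain)))
  }
})

test_that("common haplotype extension rules behave at the boundaries", {
  m <- 6
  map <- toy_map(m)
  # two affecteds homozygous-identical everywhere
  aff_al <- rbind(rep(0L, m), rep(0L, m), rep(0L, m), rep(0L, m))
  aff <- haplotype_panel(c("a1", "a2"), aff_al)
  # carriers each with one matching haplotype over the whole map
  car <- haplotype_panel(c("c1", "c2"),
                         rbind(rep(0L, m), rep(1L, m),
                               rep(0L, m), c(1L, 0L, 1L, 0L, 1L, 0L)))
  full <- common_haplotype(aff, car, map, anchor_bp = 3e5)
  expect_equal(full$first_snp, 1L)
  expect_equal(full$last_snp, m)
  expect_equal(full$carrier_copies$n_copies, c(1L, 1L))

  # one affected heterozygous right after the anchor stops the extension
  aff2_al <- aff_al
  aff2_al[2, 4] <- 1L # a1 het at SNP 4
  aff2 <- haplotype_panel(c("a1", "a2"), aff2_al)
  part <- common_haplotype(aff2, car, map, anchor_bp = 3e5)
  expect_equal(part$last_snp, 3L)
  expect_equal(part$first_snp, 1L)

  # anchor violated -> error naming the animal
  aff3_al <- aff_al; aff3_al[1, 3] <- 1L
  expect_error(common_haplotype(haplotype_panel(c("a1", "a2"), aff3_al),
                                car, map, anchor_bp = 3e5), "a1")
})

test_that("removing a carrier never shrinks the common-haplotype interval", {
  sim <- small_sim(seed = 7)
  tr <- sim$truth
  true_target <- sim$true_haplotypes
  true_target$alleles <- true_target$alleles[, seq_len(sim$n_target_snps)]
  aff <- subset_panel(true_target, tr$animal[tr$copies == 2])
  carr_ids <- tr$animal[tr$copies == 1]
  car <- subset_panel(true_target, carr_ids)
  ch_all <- common_haplotype(aff, car, sim$target_map, sim$cfg$disease_bp)
  for (drop1 in carr_ids[1:3]) {
    ch_sub <- common_haplotype(aff,
                               subset_panel(true_target,
                                            setdiff(carr_ids, drop1)),
                               sim$target_map, sim$cfg$disease_bp)
    expect_lte(ch_sub$start_bp, ch_all$start_bp)
    expect_gte(ch_sub$end_bp, ch_all$end_bp)
  }
})
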