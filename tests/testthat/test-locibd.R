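# toy 40-SNP map with uniform spacing and controllable frequencies
toy_map40 <- function(spacing_m = 5e-4) {
  m <- 40L
  data.frame(snp = paste0("s", 1:m), chrom = "4",
             bp = as.numeric(seq_len(m) * 1e5),
             morgans = seq_len(m) * spacing_m)
}

test_that("window geometry follows the sliding-window definition", {
  map <- small_sim(seed = 7)$target_map
  big <- do.call(rbind, replicate(7, map, simplify = FALSE))
  big$bp <- seq_len(nrow(big)); big$morgans <- big$bp * 1e-8
  big$snp <- paste0("m", seq_len(nrow(big)))
  w1958 <- make_windows(big[1:1958, ], size = 40)
  expect_equal(nrow(w1958), 1919)
  w40 <- make_windows(big[1:40, ], size = 40)
  expect_equal(nrow(w40), 1)
  expect_error(make_windows(big[1:39, ], size = 40), "need at least")
  # midpoint between the 20th and 21st SNP of the span
  mm <- data.frame(snp = paste0("s", 1:40), chrom = "1",
                   bp = c(seq_len(19) * 2, 100, 200, 22:40 * 50 + 200),
                   morgans = cumsum(rep(1e-6, 40)))
  expect_equal(make_windows(mm, 40)$midpoint_bp, 150)
})

test_that("no flanking identity-by-state returns the prior", {
  map <- toy_map40()
  w <- make_windows(map, 40)
  hapA <- rep(c(0L, 1L), 20)
  hapB <- 1L - hapA # mismatch everywhere
  p <- locibd_pair(hapA, hapB, w[1, ], map, freqs = rep(0.5, 40))
  prm <- ibd_params()
  expect_equal(p, prm$phi, tolerance = 1e-12)
  expect_equal(prm$phi, 1 - (1 - 1 / 200)^10, tolerance = 1e-12)
})

test_that("one informative marker each side matches the closed form exactly", {
  map <- toy_map40()
  w <- make_windows(map, 40)[1, ]
  # IBS exactly at SNPs 20 and 21 (adjacent to the midpoint), mismatch elsewhere
  hapA <- rep(0L, 40)
  hapB <- rep(1L, 40); hapB[c(20, 21)] <- 0L
  freqs <- rep(0.5, 40) # h_i = 0.5
  p <- locibd_pair(hapA, hapB, w, map, freqs)
  d <- (w$midpoint_morgans - map$morgans[20]) +
    (map$morgans[21] - w$midpoint_morgans) # total run span
  phi <- 1 - (1 - 1 / 200)^10
  s <- exp(-2 * 10 * d)
  expected <- phi * s / (phi * s + (1 - phi) * 0.25)
  expect_equal(p, expected, tolerance = 1e-12)
  # symmetry in the two haplotypes
  expect_equal(locibd_pair(hapB, hapA, w, map, freqs), p, tolerance = 1e-15)
})

test_that("run extension increases the IBD posterior where survival dominates", {
  spacing <- 1e-4 # h = 0.68 > exp(-2*10*1e-4): chance term shrinks faster
  map <- toy_map40(spacing)
  w <- make_windows(map, 40)[1, ]
  freqs <- rep(0.7, 40)
  h <- 0.7^2 + 0.3^2
  stopifnot(h < exp(-2 * 10 * spacing))
  hapA <- rep(0L, 40)
  last <- -Inf
  for (len in 0:10) {
    hapB <- rep(1L, 40)
    if (len > 0) hapB[c(20 - seq_len(len) + 1, 20 + seq_len(len))] <- 0L
    p <- locibd_pair(hapA, hapB, w, map, freqs)
    expect_gt(p, last)
    last <- p
  }
})

test_that("matrix assembly agrees with the per-pair closed form", {
  sim <- small_sim(seed = 7)
  panel <- impute_panel(sim$haplotypes)
  panel$alleles <- panel$alleles[, seq_len(sim$n_target_snps), drop = FALSE]
  panel <- subset_panel(panel, panel$animals[1:7])
  map <- sim$target_map
  freqs <- panel_freqs(panel)
  w <- make_windows(map, 40)[25, ]
  M <- locibd_matrix(panel, w, map, freqs, method = "runs")
  nh <- nrow(panel$alleles)
  for (i in seq_len(nh)) {
    for (j in seq_len(nh)) {
      expected <- if (i == j) 1 else
        locibd_pair(panel$alleles[i, ], panel$alleles[j, ], w, map, freqs)
      expect_equal(M[i, j], expected, tolerance = 1e-12)
    }
  }
})

test_that("multipoint matrix matches an independent per-pair R evaluation", {
  sim <- small_sim(seed = 7)
  panel <- impute_panel(sim$haplotypes)
  panel$alleles <- panel$alleles[, seq_len(sim$n_target_snps), drop = FALSE]
  panel <- subset_panel(panel, panel$animals[1:6])
  map <- sim$target_map
  freqs <- panel_freqs(panel)
  w <- make_windows(map, 40)[100, ]
  prm <- ibd_params()
  M <- locibd_matrix(panel, w, map, freqs, prm, method = "multipoint")
  span <- w$first_snp:w$last_snp
  a <- exp(-2 * prm$T * abs(map$morgans[span] - w$midpoint_morgans))
  h <- freqs[span]^2 + (1 - freqs[span])^2
  H <- panel$alleles
  for (i in 1:11) {
    for (j in (i + 1):12) {
      ibs <- H[i, span] == H[j, span]
      R <- prod(ifelse(ibs, (a + (1 - a) * h) / h, 1 - a))
      expected <- prm$phi * R / (prm$phi * R + 1 - prm$phi)
      expect_equal(M[i, j], expected, tolerance = 1e-10)
    }
  }
  expect_true(all(diag(M) == 1))
  expect_identical(M, t(M))
})

test_that("missing alleles in the window are rejected", {
  sim <- small_sim(seed = 7)
  panel <- sim$haplotypes # still masked
  map <- sim$target_map
  w <- make_windows(map, 40)[1, ]
  expect_error(locibd_matrix(panel, w, map), "impute")
})

test_that("DRM conversion follows the four-term rule and repairs negativity", {
  # identity locus-IBD: unrelated, non-inbred diplotypes
  expect_equal(unname(drm_from_locibd(diag(8))), diag(4), ignore_attr = TRUE)
  # fully autozygous animal
  M <- diag(4); M[1, 2] <- M[2, 1] <- 1
  expect_equal(drm_from_locibd(M)[1, 1], 2)
  expect_error(drm_from_locibd(diag(5)), "even")
  # brute-force four-term oracle on a random valid matrix (4 animals)
  set.seed(11)
  B <- matrix(runif(64), 8); B <- (B + t(B)) / 2; diag(B) <- 1
  D <- drm_from_locibd(B)
  for (j in 1:4) {
    for (k in 1:4) {
      j1 <- 2 * j - 1; j2 <- 2 * j; k1 <- 2 * k - 1; k2 <- 2 * k
      expected <- if (j == k) 1 + B[j1, j2] else
        (B[j1, k1] + B[j1, k2] + B[j2, k1] + B[j2, k2]) / 2
      expect_equal(D[j, k] - (j == k) * attr(D, "ridge"), expected,
                   tolerance = 1e-10)
    }
  }
  e <- attr(D, "eigen")
  expect_gte(min(e$values), 1e-6 - 1e-12)
  expect_equal(e$vectors %*% diag(e$values) %*% t(e$vectors), unclass(D),
               tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("diplotype matrices from IBD probabilities are symmetric with diagonal >= 1", {
  sim <- small_sim(seed = 7)
  panel <- impute_panel(sim$haplotypes)
  panel$alleles <- panel$alleles[, seq_len(sim$n_target_snps), drop = FALSE]
  map <- sim$target_map
  for (wi in c(10, 120)) {
    w <- make_windows(map, 40)[wi, ]
    M <- locibd_matrix(panel, w, map)
    expect_true(all(M >= 0 & M <= 1))
    D <- drm_from_locibd(M)
    expect_identical(unclass(D), t(unclass(D)))
    expect_true(all(diag(D) >= 1))
    expect_true(all(D[upper.tri(D)] >= 0 & D[upper.tri(D)] <= 2))
  }
})

test_that("IBD-truth pairs score higher locus-IBD than non-IBD pairs at the locus", {
  ok <- 0L
  for (s in c(7, 8, 9)) {
    sim <- small_sim(s)
    panel <- impute_panel(sim$haplotypes)
    panel$alleles <- panel$alleles[, seq_len(sim$n_target_snps), drop = FALSE]
    map <- sim$target_map
    wins <- make_windows(map, 40)
    w <- wins[which.min(abs(wins$midpoint_bp - sim$cfg$disease_bp)), ]
    M <- locibd_matrix(panel, w, map)
    jL <- findInterval(sim$cfg$disease_bp, map$bp)
    lab <- sim$labels[, jL]
    same <- outer(lab, lab, "==")
    ut <- upper.tri(M)
    if (mean(M[ut][same[ut]]) > mean(M[ut][!same[ut]])) ok <- ok + 1L
  }
  expect_gte(ok, 3L)
})
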