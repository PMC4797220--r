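#' Phase genotypes using trio transmission and local haplotype frequencies
#'
#' A deliberately simple phasing utility for panels whose contract input is
#' already phased: heterozygous sites are resolved by Mendelian transmission
#' wherever a genotyped parent is informative (a homozygous parent fixes the
#' transmitted allele), remaining heterozygotes are phased by greedy extension
#' using two-site haplotype frequencies within a 10-SNP lookback window
#' estimated from already-resolved haplotypes, and remaining missing alleles
#' are imputed to the major allele. Deterministic given input order. Sites
#' that are Mendelian-inconsistent within a trio are set to missing for the
#' offspring and counted in the `n_mendel_conflicts` attribute.
#'
#' Haplotype 1 is maternal where transmission is informative (child 0/1 with
#' dam homozygous, or with dam heterozygous and sire homozygous).
#'
#' @param geno Genotype dosage matrix (animals x SNPs, 0/1/2/NA) with animal
#'   rownames.
#' @param pedigree Optional pedigree (animal_id, sire_id, dam_id); parents
#'   must appear in `geno` to be used.
#' @param window Lookback width (SNPs) for the frequency-guided extension.
#' @return A phased [haplotype_panel()] with attribute `n_mendel_conflicts`.
#' @export
trio_phase <- function(geno, pedigree = NULL, window = 10L) {
  stopifnot(is.matrix(geno), !is.null(rownames(geno)))
  n <- nrow(geno); m <- ncol(geno)
  animals <- rownames(geno)
  h1 <- matrix(NA_integer_, n, m)
  h2 <- matrix(NA_integer_, n, m)
  # homozygous and missing-free assignments
  h1[geno == 0L] <- 0L; h2[geno == 0L] <- 0L
  h1[geno == 2L] <- 1L; h2[geno == 2L] <- 1L

  conflicts <- 0L
  resolved_het <- matrix(FALSE, n, m) # het site with known phase
  if (!is.null(pedigree)) {
    sire <- pedigree$sire_id[match(animals, pedigree$animal_id)]
    dam <- pedigree$dam_id[match(animals, pedigree$animal_id)]
    si <- match(sire, animals); di <- match(dam, animals)
    for (i in seq_len(n)) {
      gs <- if (!is.na(si[i])) geno[si[i], ] else rep(NA_integer_, m)
      gd <- if (!is.na(di[i])) geno[di[i], ] else rep(NA_integer_, m)
      gc_ <- geno[i, ]
      # hard Mendelian conflicts: opposite homozygotes, or het impossible
      bad <- (!is.na(gc_) & !is.na(gs) & abs(gc_ - gs) == 2L) |
        (!is.na(gc_) & !is.na(gd) & abs(gc_ - gd) == 2L) |
        (!is.na(gc_) & gc_ == 1L & !is.na(gs) & !is.na(gd) & gs == gd &
           gs %in% c(0L, 2L))
      if (any(bad)) {
        conflicts <- conflicts + sum(bad)
        geno[i, bad] <- NA_integer_
        h1[i, bad] <- NA_integer_; h2[i, bad] <- NA_integer_
        gc_ <- geno[i, ]
      }
      het <- !is.na(gc_) & gc_ == 1L
      # dam homozygous -> maternal allele known
      mhom <- het & !is.na(gd) & gd %in% c(0L, 2L)
      h1[i, mhom] <- as.integer(gd[mhom] / 2L)
      h2[i, mhom] <- 1L - h1[i, mhom]
      # else sire homozygous -> paternal allele known
      phom <- het & !mhom & !is.na(gs) & gs %in% c(0L, 2L)
      h2[i, phom] <- as.integer(gs[phom] / 2L)
      h1[i, phom] <- 1L - h2[i, phom]
      resolved_het[i, mhom | phom] <- TRUE
    }
  }

  # frequency-guided greedy extension for remaining heterozygotes
  for (i in seq_len(n)) {
    todo <- which(!is.na(geno[i, ]) & geno[i, ] == 1L & is.na(h1[i, ]))
    for (s in todo) {
      prev <- which(!is.na(h1[i, seq_len(s - 1L)]) &
                      !is.na(h2[i, seq_len(s - 1L)]))
      prev <- prev[prev >= s - window]
      orient <- 0L
      if (length(prev)) {
        t <- max(prev)
        # two-site haplotype counts at (t, s) over animals resolved at both
        ok <- !is.na(h1[, t]) & !is.na(h1[, s]) & !is.na(h2[, t]) & !is.na(h2[, s])
        if (any(ok)) {
          at <- c(h1[ok, t], h2[ok, t]); as_ <- c(h1[ok, s], h2[ok, s])
          n11 <- sum(at == h1[i, t] & as_ == 1L) + sum(at == h2[i, t] & as_ == 0L)
          n10 <- sum(at == h1[i, t] & as_ == 0L) + sum(at == h2[i, t] & as_ == 1L)
          orient <- if (n11 > n10) 1L else 0L
        }
      }
      h1[i, s] <- orient; h2[i, s] <- 1L - orient
    }
  }

  # impute remaining missing alleles to the major allele
  al <- matrix(NA_integer_, 2L * n, m)
  al[seq(1L, 2L * n, 2L), ] <- h1
  al[seq(2L, 2L * n, 2L), ] <- h2
  f <- colMeans(al, na.rm = TRUE)
  maj <- as.integer(!is.na(f) & f > 0.5)
  idx <- which(is.na(al), arr.ind = TRUE)
  if (nrow(idx)) al[idx] <- maj[idx[, 2L]]
  out <- haplotype_panel(animals, al, phased = TRUE)
  attr(out, "n_mendel_conflicts") <- conflicts
  out
}
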