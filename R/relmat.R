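#' Genome-wide unified additive relationship (UAR) matrix
#'
#' Off-diagonals are `A_jk = (1/N) sum_i (x_ij - 2p_i)(x_ik - 2p_i) /
#' (2 p_i (1 - p_i))`; diagonals are `A_jj = 1 + (1/N) sum_i (x_ij^2 -
#' (1 + 2p_i) x_ij + 2 p_i^2) / (2 p_i (1 - p_i))`. Missing genotypes are
#' imputed to `2 p_i` for this computation only (standard mean imputation for
#' relationship matrices).
#'
#' @param geno Genotype dosage matrix (animals x SNPs, 0/1/2/NA).
#' @param allele_freqs Optional per-SNP frequencies of allele 1; estimated
#'   from the sample when omitted. Frequencies of 0 or 1 are an error
#'   (monomorphic SNPs must be pre-filtered).
#' @return n x n symmetric matrix of class `matrix` with animal dimnames.
#' @export
uar_matrix <- function(geno, allele_freqs = NULL) {
  stopifnot(is.matrix(geno))
  p <- if (is.null(allele_freqs)) colMeans(geno, na.rm = TRUE) / 2 else allele_freqs
  if (length(p) != ncol(geno)) stop("allele_freqs length must equal SNP count")
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("SNP with allele frequency 0 or 1: monomorphic SNPs must be pre-filtered")
  N <- ncol(geno)
  x <- geno
  na <- which(is.na(x), arr.ind = TRUE)
  if (nrow(na)) x[na] <- 2 * p[na[, 2L]]
  d <- 2 * p * (1 - p)
  z <- sweep(x, 2L, 2 * p, "-")
  z <- sweep(z, 2L, sqrt(d), "/")
  A <- tcrossprod(z) / N
  # diagonal uses its own estimator
  diagv <- 1 + rowSums(sweep(x^2 - sweep(x, 2L, 1 + 2 * p, "*"),
                             2L, 2 * p^2, "+") / rep(d, each = nrow(x))) / N
  diag(A) <- diagv
  dimnames(A) <- list(rownames(geno), rownames(geno))
  A
}

#' Principal components of a relationship matrix
#'
#' @param uar Symmetric relationship matrix.
#' @param tol Symmetry tolerance.
#' @return List of class `pc_set`: `eigenvalues` (descending), `components`
#'   (unit-norm eigenvectors, one column per component), `k_retained`
#'   (`NA` until set by the caller, e.g. from [horn_retain()]).
#' @export
uar_pca <- function(uar, tol = 1e-8) {
  stopifnot(is.matrix(uar), nrow(uar) == ncol(uar))
  if (max(abs(uar - t(uar))) > tol) stop("input matrix is not symmetric")
  e <- eigen((uar + t(uar)) / 2, symmetric = TRUE)
  structure(list(eigenvalues = e$values, components = e$vectors,
                 k_retained = NA_integer_),
            class = "pc_set")
}

#' Horn's parallel analysis on the UAR eigenvalue spectrum
#'
#' For each of `n_perm` replicates, every SNP's genotype column is permuted
#' independently across animals, the UAR matrix rebuilt and its spectrum
#' recorded. The retained count is the number of leading components whose
#' observed eigenvalue exceeds the given percentile of the permuted
#' eigenvalues at the same rank.
#'
#' @param geno Genotype dosage matrix (animals x SNPs, 0/1/2/NA).
#' @param n_perm Number of permutation replicates (>= 30).
#' @param percentile Percentile of the null spectrum (default 95).
#' @param seed Integer seed.
#' @return Integer count of retained principal components.
#' @export
horn_retain <- function(geno, n_perm = 100L, percentile = 95, seed = 1L) {
  stopifnot(is.matrix(geno))
  if (nrow(geno) < 3L) stop("need at least 3 animals")
  if (n_perm < 30L) stop("n_perm must be at least 30")
  set.seed(as.integer(seed))
  obs <- eigen(uar_matrix(geno), symmetric = TRUE, only.values = TRUE)$values
  n <- nrow(geno)
  null_eigs <- matrix(0, n_perm, n)
  for (r in seq_len(n_perm)) {
    gp <- permute_columns(geno)
    null_eigs[r, ] <- eigen(uar_matrix(gp), symmetric = TRUE,
                            only.values = TRUE)$values
  }
  thr <- apply(null_eigs, 2L, stats::quantile, probs = percentile / 100,
               names = FALSE)
  above <- obs > thr
  if (!above[1L]) return(0L)
  which.min(c(above, FALSE)) - 1L
}
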