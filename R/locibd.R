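#' Coalescent prior parameters for locus-IBD estimation
#'
#' The prior probability that two random haplotypes are identical by descent
#' at a point is `phi = 1 - (1 - 1/(2 Ne))^T`, for effective population size
#' `Ne` and `T` generations to the base population. Defaults give
#' `phi ~ 0.049`, typical for a closed livestock breed.
#'
#' @param Ne Effective population size (> 0).
#' @param T Generations to the base population (> 0).
#' @return List of class `ibd_params` with `Ne`, `T`, `phi`.
#' @export
ibd_params <- function(Ne = 100, T = 10) {
  stopifnot(Ne > 0, T > 0)
  phi <- 1 - (1 - 1 / (2 * Ne))^T
  structure(list(Ne = Ne, T = T, phi = phi), class = "ibd_params")
}

#' Sliding windows of consecutive SNPs
#'
#' @param map Marker map (snp, chrom, bp, morgans).
#' @param size Window size in SNPs (default 40).
#' @param step Start offset between windows in SNPs (default 1).
#' @return Data frame with one row per window: `index`, `first_snp`,
#'   `last_snp` (inclusive indices into `map`), `midpoint_bp` (floor of the
#'   mean base-pair position of the two SNPs flanking the window midpoint)
#'   and `midpoint_morgans` (their mean genetic position).
#' @export
make_windows <- function(map, size = 40L, step = 1L) {
  check_marker_map(map)
  m <- nrow(map)
  if (m < size) stop(sprintf("map has %d SNPs, need at least %d", m, size))
  starts <- seq(1L, m - size + 1L, by = step)
  left <- starts + size %/% 2L - 1L # 20th SNP of the span for size 40
  right <- left + 1L
  data.frame(index = seq_along(starts), first_snp = starts,
             last_snp = starts + size - 1L,
             midpoint_bp = floor((map$bp[left] + map$bp[right]) / 2),
             midpoint_morgans = (map$morgans[left] + map$morgans[right]) / 2)
}

#' Locus-IBD probability for one haplotype pair at a window midpoint
#'
#' Two-hypothesis estimator: with identity-by-state runs of `L` markers
#' immediately left and `R` markers immediately right of the midpoint,
#' the IBD-survival term is `s = exp(-2 T d)` with `d` the genetic span of the
#' run, the chance-IBS term is the product of population homozygosities
#' `h_i = f_i^2 + (1 - f_i)^2` over run markers, and the posterior is
#' `phi * s / (phi * s + (1 - phi) * c)`. With no flanking IBS the value is
#' the prior `phi`.
#'
#' @param hapA,hapB 0/1 allele vectors over the full map (no missing alleles
#'   within the window; impute first).
#' @param window One row of [make_windows()] output.
#' @param map Marker map.
#' @param freqs Per-SNP frequencies of allele 1.
#' @param params An [ibd_params()].
#' @return IBD probability in (0, 1).
#' @export
locibd_pair <- function(hapA, hapB, window, map, freqs, params = ibd_params()) {
  span <- window$first_snp:window$last_snp
  if (anyNA(hapA[span]) || anyNA(hapB[span]))
    stop("missing allele within window: impute before locus-IBD estimation")
  half <- length(span) %/% 2L
  leftcols <- rev(span[seq_len(half)])
  rightcols <- span[(half + 1L):length(span)]
  runlen <- function(cols) {
    eq <- hapA[cols] == hapB[cols]
    if (!eq[1L]) return(0L)
    which.min(c(eq, FALSE)) - 1L
  }
  L <- runlen(leftcols)
  R <- runlen(rightcols)
  mid_m <- window$midpoint_morgans
  d <- (if (L > 0L) mid_m - map$morgans[leftcols[L]] else 0) +
    (if (R > 0L) map$morgans[rightcols[R]] - mid_m else 0)
  run_idx <- c(if (L > 0L) leftcols[seq_len(L)], if (R > 0L) rightcols[seq_len(R)])
  h <- freqs[run_idx]^2 + (1 - freqs[run_idx])^2
  s <- exp(-2 * params$T * d)
  cc <- prod(h)
  phi <- params$phi
  phi * s / (phi * s + (1 - phi) * cc)
}

#' Locus-IBD matrix over all haplotype pairs of a panel
#'
#' Two estimators are available behind the same interface. The default
#' `"multipoint"` estimator uses every window marker probabilistically:
#' with `a_i = exp(-2 T d_i)` the probability that a midpoint IBD segment
#' still covers marker `i` at genetic distance `d_i`, a marker is
#' identical-by-state with probability `a_i + (1 - a_i) h_i` under midpoint
#' IBD and `h_i` otherwise (`h_i` the population homozygosity); treating
#' markers as independent gives a likelihood ratio `R` and posterior
#' `phi R / (phi R + 1 - phi)`. It varies smoothly as the window slides,
#' which the likelihood-ratio profile and its drop-off intervals need.
#' The `"runs"` estimator is the flanking identity-by-state run closed form
#' of [locibd_pair()], kept as the simpler reference. The diagonal is 1.
#'
#' @param panel Phased [haplotype_panel()] without missing alleles in the
#'   window (impute first, e.g. [impute_panel()]).
#' @param window One row of [make_windows()] output.
#' @param map Marker map.
#' @param freqs Per-SNP frequencies of allele 1; defaults to panel
#'   frequencies.
#' @param params An [ibd_params()].
#' @param method `"multipoint"` (default) or `"runs"`.
#' @return 2n x 2n symmetric matrix of IBD probabilities, unit diagonal.
#' @export
locibd_matrix <- function(panel, window, map, freqs = NULL,
                          params = ibd_params(),
                          method = c("multipoint", "runs")) {
  method <- match.arg(method)
  stopifnot(inherits(panel, "haplotype_panel"))
  if (!panel$phased) stop("panel must be phased")
  if (is.null(freqs)) freqs <- panel_freqs(panel)
  H <- panel$alleles
  span <- window$first_snp:window$last_snp
  if (anyNA(H[, span]))
    stop("missing allele within window: impute before locus-IBD estimation")
  nh <- nrow(H)
  half <- length(span) %/% 2L
  leftcols <- rev(span[seq_len(half)])
  rightcols <- span[(half + 1L):length(span)]

  mid_m <- window$midpoint_morgans
  h <- freqs^2 + (1 - freqs)^2
  if (method == "runs") {
    logh <- log(h)
    return(locibd_fill(H, leftcols, rightcols,
                       mid_m - map$morgans[leftcols],
                       map$morgans[rightcols] - mid_m,
                       c(0, cumsum(logh[leftcols])),
                       c(0, cumsum(logh[rightcols])),
                       params$T, params$phi))
  }
  a <- exp(-2 * params$T * abs(map$morgans[span] - mid_m))
  hs <- h[span]
  lr1 <- log(a + (1 - a) * hs) - log(hs)
  lr0 <- log1p(-a)
  locibd_fill_mp(H, span, lr1, lr0, params$phi)
}

#' Convert a locus-IBD matrix into a diplotype relationship matrix
#'
#' For animals j != k with haplotypes (j1, j2), (k1, k2):
#' `D_jk = (M[j1,k1] + M[j1,k2] + M[j2,k1] + M[j2,k2]) / 2` and
#' `D_jj = 1 + M[j1,j2]`. If the smallest eigenvalue falls below `min_eigen`
#' a diagonal ridge of `min_eigen - lambda_min` is added so that downstream
#' REML always sees an invertible covariance; the amount is recorded in the
#' `ridge` attribute and the (ridged) eigendecomposition in the `eigen`
#' attribute.
#'
#' @param M 2n x 2n locus-IBD matrix, haplotype rows paired per animal.
#' @param min_eigen Positive-definiteness floor (default 1e-6).
#' @return n x n symmetric matrix with attributes `ridge` and `eigen`.
#' @export
drm_from_locibd <- function(M, min_eigen = 1e-6) {
  stopifnot(is.matrix(M))
  if (nrow(M) %% 2L != 0L) stop("locus-IBD matrix must have an even dimension")
  i1 <- seq(1L, nrow(M), by = 2L)
  i2 <- i1 + 1L
  D <- (M[i1, i1, drop = FALSE] + M[i1, i2, drop = FALSE] +
          M[i2, i1, drop = FALSE] + M[i2, i2, drop = FALSE]) / 2
  diag(D) <- 1 + M[cbind(i1, i2)]
  D <- (D + t(D)) / 2
  e <- sym_eigen(D)
  ridge <- 0
  if (e$values[length(e$values)] < min_eigen) {
    ridge <- min_eigen - e$values[length(e$values)]
    D <- D + diag(ridge, nrow(D))
    e$values <- e$values + ridge
  }
  attr(D, "ridge") <- ridge
  attr(D, "eigen") <- e
  D
}
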