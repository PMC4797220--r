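# per-SNP case-consensus used by the homozygosity scans:
# a SNP is "compatible" when every case is non-missing and homozygous for the
# same allele; returns that allele and the -log10 control-frequency score
.case_consensus <- function(cases, controls, map) {
  stopifnot(is.matrix(cases), is.matrix(controls))
  if (ncol(cases) != ncol(controls)) stop("cases and controls must share the SNP set")
  if (!is.null(colnames(cases)) && !is.null(colnames(controls)) &&
      !identical(colnames(cases), colnames(controls)))
    stop("cases and controls must share the SNP set")
  all0 <- colSums(cases == 0L, na.rm = TRUE) == nrow(cases) &
    colSums(is.na(cases)) == 0L
  all2 <- colSums(cases == 2L, na.rm = TRUE) == nrow(cases) &
    colSums(is.na(cases)) == 0L
  compat <- all0 | all2
  allele <- ifelse(all2, 1L, 0L) # allele code whose homozygote is shared
  p1 <- colMeans(controls, na.rm = TRUE) / 2 # control freq of allele 1
  f <- ifelse(allele == 1L, p1, 1 - p1)
  eps <- 1 / (2 * nrow(controls) + 2)
  f[is.nan(f)] <- eps
  score <- -log10(pmax(f, eps))
  list(compat = compat, allele = allele, score = score)
}

#' Case-control homozygosity scan
#'
#' Identifies maximal runs of consecutive SNPs at which every case animal is
#' homozygous for one identical allele per SNP, and scores each run as
#' `sum_i -log10(max(f_i, eps))`, where `f_i` is the shared allele's
#' frequency among controls and `eps = 1/(2 n_controls + 2)`. Rarer and
#' longer shared homozygosity scores higher. A missing case genotype
#' terminates any run through it.
#'
#' @param cases Genotype dosage matrix of case animals (animals x SNPs,
#'   0/1/2/NA); at least 2 rows.
#' @param controls Genotype dosage matrix of control animals over the same
#'   SNPs; at least 1 row.
#' @param map Marker map aligned with the genotype columns.
#' @return Data frame of runs sorted by descending score: `start_bp`,
#'   `end_bp`, `first_snp`, `last_snp`, `n_snps`, `score`, with the per-run
#'   shared alleles in the `alleles` attribute (list of 0/1 vectors).
#' @export
asshom_scan <- function(cases, controls, map) {
  if (nrow(cases) < 2L) stop("need at least 2 cases")
  if (nrow(controls) < 1L) stop("need at least 1 control")
  check_marker_map(map)
  cons <- .case_consensus(cases, controls, map)
  r <- rle(cons$compat)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  if (!any(keep)) {
    out <- data.frame(start_bp = numeric(0), end_bp = numeric(0),
                      first_snp = integer(0), last_snp = integer(0),
                      n_snps = integer(0), score = numeric(0))
    attr(out, "alleles") <- list()
    return(out)
  }
  starts <- starts[keep]; ends <- ends[keep]
  score <- vapply(seq_along(starts),
                  function(k) sum(cons$score[starts[k]:ends[k]]), numeric(1))
  out <- data.frame(start_bp = map$bp[starts], end_bp = map$bp[ends],
                    first_snp = starts, last_snp = ends,
                    n_snps = ends - starts + 1L, score = score)
  ord <- order(-out$score)
  alleles <- lapply(ord, function(k) cons$allele[starts[k]:ends[k]])
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "alleles") <- alleles
  out
}

#' Flag case animals that break the strongest homozygosity run
#'
#' Phenocopy diagnostics for homozygosity mapping. A run score with every
#' case forced in collapses as soon as one misdiagnosed animal is included,
#' so the scan is repeated allowing up to `k` case animals to be incompatible
#' with the run: for every candidate run (maximum-score window such that at
#' most `k` cases mismatch the per-SNP majority homozygous allele), the
#' incompatible animals are reported with their mismatch counts, together
#' with the leave-one-out gain (top [asshom_scan()] score after excluding
#' that single animal minus the all-case top score). With `k = 1` this
#' reduces to plain leave-one-out ranking. Missing genotypes never count as
#' mismatches.
#'
#' @param cases Genotype dosage matrix of case animals (>= 3 rows, animal ids
#'   as rownames).
#' @param controls Control genotype matrix over the same SNPs.
#' @param map Marker map.
#' @param k Maximum number of case animals allowed to be incompatible
#'   (candidates reported, up to `k`).
#' @return Data frame ordered by descending mismatch count: `animal_id`,
#'   `n_mismatch` (mismatching SNPs within the top budgeted run),
#'   `loo_top_score`, `gain`. Empty for `k = 0`. The top budgeted run is in
#'   the `run` attribute (`first_snp`, `last_snp`, `start_bp`, `end_bp`,
#'   `score`).
#' @export
drop_incompatible_cases <- function(cases, controls, map, k = 1L) {
  if (nrow(cases) < 3L) stop("need at least 3 cases")
  if (is.null(rownames(cases))) stop("cases must have animal ids as rownames")
  check_marker_map(map)
  empty <- data.frame(animal_id = character(0), n_mismatch = integer(0),
                      loo_top_score = numeric(0), gain = numeric(0))
  if (k == 0L) return(empty)
  m <- ncol(cases); nc <- nrow(cases)

  # per-SNP majority homozygous allele among cases
  n0 <- colSums(cases == 0L, na.rm = TRUE)
  n2 <- colSums(cases == 2L, na.rm = TRUE)
  allele <- ifelse(n2 > n0, 1L, 0L)
  target <- 2L * allele
  mism <- sweep(cases, 2L, target, "!=")
  mism[is.na(mism)] <- FALSE # missing is not evidence against an animal

  p1 <- colMeans(controls, na.rm = TRUE) / 2
  f <- ifelse(allele == 1L, p1, 1 - p1)
  eps <- 1 / (2 * nrow(controls) + 2)
  f[is.nan(f)] <- eps
  score <- -log10(pmax(f, eps))

  # max-score window with at most k incompatible animals (sliding window;
  # the incompatible set only grows as a window extends)
  cnt <- integer(nc)
  nviol <- 0L
  best <- list(score = -Inf, lo = NA_integer_, hi = NA_integer_)
  lo <- 1L
  wscore <- 0
  for (hi in seq_len(m)) {
    hit <- which(mism[, hi])
    for (a in hit) {
      cnt[a] <- cnt[a] + 1L
      if (cnt[a] == 1L) nviol <- nviol + 1L
    }
    wscore <- wscore + score[hi]
    while (nviol > k) {
      drop_ <- which(mism[, lo])
      for (a in drop_) {
        cnt[a] <- cnt[a] - 1L
        if (cnt[a] == 0L) nviol <- nviol - 1L
      }
      wscore <- wscore - score[lo]
      lo <- lo + 1L
    }
    if (wscore > best$score) best <- list(score = wscore, lo = lo, hi = hi)
  }
  span <- best$lo:best$hi
  n_mis <- rowSums(mism[, span, drop = FALSE])
  flagged <- which(n_mis > 0L)
  if (!length(flagged)) {
    attr(empty, "run") <- data.frame(first_snp = best$lo, last_snp = best$hi,
                                     start_bp = map$bp[best$lo],
                                     end_bp = map$bp[best$hi],
                                     score = best$score)
    return(empty)
  }
  flagged <- flagged[order(-n_mis[flagged])]
  flagged <- utils::head(flagged, k)

  base_top <- asshom_scan(cases, controls, map)
  base_score <- if (nrow(base_top)) base_top$score[1L] else 0
  loo <- vapply(flagged, function(a) {
    sc <- asshom_scan(cases[-a, , drop = FALSE], controls, map)
    if (nrow(sc)) sc$score[1L] else 0
  }, numeric(1))
  out <- data.frame(animal_id = rownames(cases)[flagged],
                    n_mismatch = n_mis[flagged],
                    loo_top_score = loo, gain = loo - base_score,
                    row.names = NULL)
  attr(out, "run") <- data.frame(first_snp = best$lo, last_snp = best$hi,
                                 start_bp = map$bp[best$lo],
                                 end_bp = map$bp[best$hi], score = best$score)
  out
}

#' Extract the common disease haplotype around an anchor position
#'
#' Starting from the SNP nearest `anchor_bp`, extends left and right the
#' maximal interval over which (a) all affected animals are homozygous for
#' identical alleles and (b) every carrier has at least one haplotype
#' matching those alleles over the whole interval (`exact_one = TRUE`
#' requires exactly one matching haplotype per carrier, the classic obligate
#' carrier configuration).
#'
#' @param affected Phased [haplotype_panel()] of affected animals.
#' @param carriers Phased [haplotype_panel()] of carrier animals.
#' @param map Marker map aligned with both panels.
#' @param anchor_bp Anchor base-pair position within the map range.
#' @param exact_one Require exactly one matching haplotype per carrier.
#' @return List of class `common_haplotype`: `start_bp`, `end_bp`,
#'   `first_snp`, `last_snp`, `n_snps`, `alleles` (0/1 vector over the
#'   interval), `carrier_copies` (data frame animal_id, n_copies).
#' @export
common_haplotype <- function(affected, carriers, map, anchor_bp,
                             exact_one = FALSE) {
  stopifnot(inherits(affected, "haplotype_panel"),
            inherits(carriers, "haplotype_panel"))
  if (!affected$phased || !carriers$phased) stop("panels must be phased")
  check_marker_map(map)
  if (anchor_bp < map$bp[1L] || anchor_bp > map$bp[nrow(map)])
    stop("anchor_bp outside map range")
  A <- affected$alleles; C <- carriers$alleles
  a1 <- seq(1L, nrow(A), 2L)
  j0 <- which.min(abs(map$bp - anchor_bp))

  snp_consensus <- function(j) {
    hom <- A[a1, j] == A[a1 + 1L, j]
    if (anyNA(hom) || !all(hom)) {
      bad <- which(is.na(hom) | !hom)[1L]
      return(list(ok = FALSE, who = affected$animals[bad]))
    }
    al <- A[a1, j]
    if (length(unique(al)) != 1L)
      return(list(ok = FALSE, who = affected$animals[which(al != al[1L])[1L]]))
    list(ok = TRUE, allele = al[1L])
  }

  carriers_ok <- function(match_state) {
    per <- match_state[c(TRUE, FALSE)] + match_state[c(FALSE, TRUE)]
    if (exact_one) all(per == 1L) else all(per >= 1L)
  }

  cs0 <- snp_consensus(j0)
  if (!cs0$ok)
    stop(sprintf("no common haplotype even at the anchor SNP: animal %s violates",
                 cs0$who))
  match_state <- C[, j0] == cs0$allele
  if (!carriers_ok(match_state)) {
    per <- match_state[c(TRUE, FALSE)] + match_state[c(FALSE, TRUE)]
    bad <- carriers$animals[which(if (exact_one) per != 1L else per < 1L)[1L]]
    stop(sprintf("no common haplotype even at the anchor SNP: animal %s violates", bad))
  }
  alleles <- stats::setNames(cs0$allele, map$snp[j0])
  lo <- hi <- j0
  extend <- function(j, match_state) {
    cs <- snp_consensus(j)
    if (!cs$ok) return(NULL)
    ms <- match_state & (C[, j] == cs$allele)
    if (!carriers_ok(ms)) return(NULL)
    list(allele = cs$allele, match_state = ms)
  }
  ms <- match_state
  while (hi < nrow(map)) {
    step <- extend(hi + 1L, ms)
    if (is.null(step)) break
    hi <- hi + 1L; ms <- step$match_state
    alleles <- c(alleles, stats::setNames(step$allele, map$snp[hi]))
  }
  while (lo > 1L) {
    step <- extend(lo - 1L, ms)
    if (is.null(step)) break
    lo <- lo - 1L; ms <- step$match_state
    alleles <- c(stats::setNames(step$allele, map$snp[lo]), alleles)
  }
  per <- ms[c(TRUE, FALSE)] + ms[c(FALSE, TRUE)]
  structure(list(start_bp = map$bp[lo], end_bp = map$bp[hi],
                 first_snp = lo, last_snp = hi, n_snps = hi - lo + 1L,
                 alleles = alleles,
                 carrier_copies = data.frame(animal_id = carriers$animals,
                                             n_copies = as.integer(per),
                                             row.names = NULL)),
            class = "common_haplotype")
}

#' @export
print.common_haplotype <- function(x, ...) {
  cat(sprintf("common_haplotype: %d SNPs, %.0f-%.0f bp\n",
              x$n_snps, x$start_bp, x$end_bp))
  invisible(x)
}
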