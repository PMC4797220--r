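#' Construct a haplotype panel
#'
#' A haplotype panel stores two phased (or unphased) haplotypes per animal as
#' rows of a 0/1 allele matrix aligned to a marker map. Rows `2j - 1` and `2j`
#' belong to animal `j`; missing alleles are `NA`.
#'
#' @param animals Character vector of animal ids, one per individual.
#' @param alleles Integer/numeric matrix with `2 * length(animals)` rows and
#'   one column per SNP, entries in `{0, 1, NA}`.
#' @param phased Logical flag; `TRUE` when row order within an animal carries
#'   phase information.
#' @return An object of class `haplotype_panel`.
#' @export
haplotype_panel <- function(animals, alleles, phased = TRUE) {
  animals <- as.character(animals)
  alleles <- as.matrix(alleles)
  if (nrow(alleles) != 2L * length(animals))
    stop("alleles must have exactly two rows per animal")
  ok <- alleles %in% c(0L, 1L) | is.na(alleles)
  if (!all(ok)) stop("alleles must be coded 0/1/NA")
  storage.mode(alleles) <- "integer"
  rownames(alleles) <- paste0(rep(animals, each = 2L), c("_1", "_2"))
  structure(list(animals = animals, alleles = alleles, phased = isTRUE(phased)),
            class = "haplotype_panel")
}

#' @export
print.haplotype_panel <- function(x, ...) {
  cat(sprintf("haplotype_panel: %d animals x %d SNPs (%s)\n",
              length(x$animals), ncol(x$alleles),
              if (x$phased) "phased" else "unphased"))
  invisible(x)
}

#' Collapse a haplotype panel to 0/1/2 genotype dosages
#'
#' @param panel A [haplotype_panel()].
#' @return Integer matrix, animals x SNPs, counting copies of allele 1;
#'   `NA` where either haplotype allele is missing.
#' @export
geno_from_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$alleles
  i1 <- seq(1L, nrow(h), by = 2L)
  g <- h[i1, , drop = FALSE] + h[i1 + 1L, , drop = FALSE]
  rownames(g) <- panel$animals
  g
}

#' Allele-1 frequencies of a panel
#'
#' @param panel A [haplotype_panel()].
#' @return Numeric vector of per-SNP frequencies of allele 1 over non-missing
#'   haplotypes.
#' @export
panel_freqs <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  colMeans(panel$alleles, na.rm = TRUE)
}

#' Fill missing panel alleles with the major allele
#'
#' Downstream locus-IBD estimation requires complete haplotypes; this is the
#' minimal imputation used when no phasing step is run.
#'
#' @param panel A [haplotype_panel()].
#' @return The panel with every `NA` allele replaced by the per-SNP major
#'   allele (ties resolved to allele 0).
#' @export
impute_panel <- function(panel) {
  stopifnot(inherits(panel, "haplotype_panel"))
  h <- panel$alleles
  f <- colMeans(h, na.rm = TRUE)
  maj <- as.integer(f > 0.5)
  idx <- which(is.na(h), arr.ind = TRUE)
  if (nrow(idx)) h[idx] <- maj[idx[, 2L]]
  panel$alleles <- h
  panel
}

#' Subset a panel by animal ids
#'
#' @param panel A [haplotype_panel()].
#' @param ids Animal ids to keep, in the requested order.
#' @param snps Optional SNP column indices to keep.
#' @return A [haplotype_panel()] restricted to `ids` (and `snps`).
#' @export
subset_panel <- function(panel, ids, snps = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  j <- match(ids, panel$animals)
  if (anyNA(j)) stop("unknown animal id(s): ", paste(ids[is.na(j)], collapse = ", "))
  rows <- as.vector(rbind(2L * j - 1L, 2L * j))
  al <- panel$alleles[rows, , drop = FALSE]
  if (!is.null(snps)) al <- al[, snps, drop = FALSE]
  haplotype_panel(ids, al, phased = panel$phased)
}

# marker map validation shared by several entry points
check_marker_map <- function(map) {
  need <- c("snp", "chrom", "bp", "morgans")
  if (!is.data.frame(map) || !all(need %in% names(map)))
    stop("marker map needs columns snp, chrom, bp, morgans")
  for (ch in unique(map$chrom)) {
    b <- map$bp[map$chrom == ch]
    if (is.unsorted(b, strictly = TRUE)) stop("bp must be strictly increasing within chrom")
    if (is.unsorted(map$morgans[map$chrom == ch]))
      stop("morgans must be non-decreasing within chrom")
  }
  invisible(map)
}
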