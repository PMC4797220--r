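#' Carrier-concordance filtering of sequence variants
#'
#' Restricts a variant table to a mapped interval and keeps variants for
#' which every declared carrier is heterozygous while every other animal is
#' homozygous for the reference allele. Missing genotypes in non-carriers are
#' treated as violations in `strict` mode and as compatible (but counted) in
#' `lenient` mode; variants with any missing carrier genotype are excluded in
#' both modes. Variants violating the pattern in at most `max_violations`
#' animals are reported as near-misses for diagnostics.
#'
#' @param vt A `variant_table`.
#' @param carrier_ids Non-empty character vector of carrier animal ids, all
#'   present in the table.
#' @param region Numeric `c(start_bp, end_bp)` (1-based closed interval).
#' @param mode `"lenient"` (default) or `"strict"` missing-genotype policy.
#' @param max_violations Near-miss reporting cap (default 2).
#' @return List of class `concordance_result`: `kept` (variant data frame),
#'   `near_misses` (variant id, n_violations, violating animal ids),
#'   `n_missing_lenient` (missing non-carrier genotypes accepted in lenient
#'   mode), `mode`, `region`.
#' @export
concordance_filter <- function(vt, carrier_ids, region,
                               mode = c("lenient", "strict"),
                               max_violations = 2L) {
  stopifnot(inherits(vt, "variant_table"), length(region) == 2L)
  mode <- match.arg(mode)
  if (region[1] > region[2]) stop("empty region")
  if (!length(carrier_ids)) stop("carrier_ids must be non-empty")
  missing_ids <- setdiff(carrier_ids, vt$animals)
  if (length(missing_ids))
    stop("unknown carrier id(s): ", paste(missing_ids, collapse = ", "))
  inreg <- vt$variants$pos >= region[1] & vt$variants$pos <= region[2]
  variants <- vt$variants[inreg, , drop = FALSE]
  geno <- vt$geno[inreg, , drop = FALSE]
  is_carrier <- vt$animals %in% carrier_ids

  kept <- logical(nrow(variants))
  nviol <- integer(nrow(variants))
  violators <- vector("list", nrow(variants))
  n_missing_lenient <- 0L
  for (v in seq_len(nrow(variants))) {
    g <- geno[v, ]
    carrier_missing <- any(is.na(g[is_carrier]))
    bad_carrier <- !is.na(g[is_carrier]) & g[is_carrier] != 1L
    g_nc <- g[!is_carrier]
    if (mode == "strict") {
      bad_nc <- is.na(g_nc) | g_nc != 0L
    } else {
      bad_nc <- !is.na(g_nc) & g_nc != 0L
      n_missing_lenient <- n_missing_lenient + sum(is.na(g_nc))
    }
    nviol[v] <- sum(bad_carrier) + sum(bad_nc)
    violators[[v]] <- c(vt$animals[is_carrier][bad_carrier],
                        vt$animals[!is_carrier][bad_nc])
    kept[v] <- nviol[v] == 0L && !carrier_missing
  }
  nm <- which(!kept & nviol >= 1L & nviol <= max_violations)
  structure(list(kept = variants[kept, , drop = FALSE],
                 near_misses = data.frame(
                   id = variants$id[nm], n_violations = nviol[nm],
                   violating_animals = vapply(violators[nm], paste,
                                              character(1), collapse = ","),
                   stringsAsFactors = FALSE),
                 n_missing_lenient = n_missing_lenient,
                 mode = mode, region = region),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat(sprintf("concordance_result (%s): %d kept, %d near-miss(es)\n",
              x$mode, nrow(x$kept), nrow(x$near_misses)))
  invisible(x)
}

#' Allele-frequency report from monitoring genotype counts
#'
#' Per-stratum and pooled alternative-allele frequency
#' `(n_het + 2 n_hom_alt) / (2 n_genotyped)`, reported in percent rounded to
#' two decimals (exact rational arithmetic before rounding).
#'
#' @param counts Data frame with columns `stratum`, `n_genotyped`, `n_het`,
#'   and optionally `n_hom_alt` (0 when absent).
#' @return Data frame with the input counts, `allele_freq_percent`, and a
#'   final `pooled` row. Strata with `n_genotyped = 0` are skipped with a
#'   warning.
#' @export
allele_frequency <- function(counts) {
  stopifnot(is.data.frame(counts),
            all(c("stratum", "n_genotyped", "n_het") %in% names(counts)))
  if (!"n_hom_alt" %in% names(counts)) counts$n_hom_alt <- 0L
  with(counts, stopifnot(all(n_genotyped >= 0), all(n_het >= 0),
                         all(n_hom_alt >= 0),
                         all(n_het + n_hom_alt <= n_genotyped)))
  zero <- counts$n_genotyped == 0
  if (any(zero)) {
    warning(sprintf("stratum with no genotyped animals skipped: %s",
                    paste(counts$stratum[zero], collapse = ", ")))
    counts <- counts[!zero, , drop = FALSE]
  }
  pooled <- data.frame(stratum = "pooled",
                       n_genotyped = sum(counts$n_genotyped),
                       n_het = sum(counts$n_het),
                       n_hom_alt = sum(counts$n_hom_alt))
  out <- rbind(counts[, names(pooled)], pooled)
  out$allele_freq_percent <-
    round(100 * (out$n_het + 2 * out$n_hom_alt) / (2 * out$n_genotyped), 2)
  rownames(out) <- NULL
  out
}

#' Carrier frequency and carrier-mating risk under Hardy-Weinberg
#'
#' For deleterious-allele frequency `q`, the carrier frequency is
#' `2 q (1 - q)` and the probability that a random mating pairs two carriers
#' and produces an affected offspring is `(2 q (1 - q))^2 / 4`.
#'
#' @param q Allele frequency as a proportion in `[0, 1]`.
#' @return List with `carrier_freq` and `risk_affected_offspring`.
#' @export
mating_risk <- function(q) {
  if (!is.numeric(q) || length(q) != 1L || is.na(q) || q < 0 || q > 1)
    stop("q must be a single proportion in [0, 1]")
  cf <- 2 * q * (1 - q)
  list(carrier_freq = cf, risk_affected_offspring = cf^2 / 4)
}
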