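#' SNP and animal quality control
#'
#' Applies, in order of precedence, the exclusion criteria of a chip-based
#' mapping study: (1) missingness above `max_missing`; (2) Mendelian-conflict
#' rate among checkable parent-offspring pairs above `max_conflict_rate`;
#' (3) unknown or ambiguous map position; (4) observed heterozygosity below
#' `min_het`; (5) chromosome other than `target_chrom`. Each dropped SNP is
#' assigned the first applicable reason. Animal call rates are reported and
#' animals below `min_call_rate` flagged, not removed.
#'
#' @param geno Genotype dosage matrix (animals x SNPs, 0/1/2/NA, animal ids as
#'   rownames, SNP ids as colnames) or a [haplotype_panel()].
#' @param map Marker map (snp, chrom, bp, morgans); SNPs absent from the map
#'   are dropped with reason `no_map_position`.
#' @param pedigree Optional pedigree (animal_id, sire_id, dam_id). Pairs whose
#'   parent is not genotyped are skipped; a single warning reports how many
#'   pedigree ids were absent from the genotypes.
#' @param target_chrom Chromosome retained for analysis.
#' @param max_missing Maximum tolerated SNP missingness (default 0.05).
#' @param max_conflict_rate Maximum Mendelian-conflict rate (default 0.01).
#' @param min_het Minimum observed heterozygosity (default 0.05).
#' @param min_call_rate Animal call-rate flagging threshold (default 0.95).
#' @return A list of class `qc_report`: `kept_snps`, `dropped` (snp_id,
#'   reason), `flagged_animals` (animal_id, call_rate), `animal_call_rates`.
#' @export
filter_snps <- function(geno, map, pedigree = NULL, target_chrom,
                        max_missing = 0.05, max_conflict_rate = 0.01,
                        min_het = 0.05, min_call_rate = 0.95) {
  if (inherits(geno, "haplotype_panel")) geno <- geno_from_panel(geno)
  if (!is.matrix(geno) || is.null(colnames(geno)) || is.null(rownames(geno)))
    stop("geno must be a matrix with animal rownames and SNP colnames")
  if (nrow(geno) == 0L || ncol(geno) == 0L) stop("empty genotype input")
  check_marker_map(map)
  snps <- colnames(geno)

  miss <- colMeans(is.na(geno))
  conflict_rate <- rep(0, ncol(geno))
  if (!is.null(pedigree)) {
    pr <- pedigree[pedigree$animal_id %in% rownames(geno), , drop = FALSE]
    pairs <- rbind(
      data.frame(child = pr$animal_id, parent = pr$sire_id),
      data.frame(child = pr$animal_id, parent = pr$dam_id))
    pairs <- pairs[pairs$parent != "0", , drop = FALSE]
    absent <- setdiff(unique(pairs$parent), rownames(geno))
    if (length(absent))
      warning(sprintf("%d pedigree parent id(s) absent from genotypes; pairs skipped",
                      length(absent)))
    pairs <- pairs[pairs$parent %in% rownames(geno), , drop = FALSE]
    if (nrow(pairs)) {
      gc_ <- geno[pairs$child, , drop = FALSE]
      gp_ <- geno[pairs$parent, , drop = FALSE]
      checkable <- !is.na(gc_) & !is.na(gp_)
      conflict <- checkable & abs(gc_ - gp_) == 2L # opposite homozygotes
      n_chk <- colSums(checkable)
      conflict_rate <- ifelse(n_chk > 0L, colSums(conflict) / n_chk, 0)
    }
  }
  pos <- map$bp[match(snps, map$snp)]
  chrom <- map$chrom[match(snps, map$snp)]
  no_pos <- is.na(pos)
  het <- colMeans(geno == 1L, na.rm = TRUE)
  het[is.nan(het)] <- 0

  reason <- rep(NA_character_, length(snps))
  reason[is.na(reason) & miss > max_missing] <- "missingness"
  reason[is.na(reason) & conflict_rate > max_conflict_rate] <- "paternity_conflict"
  reason[is.na(reason) & no_pos] <- "no_map_position"
  reason[is.na(reason) & het < min_het] <- "low_heterozygosity"
  reason[is.na(reason) & !is.na(chrom) & chrom != target_chrom] <- "off_target_chrom"

  call_rate <- rowMeans(!is.na(geno))
  flagged <- data.frame(animal_id = rownames(geno)[call_rate < min_call_rate],
                        call_rate = call_rate[call_rate < min_call_rate],
                        stringsAsFactors = FALSE, row.names = NULL)
  structure(list(kept_snps = snps[is.na(reason)],
                 dropped = data.frame(snp_id = snps[!is.na(reason)],
                                      reason = reason[!is.na(reason)],
                                      stringsAsFactors = FALSE),
                 flagged_animals = flagged,
                 animal_call_rates = stats::setNames(call_rate, rownames(geno))),
            class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("qc_report: %d kept, %d dropped, %d animal(s) flagged\n",
              length(x$kept_snps), nrow(x$dropped), nrow(x$flagged_animals)))
  if (nrow(x$dropped)) print(table(x$dropped$reason))
  invisible(x)
}

#' Encode diagnostic status records into quantitative phenotypes
#'
#' Maps the diagnostic evidence classes onto the quantitative scale used by
#' the variance-component model: free animals 1.0, progeny-confirmed carriers
#' 2.0, pathologically confirmed affected 3.0, and clinically-confirmed-only
#' animals interpolated by pedigree evidence (2.75 when confirmed carrier
#' ancestors are present on both sides within two generations, 2.5 with an
#' interval of three or more generations, 2.25 with a single official carrier
#' in the pedigree, 2.0 with missing pedigree data).
#'
#' @param status Data frame with `animal_id`, `diagnosis` in
#'   `free | carrier_progeny | affected_path | affected_clinical`, and
#'   `carrier_ancestor_evidence` (required exactly when diagnosis is
#'   `affected_clinical`) in `both_sides_within_2 | gap_3plus_generations |
#'   single_official_carrier | missing_pedigree`.
#' @return Named numeric phenotype vector y, one value per record.
#' @export
encode_phenotypes <- function(status) {
  stopifnot(is.data.frame(status),
            all(c("animal_id", "diagnosis") %in% names(status)))
  ev <- if ("carrier_ancestor_evidence" %in% names(status))
    status$carrier_ancestor_evidence else rep(NA_character_, nrow(status))
  base <- c(free = 1.0, carrier_progeny = 2.0, affected_path = 3.0)
  clin <- c(both_sides_within_2 = 2.75, gap_3plus_generations = 2.5,
            single_official_carrier = 2.25, missing_pedigree = 2.0)
  y <- numeric(nrow(status))
  for (i in seq_len(nrow(status))) {
    d <- status$diagnosis[i]
    if (d %in% names(base)) {
      if (!is.na(ev[i]))
        stop(sprintf("record %s: carrier_ancestor_evidence only allowed for affected_clinical",
                     status$animal_id[i]))
      y[i] <- base[[d]]
    } else if (d == "affected_clinical") {
      if (is.na(ev[i]) || !ev[i] %in% names(clin))
        stop(sprintf("record %s: affected_clinical requires valid carrier_ancestor_evidence",
                     status$animal_id[i]))
      y[i] <- clin[[ev[i]]]
    } else {
      stop(sprintf("record %s: unknown diagnosis '%s'", status$animal_id[i], d))
    }
  }
  stats::setNames(y, status$animal_id)
}
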