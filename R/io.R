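#' Write a haplotype panel as PLINK-style ped/map files
#'
#' Alleles are written as 1/2 (allele 0 -> "1", allele 1 -> "2", missing ->
#' "0"), two per SNP, in haplotype order (first allele = first haplotype), so
#' a phased panel round-trips through [read_plink()].
#'
#' @param panel A [haplotype_panel()].
#' @param map Marker map data frame (snp, chrom, bp, morgans).
#' @param prefix Output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @param pedigree Optional pedigree (animal_id, sire_id, dam_id); unknown
#'   parents written as 0.
#' @return Invisibly, the two file paths.
#' @export
write_plink <- function(panel, map, prefix, pedigree = NULL) {
  stopifnot(inherits(panel, "haplotype_panel"))
  check_marker_map(map)
  h <- panel$alleles
  code <- function(x) ifelse(is.na(x), "0", as.character(x + 1L))
  n <- length(panel$animals)
  sire <- dam <- rep("0", n)
  if (!is.null(pedigree)) {
    i <- match(panel$animals, pedigree$animal_id)
    sire <- ifelse(is.na(i), "0", pedigree$sire_id[i])
    dam <- ifelse(is.na(i), "0", pedigree$dam_id[i])
  }
  g1 <- code(h[seq(1L, nrow(h), 2L), , drop = FALSE])
  g2 <- code(h[seq(2L, nrow(h), 2L), , drop = FALSE])
  gcols <- matrix("", n, 2L * ncol(h))
  gcols[, seq(1L, ncol(gcols), 2L)] <- g1
  gcols[, seq(2L, ncol(gcols), 2L)] <- g2
  ped <- data.table::data.table(fid = "FAM1", iid = panel$animals,
                                sire = sire, dam = dam, sex = 0L, pheno = -9L)
  ped <- cbind(ped, data.table::as.data.table(gcols))
  data.table::fwrite(ped, paste0(prefix, ".ped"), sep = " ", col.names = FALSE)
  mp <- data.frame(chrom = map$chrom, snp = map$snp,
                   cm = map$morgans * 100, bp = map$bp)
  data.table::fwrite(mp, paste0(prefix, ".map"), sep = " ", col.names = FALSE)
  invisible(c(paste0(prefix, ".ped"), paste0(prefix, ".map")))
}

#' Read PLINK-style ped/map files
#'
#' @param prefix Path prefix of `<prefix>.ped` / `<prefix>.map`.
#' @param phased Whether the allele order within each SNP carries phase.
#' @return List with `panel` ([haplotype_panel()]), `map`, and `pedigree`.
#' @export
read_plink <- function(prefix, phased = FALSE) {
  mp <- data.table::fread(paste0(prefix, ".map"), header = FALSE)
  data.table::setnames(mp, c("chrom", "snp", "cm", "bp"))
  map <- data.frame(snp = as.character(mp$snp), chrom = as.character(mp$chrom),
                    bp = as.numeric(mp$bp), morgans = mp$cm / 100,
                    stringsAsFactors = FALSE)
  pd <- data.table::fread(paste0(prefix, ".ped"), header = FALSE,
                          colClasses = "character")
  m <- nrow(map)
  if (ncol(pd) != 6L + 2L * m) stop("ped/map column mismatch")
  animals <- pd[[2L]]
  g <- as.matrix(pd[, -(1:6), with = FALSE])
  decode <- function(x) {
    out <- suppressWarnings(as.integer(x)) - 1L
    out[out < 0L] <- NA_integer_
    out
  }
  a1 <- decode(g[, seq(1L, ncol(g), 2L), drop = FALSE])
  a2 <- decode(g[, seq(2L, ncol(g), 2L), drop = FALSE])
  al <- matrix(NA_integer_, 2L * length(animals), m)
  al[seq(1L, nrow(al), 2L), ] <- a1
  al[seq(2L, nrow(al), 2L), ] <- a2
  pedigree <- data.frame(animal_id = animals, sire_id = pd[[3L]],
                         dam_id = pd[[4L]], stringsAsFactors = FALSE)
  list(panel = haplotype_panel(animals, al, phased = phased), map = map,
       pedigree = pedigree)
}

#' Write a variant table as VCF 4.2
#'
#' @param vt A `variant_table` (see [make_variant_table()]).
#' @param path Output file path (plain text).
#' @return Invisibly, `path`.
#' @export
write_variant_vcf <- function(vt, path) {
  stopifnot(inherits(vt, "variant_table"))
  gt <- matrix("./.", nrow(vt$geno), ncol(vt$geno))
  gt[vt$geno == 0L] <- "0/0"
  gt[vt$geno == 1L] <- "0/1"
  gt[vt$geno == 2L] <- "1/1"
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", vt$animals), collapse = "\t"))
  body <- apply(cbind(vt$variants$chrom, format(vt$variants$pos, scientific = FALSE,
                                                trim = TRUE),
                      vt$variants$id, vt$variants$ref, vt$variants$alt,
                      ".", "PASS", paste0("TYPE=", vt$variants$type), "GT", gt),
                1L, paste, collapse = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a biallelic VCF (GT field) into a variant table
#'
#' Uses vcfR for parsing; both phased (`|`) and unphased (`/`) genotype
#' separators are accepted. Multi-allelic records must be split upstream.
#'
#' @param path VCF file path.
#' @return A `variant_table`.
#' @export
read_variant_vcf <- function(path) {
  if (!requireNamespace("vcfR", quietly = TRUE))
    stop("package vcfR is required to read VCF files")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (any(grepl(",", fix[, "ALT"]))) stop("multi-allelic records must be split upstream")
  gt <- vcfR::extract.gt(v, element = "GT")
  count_alt <- function(x) {
    a <- strsplit(gsub("\\|", "/", x), "/", fixed = TRUE)
    vapply(a, function(p) {
      if (length(p) < 2L || any(p == ".")) return(NA_integer_)
      sum(p != "0")
    }, integer(1))
  }
  geno <- t(apply(gt, 1L, count_alt))
  if (nrow(gt) == 1L) geno <- matrix(geno, nrow = 1L, dimnames = dimnames(gt))
  variants <- data.frame(id = as.character(fix[, "ID"]),
                         chrom = as.character(fix[, "CHROM"]),
                         pos = as.numeric(fix[, "POS"]),
                         ref = as.character(fix[, "REF"]),
                         alt = as.character(fix[, "ALT"]),
                         type = ifelse(nchar(fix[, "REF"]) == 1L &
                                         nchar(fix[, "ALT"]) == 1L, "SNP", "indel"),
                         stringsAsFactors = FALSE)
  ord <- order(variants$chrom, variants$pos)
  geno <- geno[ord, , drop = FALSE]
  variants <- variants[ord, , drop = FALSE]
  rownames(geno) <- variants$id
  storage.mode(geno) <- "integer"
  structure(list(variants = variants, geno = geno, animals = colnames(geno)),
            class = "variant_table")
}

#' Write a data frame as a headered TSV
#'
#' @param x Data frame.
#' @param path Output path.
#' @param comment Optional comment lines written first, prefixed with `#`.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a headered TSV written by [write_tsv()]
#'
#' @param path File path.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE)
}
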