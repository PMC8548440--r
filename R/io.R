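#' Read a multi-sample VCF into the internal genotype model
#'
#' Parses a VCF 4.x file (plain or gzipped) with `vcfR`, keeps biallelic
#' autosomal SNPs only, and returns an alt-coded [geno_matrix()] plus a
#' partial site table (`chrom, pos, ref, alt` and, when present in the
#' genotype fields, per-genotype `DP`/`GQ` matrices for QC masking).
#'
#' @param path VCF path.
#' @param panel optional panel data frame; every panel sample must be in
#'   the VCF and the matrix is restricted (and ordered) to panel samples.
#' @param sex_chroms chromosome labels treated as sex chromosomes and
#'   dropped.
#' @return List with `gm` (alt-coded `geno_matrix`, with `dp`/`gq`
#'   matrices attached when the VCF carries them), `sites` (data frame
#'   `chrom, pos, ref, alt`), and `dropped` (named counts of records
#'   removed as indel / multiallelic / sex-chromosome).
#' @export
read_vcf <- function(path, panel = NULL,
                     sex_chroms = c("X", "Y", "chrX", "chrY", "23", "24")) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(vcf@gt) == 0 || !any(grepl("GT", vcf@gt[, "FORMAT"])))
    stop("VCF has no GT field")
  fix <- as.data.frame(vcf@fix, stringsAsFactors = FALSE)
  ref <- fix$REF
  alt <- fix$ALT
  is_multi <- grepl(",", alt, fixed = TRUE)
  is_indel <- (nchar(ref) != 1L | nchar(alt) != 1L) & !is_multi
  is_sex <- fix$CHROM %in% sex_chroms
  keep <- !(is_multi | is_indel | is_sex)
  dropped <- c(indel = sum(is_indel & !is_sex),
               multiallelic = sum(is_multi & !is_sex),
               sex_chromosome = sum(is_sex))
  if (!any(keep)) stop("no biallelic autosomal SNPs retained from VCF")
  vcf <- vcf[keep, ]
  fix <- fix[keep, , drop = FALSE]

  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  if (!is.null(panel)) {
    missing <- setdiff(panel$sample_id, samples)
    if (length(missing))
      stop("panel sample(s) absent from VCF: ", paste(missing, collapse = ", "))
    gt <- gt[, panel$sample_id, drop = FALSE]
    samples <- panel$sample_id
  }
  dosage <- t(gt_to_dosage(gt))

  gm <- geno_matrix(dosage, samples, polarized = FALSE)
  fmt <- vcf@gt[1, "FORMAT"]
  for (el in c("DP", "GQ")) {
    if (grepl(el, fmt)) {
      m <- suppressWarnings(
        vcfR::extract.gt(vcf, element = el, as.numeric = TRUE))
      m <- t(m[, samples, drop = FALSE])
      gm[[tolower(el)]] <- m
    }
  }
  sites <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                      ref = ref[keep], alt = alt[keep],
                      stringsAsFactors = FALSE)
  list(gm = gm, sites = sites, dropped = dropped)
}

# GT strings (sites x samples) -> integer alt dosage; any missing allele -> NA
gt_to_dosage <- function(gt) {
  d <- matrix(NA_integer_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  a1 <- substr(gt, 1, 1)
  a2 <- substr(gt, 3, 3)
  ok <- a1 %in% c("0", "1") & a2 %in% c("0", "1")
  d[ok] <- (a1[ok] == "1") + (a2[ok] == "1")
  d
}

#' Write a genotype matrix back to a plain-text VCF 4.2 file
#'
#' Genotypes are written alt-coded; a polarized matrix is converted back
#' using the site table's ancestral alleles so that a written file
#' re-read with [read_vcf()] reproduces the original records.
#'
#' @param gm a [geno_matrix()].
#' @param sites site table aligned with `gm` columns (needs `chrom, pos,
#'   ref, alt`; `ancestral` too when `gm` is polarized).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, sites, path) {
  d <- gm$dosage
  if (gm$polarized) {
    if (is.null(sites$ancestral)) stop("polarized matrix needs sites$ancestral")
    flip <- which(sites$ancestral == sites$alt)
    d[, flip] <- 2L - d[, flip]
  }
  gt_chr <- matrix("./.", nrow(d), ncol(d))
  gt_chr[!is.na(d) & d == 0L] <- "0/0"
  gt_chr[!is.na(d) & d == 1L] <- "0/1"
  gt_chr[!is.na(d) & d == 2L] <- "1/1"
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", gm$sample_ids), collapse = "\t"))
  body <- paste(sites$chrom, sites$pos, ".", sites$ref, sites$alt, ".",
                "PASS", ".", "GT",
                apply(gt_chr, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}
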