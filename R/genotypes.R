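#' Genotype matrix container
#'
#' A `geno_matrix` holds a samples x sites matrix of allele dosages in
#' `{0, 1, 2, NA}` together with sample identifiers and a flag saying
#' whether dosages count derived alleles (after [polarize()]) or ALT
#' alleles (straight from the VCF).
#'
#' @param dosage integer matrix, samples in rows, sites in columns;
#'   values 0/1/2/`NA`.
#' @param sample_ids character vector of row labels.
#' @param polarized logical; `TRUE` once dosages count derived alleles.
#' @return An object of class `geno_matrix`: a list with elements
#'   `dosage`, `sample_ids`, `polarized`.
#' @export
geno_matrix <- function(dosage, sample_ids = rownames(dosage), polarized = FALSE) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  if (is.null(sample_ids)) stop("sample_ids required")
  if (length(sample_ids) != nrow(dosage)) stop("sample_ids length != nrow(dosage)")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  rownames(dosage) <- sample_ids
  structure(list(dosage = dosage, sample_ids = sample_ids,
                 polarized = isTRUE(polarized)),
            class = "geno_matrix")
}

#' @export
print.geno_matrix <- function(x, ...) {
  cat(sprintf("geno_matrix: %d samples x %d sites (%s)\n",
              nrow(x$dosage), ncol(x$dosage),
              if (x$polarized) "derived-coded" else "alt-coded"))
  invisible(x)
}

#' @export
dim.geno_matrix <- function(x) dim(x$dosage)

n_sites <- function(gm) ncol(gm$dosage)
n_samples <- function(gm) nrow(gm$dosage)

#' Subset a genotype matrix
#'
#' @param gm a [geno_matrix()].
#' @param samples row selector (indices, logical, or sample ids); `NULL` keeps all.
#' @param sites column selector; `NULL` keeps all.
#' @return A `geno_matrix` restricted to the selection.
#' @export
gm_subset <- function(gm, samples = NULL, sites = NULL) {
  d <- gm$dosage
  if (!is.null(samples)) d <- d[samples, , drop = FALSE]
  if (!is.null(sites))   d <- d[, sites, drop = FALSE]
  geno_matrix(d, rownames(d), polarized = gm$polarized)
}

#' Rows of a genotype matrix belonging to one population
#'
#' @param gm a [geno_matrix()].
#' @param panel data frame with columns `sample_id`, `population`.
#' @param population population label.
#' @return Integer row indices into `gm$dosage`.
#' @export
pop_rows <- function(gm, panel, population) {
  ids <- panel$sample_id[panel$population == population]
  idx <- which(gm$sample_ids %in% ids)
  if (!length(idx)) stop("population not present in genotype matrix: ", population)
  idx
}

#' Per-site allele-count summaries for a set of samples
#'
#' For each site returns the summed dosage (`dac`, the derived/alt allele
#' count), the number of non-missing haplotypes (`an`, twice the called
#' diploids), and the heterozygote count (`het`).
#'
#' @param gm a [geno_matrix()].
#' @param rows integer row indices (default: all samples).
#' @return List of numeric vectors `dac`, `an`, `het`, each of length
#'   `ncol(gm$dosage)`.
#' @export
site_counts <- function(gm, rows = seq_len(nrow(gm$dosage))) {
  d <- gm$dosage[rows, , drop = FALSE]
  called <- !is.na(d)
  list(dac = colSums(d, na.rm = TRUE),
       an  = 2 * colSums(called),
       het = colSums(d == 1L, na.rm = TRUE))
}

#' Derived allele frequency per site within a population
#'
#' q = (sum of derived dosages) / (2 x non-missing diploids). Sites where
#' every genotype is missing get `NA`, never zero.
#'
#' @param gm a polarized [geno_matrix()].
#' @param panel population panel data frame.
#' @param population population label; `NULL` uses all samples.
#' @return Numeric vector of frequencies in `[0, 1]` (or `NA`).
#' @export
derived_freq <- function(gm, panel = NULL, population = NULL) {
  if (!gm$polarized) stop("derived_freq requires a polarized genotype matrix")
  rows <- if (is.null(population)) seq_len(nrow(gm$dosage))
          else pop_rows(gm, panel, population)
  sc <- site_counts(gm, rows)
  q <- ifelse(sc$an > 0, sc$dac / sc$an, NA_real_)
  as.numeric(q)
}

#' Read a sample-to-population panel file
#'
#' @param path two-column TSV (`sample_id`, `population`), with or without
#'   a header line.
#' @return Data frame with columns `sample_id`, `population`.
#' @export
read_panel <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("sample", tolower(first))
  df <- if (header)
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("sample_id", "population"))
  names(df)[1:2] <- c("sample_id", "population")
  if (anyDuplicated(df$sample_id)) stop("duplicated sample_id in panel")
  df[, c("sample_id", "population")]
}

#' Read a per-site annotation table
#'
#' Expects a header TSV with columns `chrom, pos, ref, alt, ancestral,
#' gene, consequence, gerp_rs` and optionally `cadd, polyphen`.
#'
#' @param path TSV path.
#' @return Data frame keyed by (`chrom`, `pos`).
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, quote = "",
                          na.strings = c("NA", ""))
  need <- c("chrom", "pos", "ref", "alt", "ancestral", "gene",
            "consequence", "gerp_rs")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing columns: ",
                         paste(miss, collapse = ", "))
  if (is.null(df$cadd)) df$cadd <- NA_real_
  if (is.null(df$polyphen)) df$polyphen <- NA_character_
  df$chrom <- as.character(df$chrom)
  df$gene[is.na(df$gene)] <- ""
  df
}

#' Read a gene-set catalog
#'
#' @param path TSV with columns `set_name`, `gene` (one row per
#'   membership), with or without a header.
#' @return Named list mapping set name to a character vector of genes.
#' @export
read_catalog <- function(path) {
  first <- readLines(path, n = 1)
  header <- grepl("set|trait", tolower(first))
  df <- if (header)
    utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
  else
    utils::read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE,
                      col.names = c("set_name", "gene"))
  names(df)[1:2] <- c("set_name", "gene")
  split(df$gene, df$set_name)
}

# join annotation rows onto a site table by (chrom, pos); errors on sites
# absent from the annotation
annotate_sites <- function(sites, annot) {
  key_s <- paste(sites$chrom, sites$pos)
  key_a <- paste(annot$chrom, annot$pos)
  idx <- match(key_s, key_a)
  if (anyNA(idx)) stop(sum(is.na(idx)), " sites missing from annotation table")
  add <- annot[idx, c("ancestral", "gene", "consequence", "gerp_rs",
                      "cadd", "polyphen")]
  rownames(add) <- NULL
  cbind(sites, add)
}
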