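#' Variant- and sample-level QC thresholds
#'
#' Defaults follow standard exome practice for small-cohort population
#' comparisons: genotypes below 5x depth or GQ 20 are set missing, sites
#' with more than 5% missingness or a Hardy-Weinberg exact p below 1e-3
#' in any population are removed, samples with over 10% missingness or
#' heterozygosity outside 4 SD of their population mean are removed.
#'
#' @param min_depth minimum per-genotype read depth (DP).
#' @param min_gq minimum per-genotype phred quality (GQ).
#' @param max_site_missingness maximum fraction of missing genotypes per site.
#' @param hwe_alpha Hardy-Weinberg exact-test significance level; a site
#'   failing in at least one population is removed.
#' @param max_sample_missingness maximum fraction of missing genotypes per sample.
#' @param het_sd_range allowed heterozygosity range, in population SDs.
#' @return A list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_depth = 5, min_gq = 20,
                          max_site_missingness = 0.05, hwe_alpha = 1e-3,
                          max_sample_missingness = 0.10, het_sd_range = 4) {
  stopifnot(min_depth > 0, min_gq > 0, het_sd_range > 0, hwe_alpha > 0,
            max_site_missingness > 0, max_site_missingness <= 1,
            max_sample_missingness > 0, max_sample_missingness <= 1)
  structure(list(min_depth = min_depth, min_gq = min_gq,
                 max_site_missingness = max_site_missingness,
                 hwe_alpha = hwe_alpha,
                 max_sample_missingness = max_sample_missingness,
                 het_sd_range = het_sd_range),
            class = "qc_thresholds")
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Conditional exact test on observed genotype counts: the p-value sums,
#' over all heterozygote counts compatible with the observed allele
#' counts, the hypergeometric-type probabilities not exceeding that of
#' the observed configuration (the enumeration approach standard for
#' small samples, rather than the chi-square approximation).
#'
#' @param n_aa,n_ab,n_bb genotype counts (hom-ref, het, hom-alt).
#' @return Two-sided exact p-value.
#' @export
hwe_exact_test <- function(n_aa, n_ab, n_bb) {
  n <- n_aa + n_ab + n_bb
  if (n == 0) return(1)
  n_a <- 2 * n_aa + n_ab          # minor/major labelling is irrelevant
  rare <- min(n_a, 2 * n - n_a)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  # log P(het = h | allele counts), up to a constant in the allele counts:
  # n! / (n_rr! n_het! n_cc!) * 2^het, with n_rr = (rare - h)/2 rare homs
  lp <- lfactorial(n) - lfactorial((rare - hets) / 2) - lfactorial(hets) -
    lfactorial(n - (rare + hets) / 2) + hets * log(2)
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- which(hets == n_ab)
  if (!length(obs)) return(1)     # inconsistent counts; be permissive
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

hwe_p_vector <- function(dac, an, het) {
  n <- an / 2
  n_bb <- (dac - het) / 2
  n_aa <- n - het - n_bb
  vapply(seq_along(dac), function(i) {
    if (n[i] < 1) return(1)
    hwe_exact_test(n_aa[i], het[i], n_bb[i])
  }, numeric(1))
}

#' Site-level quality-control filter
#'
#' Applies, in order: per-genotype masking (genotypes with DP below
#' `min_depth` or GQ below `min_gq` set to missing, when those matrices
#' are available), then removal of sites that are monomorphic across the
#' pooled dataset, exceed the site-missingness ceiling, or fail the exact
#' Hardy-Weinberg test at `hwe_alpha` in at least one panel population.
#'
#' @param gm alt- or derived-coded [geno_matrix()] (optionally carrying
#'   `dp`/`gq` matrices from [read_vcf()]).
#' @param sites aligned site table.
#' @param panel population panel data frame.
#' @param thr a [qc_thresholds()] object.
#' @return List with filtered `gm`, `sites`, and `report` — per-rule
#'   removal counts plus flags for skipped sub-filters.
#' @export
qc_filter_sites <- function(gm, sites, panel, thr = qc_thresholds()) {
  d <- gm$dosage
  masked <- 0L
  skipped <- character(0)
  if (!is.null(gm$dp)) {
    low <- !is.na(gm$dp) & gm$dp < thr$min_depth & !is.na(d)
    d[low] <- NA_integer_
    masked <- masked + sum(low)
  } else skipped <- c(skipped, "depth")
  if (!is.null(gm$gq)) {
    low <- !is.na(gm$gq) & gm$gq < thr$min_gq & !is.na(d)
    d[low] <- NA_integer_
    masked <- masked + sum(low)
  } else skipped <- c(skipped, "gq")
  gm$dosage <- d

  sc <- site_counts(gm)
  mono <- sc$dac == 0 | sc$dac == sc$an
  miss <- colMeans(is.na(d)) > thr$max_site_missingness

  hwe_fail <- rep(FALSE, ncol(d))
  for (pop in unique(panel$population)) {
    rows <- pop_rows(gm, panel, pop)
    pc <- site_counts(gm, rows)
    test <- !mono & !miss & !hwe_fail     # only sites still in play
    if (any(test)) {
      p <- rep(1, ncol(d))
      p[test] <- hwe_p_vector(pc$dac[test], pc$an[test], pc$het[test])
      hwe_fail <- hwe_fail | (p < thr$hwe_alpha)
    }
  }
  drop <- mono | miss | hwe_fail
  if (all(drop)) stop("all sites removed by QC")
  report <- list(
    genotypes_masked = masked,
    skipped_subfilters = skipped,
    removed = c(monomorphic = sum(mono),
                missingness = sum(miss & !mono),
                hwe = sum(hwe_fail & !mono & !miss)),
    n_in = ncol(d), n_out = sum(!drop))
  gm$dp <- if (!is.null(gm$dp)) gm$dp[, !drop, drop = FALSE]
  gm$gq <- if (!is.null(gm$gq)) gm$gq[, !drop, drop = FALSE]
  out <- gm_subset(gm, sites = !drop)
  out$dp <- gm$dp; out$gq <- gm$gq
  list(gm = out, sites = sites[!drop, , drop = FALSE], report = report)
}

#' Sample-level quality-control filter
#'
#' Removes samples whose genotype missingness exceeds
#' `max_sample_missingness` or whose heterozygosity (het genotypes over
#' non-missing genotypes) falls outside mean +/- `het_sd_range` SD of
#' their own population. A population with zero heterozygosity SD flags
#' no outliers.
#'
#' @inheritParams qc_filter_sites
#' @return List with filtered `gm`, updated `panel`, and `report` naming
#'   each dropped sample and the rule that removed it.
#' @export
qc_filter_samples <- function(gm, panel, thr = qc_thresholds()) {
  if (nrow(gm$dosage) < 3) stop("need at least 3 samples")
  d <- gm$dosage
  miss_frac <- rowMeans(is.na(d))
  het <- rowSums(d == 1L, na.rm = TRUE) / rowSums(!is.na(d))

  drop_reason <- setNames(rep(NA_character_, nrow(d)), gm$sample_ids)
  drop_reason[miss_frac > thr$max_sample_missingness] <- "missingness"
  for (pop in unique(panel$population)) {
    rows <- pop_rows(gm, panel, pop)
    mu <- mean(het[rows]); sdev <- stats::sd(het[rows])
    if (!is.na(sdev) && sdev > 0) {
      out <- rows[abs(het[rows] - mu) > thr$het_sd_range * sdev]
      drop_reason[out] <- ifelse(is.na(drop_reason[out]), "heterozygosity",
                                 drop_reason[out])
    }
  }
  keep <- is.na(drop_reason)
  if (!any(keep)) stop("all samples removed by QC")
  report <- list(dropped = drop_reason[!keep],
                 n_in = nrow(d), n_out = sum(keep))
  out <- gm_subset(gm, samples = keep)
  out$dp <- if (!is.null(gm$dp)) gm$dp[keep, , drop = FALSE]
  out$gq <- if (!is.null(gm$gq)) gm$gq[keep, , drop = FALSE]
  list(gm = out, panel = panel[panel$sample_id %in% out$sample_ids, ],
       report = report)
}

#' Polarize genotypes to derived-allele dosages
#'
#' Sites with unknown ancestral allele are removed; where the ancestral
#' allele equals ALT, dosages are flipped (d becomes 2 - d, missing stays
#' missing). Sites whose ancestral allele matches neither REF nor ALT are
#' dropped with a warning.
#'
#' @param gm alt-coded [geno_matrix()].
#' @param sites aligned site table with an `ancestral` column (REF/ALT
#'   base, or `NA`/`"."`/`"N"` for unknown).
#' @return List with polarized `gm`, filtered `sites`, and `report`
#'   (counts of unknown-ancestral and mismatching sites removed, and of
#'   flipped sites).
#' @export
polarize <- function(gm, sites) {
  if (gm$polarized) stop("matrix is already polarized")
  anc <- toupper(as.character(sites$ancestral))
  unknown <- is.na(anc) | anc %in% c(".", "N", "-", "")
  mismatch <- !unknown & anc != toupper(sites$ref) & anc != toupper(sites$alt)
  if (any(mismatch))
    warning(sum(mismatch), " site(s) with ancestral allele matching neither REF nor ALT dropped")
  keep <- !unknown & !mismatch
  if (!any(keep)) stop("no sites with known ancestral allele")
  d <- gm$dosage[, keep, drop = FALSE]
  anc_k <- anc[keep]
  flip <- anc_k == toupper(sites$alt[keep])
  d[, flip] <- 2L - d[, flip]
  out <- geno_matrix(d, gm$sample_ids, polarized = TRUE)
  list(gm = out, sites = sites[keep, , drop = FALSE],
       report = c(unknown_ancestral = sum(unknown),
                  ancestral_mismatch = sum(mismatch),
                  flipped = sum(flip)))
}
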