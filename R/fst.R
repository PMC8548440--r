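#' Per-site Weir & Cockerham Fst between two populations
#'
#' Two-population variance-component estimator from genotype counts,
#' including the observed-heterozygosity correction: per site, the
#' among-population component `a`, the among-individual-within-population
#' component `b` and the within-individual component `c` are computed
#' from the per-population sample sizes, allele frequencies and observed
#' heterozygote proportions; `fst = a / (a + b + c)`. Sites monomorphic
#' across both populations (or with a zero denominator) are `NA`, not
#' zero; per-site values can be negative by sampling.
#'
#' @param gm a [geno_matrix()] (polarization does not affect Fst).
#' @param panel panel data frame.
#' @param popA,popB distinct population labels (no shared samples).
#' @return Data frame: `site` (column index), `a, b, c`, `fst`.
#' @export
per_site_fst <- function(gm, panel, popA, popB) {
  rowsA <- pop_rows(gm, panel, popA)
  rowsB <- pop_rows(gm, panel, popB)
  if (length(intersect(rowsA, rowsB)))
    stop("populations share samples; Fst undefined")
  scA <- site_counts(gm, rowsA)
  scB <- site_counts(gm, rowsB)
  comp <- wc_components(scA$an / 2, scA$dac / pmax(scA$an, 1), scA$het / pmax(scA$an / 2, 1),
                        scB$an / 2, scB$dac / pmax(scB$an, 1), scB$het / pmax(scB$an / 2, 1))
  bad <- scA$an < 4 | scB$an < 4 |
    (scA$dac + scB$dac == 0) | (scA$dac + scB$dac == scA$an + scB$an)
  den <- comp$a + comp$b + comp$c
  fst <- ifelse(!bad & den > 0, comp$a / den, NA_real_)
  data.frame(site = seq_along(fst), a = comp$a, b = comp$b, c = comp$c,
             fst = fst)
}

# Weir & Cockerham (1984) a/b/c for r = 2 populations, vectorized over
# sites; n = diploids, p = allele frequency, h = observed het proportion
wc_components <- function(n1, p1, h1, n2, p2, h2) {
  r <- 2
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- (nbar / nc) *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- (nbar / (nbar - 1)) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  c_ <- hbar / 2
  list(a = a, b = b, c = c_)
}

#' Mean pairwise Fst between two populations
#'
#' Ratio-of-sums (weighted) estimator `sum(a) / sum(a + b + c)` over
#' sites with defined components, optionally thinning each population to
#' `n_per_pop` randomly selected individuals.
#'
#' @inheritParams per_site_fst
#' @param n_per_pop optional per-population thinning size.
#' @param seed RNG seed for thinning.
#' @return Numeric mean Fst (`NA` when no site is defined).
#' @export
mean_pairwise_fst <- function(gm, panel, popA, popB, n_per_pop = NULL, seed = 1) {
  if (!is.null(n_per_pop)) {
    rows <- c(draw_subsample(gm, panel, popA, n_per_pop, seed),
              draw_subsample(gm, panel, popB, n_per_pop, seed + 1))
    gm <- gm_subset(gm, samples = rows)
    panel <- panel[panel$sample_id %in% gm$sample_ids, ]
  }
  f <- per_site_fst(gm, panel, popA, popB)
  ok <- !is.na(f$fst)
  if (!any(ok)) return(NA_real_)
  sum(f$a[ok]) / sum(f$a[ok] + f$b[ok] + f$c[ok])
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of dosage vectors over pairwise-complete
#' samples, optionally within one population. Zero-variance sites give
#' `NA`.
#'
#' @param gm a [geno_matrix()].
#' @param site_pairs 2-column matrix of site indices.
#' @param panel,population optional restriction to one population.
#' @return Numeric vector of r-squared values, one per pair.
#' @export
ld_r2 <- function(gm, site_pairs, panel = NULL, population = NULL) {
  site_pairs <- matrix(as.integer(site_pairs), ncol = 2)
  rows <- if (is.null(population)) seq_len(nrow(gm$dosage))
          else pop_rows(gm, panel, population)
  d <- gm$dosage[rows, , drop = FALSE]
  vapply(seq_len(nrow(site_pairs)), function(i) {
    x <- d[, site_pairs[i, 1]]; y <- d[, site_pairs[i, 2]]
    ok <- !is.na(x) & !is.na(y)
    if (sum(ok) < 2 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
      return(NA_real_)
    stats::cor(x[ok], y[ok])^2
  }, numeric(1))
}

#' Fst peak detection
#'
#' A peak is a maximal single-linkage cluster of two or more sites in the
#' top `top_fraction` of the (defined) Fst distribution, on the same
#' chromosome, in which each member lies within `max_pair_distance` bp of
#' at least one other member.
#'
#' @param fst numeric per-site Fst (NA allowed).
#' @param sites site table aligned with `fst`.
#' @param top_fraction upper tail defining candidate sites (default 1%).
#' @param max_pair_distance chaining distance in bp (default 10 kb).
#' @return Data frame: `peak, chrom, start, end, n_sites, sites`
#'   (comma-joined site indices); zero rows when no peak.
#' @export
fst_peaks <- function(fst, sites, top_fraction = 0.01, max_pair_distance = 1e4) {
  ok <- which(!is.na(fst))
  if (!length(ok)) return(empty_peaks())
  thr <- stats::quantile(fst[ok], 1 - top_fraction, names = FALSE)
  top <- ok[fst[ok] >= thr]
  out <- list()
  for (chr in unique(sites$chrom[top])) {
    t_chr <- top[sites$chrom[top] == chr]
    t_chr <- t_chr[order(sites$pos[t_chr])]
    if (length(t_chr) < 2) next
    pos <- sites$pos[t_chr]
    new_cluster <- c(TRUE, diff(pos) >= max_pair_distance)
    grp <- cumsum(new_cluster)
    for (g in split(t_chr, grp)) {
      if (length(g) < 2) next
      out[[length(out) + 1L]] <- data.frame(
        chrom = chr, start = min(sites$pos[g]), end = max(sites$pos[g]),
        n_sites = length(g), sites = paste(g, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out)) return(empty_peaks())
  res <- do.call(rbind, out)
  cbind(peak = seq_len(nrow(res)), res)
}

empty_peaks <- function() {
  data.frame(peak = integer(0), chrom = character(0), start = integer(0),
             end = integer(0), n_sites = integer(0), sites = character(0))
}
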