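#' Site masks by consequence or deleteriousness
#'
#' Convenience selectors over a site table: diversity statistics are
#' conventionally computed on synonymous (putatively neutral) sites,
#' load statistics on deleterious classes.
#'
#' @param sites site table with `consequence` / `gerp_rs` columns.
#' @return Logical vector over sites.
#' @export
mask_synonymous <- function(sites) !is.na(sites$consequence) & sites$consequence == "synonymous"

#' @rdname mask_synonymous
#' @export
mask_missense <- function(sites) !is.na(sites$consequence) & sites$consequence == "missense"

resolve_mask <- function(gm, site_mask) {
  if (is.null(site_mask)) return(seq_len(ncol(gm$dosage)))
  if (is.logical(site_mask)) which(site_mask) else as.integer(site_mask)
}

#' Pairwise nucleotide diversity (theta-pi)
#'
#' Sum over masked sites of the unbiased per-site heterozygosity
#' `2 c (2n - c) / (2n (2n - 1))`, with `c` the derived count and `2n`
#' the non-missing haplotype count at the site. Sites with fewer than two
#' non-missing haplotypes are skipped.
#'
#' @param gm polarized [geno_matrix()].
#' @param panel panel data frame.
#' @param population population label.
#' @param site_mask logical mask or index vector over sites (default all).
#' @return Numeric: summed per-site pi over the mask.
#' @export
theta_pi <- function(gm, panel, population, site_mask = NULL) {
  sum(per_site_pi(gm, panel, population, site_mask), na.rm = TRUE)
}

# per-site pi contributions (NA where < 2 haplotypes called)
per_site_pi <- function(gm, panel, population, site_mask = NULL) {
  idx <- resolve_mask(gm, site_mask)
  sc <- site_counts(gm, pop_rows(gm, panel, population))
  c_ <- sc$dac[idx]; an <- sc$an[idx]
  ifelse(an >= 2, 2 * c_ * (an - c_) / (an * (an - 1)), NA_real_)
}

#' Watterson's estimator of theta
#'
#' `S / a1`, with `S` the number of masked sites segregating within the
#' population and `a1` the harmonic number over `2n - 1`, where `n` is
#' the population's diploid sample size (a single global haplotype count;
#' sites with missing calls still count through their observed state).
#'
#' @inheritParams theta_pi
#' @return Numeric.
#' @export
watterson_theta <- function(gm, panel, population, site_mask = NULL) {
  rows <- pop_rows(gm, panel, population)
  if (length(rows) < 2) stop("watterson_theta needs >= 2 diploids")
  idx <- resolve_mask(gm, site_mask)
  sc <- site_counts(gm, rows)
  S <- sum(sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx])
  S / harmonic(2 * length(rows) - 1)
}

harmonic <- function(k) sum(1 / seq_len(k))

#' Per-variable-site nucleotide diversity (pi-var)
#'
#' Theta-pi restricted to sites variable within the population, divided
#' by the number of those variable sites: the average heterozygosity of a
#' segregating site. Under relaxed purifying selection and drift this
#' moves opposite to theta-pi (fewer segregating sites, but each at more
#' intermediate frequency).
#'
#' @inheritParams theta_pi
#' @return Numeric, or `NA` when no masked site is variable.
#' @export
pi_var <- function(gm, panel, population, site_mask = NULL) {
  idx <- resolve_mask(gm, site_mask)
  sc <- site_counts(gm, pop_rows(gm, panel, population))
  var_site <- sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx]
  if (!any(var_site)) return(NA_real_)
  pi_site <- per_site_pi(gm, panel, population, idx[var_site])
  mean(pi_site, na.rm = TRUE)
}

#' Tajima's D
#'
#' Standardized difference between theta-pi and Watterson's theta using
#' the classical variance constants computed from the population's
#' haplotype count.
#'
#' @inheritParams theta_pi
#' @return Numeric; `NA` when no masked site segregates.
#' @export
tajimas_d <- function(gm, panel, population, site_mask = NULL) {
  rows <- pop_rows(gm, panel, population)
  idx <- resolve_mask(gm, site_mask)
  sc <- site_counts(gm, rows)
  S <- sum(sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx])
  if (S == 0) return(NA_real_)
  tp <- theta_pi(gm, panel, population, idx)
  tw <- watterson_theta(gm, panel, population, idx)
  (tp - tw) / sqrt(tajima_var(2 * length(rows), S))
}

# Var(theta_pi - theta_w) for n haplotypes and S segregating sites
tajima_var <- function(n, S) {
  a1 <- harmonic(n - 1)
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  e1 * S + e2 * S * (S - 1)
}

#' All diversity indexes for one population
#'
#' @inheritParams theta_pi
#' @return One-row data frame: `population, n_hap, s_seg, theta_pi,
#'   theta_w, pi_var, tajimas_d`.
#' @export
diversity_estimates <- function(gm, panel, population, site_mask = NULL) {
  rows <- pop_rows(gm, panel, population)
  idx <- resolve_mask(gm, site_mask)
  sc <- site_counts(gm, rows)
  data.frame(population = population,
             n_hap = 2 * length(rows),
             s_seg = sum(sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx]),
             theta_pi = theta_pi(gm, panel, population, idx),
             theta_w = watterson_theta(gm, panel, population, idx),
             pi_var = pi_var(gm, panel, population, idx),
             tajimas_d = tajimas_d(gm, panel, population, idx),
             stringsAsFactors = FALSE)
}

#' Segregating-site summaries per population
#'
#' For every population: the count of segregating sites `S`
#' (0 < derived count < haplotype count), the count of private
#' segregating sites (segregating there, derived count zero in every
#' other population), and the mean number of segregating sites at which
#' an individual carries at least one derived allele.
#'
#' @param gm polarized [geno_matrix()].
#' @param panel panel data frame.
#' @param site_mask mask over sites (default all).
#' @return Data frame: `population, s_seg, s_private, mean_carried`.
#' @export
segregating_site_summaries <- function(gm, panel, site_mask = NULL) {
  idx <- resolve_mask(gm, site_mask)
  pops <- unique(panel$population)
  seg <- dac <- list()
  for (pop in pops) {
    sc <- site_counts(gm, pop_rows(gm, panel, pop))
    dac[[pop]] <- sc$dac[idx]
    seg[[pop]] <- sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx]
  }
  out <- lapply(pops, function(pop) {
    others <- setdiff(pops, pop)
    absent_elsewhere <- Reduce(`&`, lapply(others, function(o) dac[[o]] == 0),
                               accumulate = FALSE,
                               init = rep(TRUE, length(idx)))
    rows <- pop_rows(gm, panel, pop)
    d <- gm$dosage[rows, idx[seg[[pop]]], drop = FALSE]
    carried <- rowSums(d >= 1L, na.rm = TRUE)
    data.frame(population = pop,
               s_seg = sum(seg[[pop]]),
               s_private = sum(seg[[pop]] & absent_elsewhere),
               mean_carried = mean(carried),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Diversity statistics with block-bootstrap intervals
#'
#' Runs [block_bootstrap()] for theta-pi, Watterson's theta, pi-var and
#' Tajima's D in one or more populations over a shared site mask.
#'
#' @inheritParams segregating_site_summaries
#' @param populations labels to evaluate (default: all in panel).
#' @param n_blocks,n_reps,seed bootstrap controls.
#' @return Data frame: `population, statistic, estimate, lo, hi`.
#' @export
diversity_bootstrap <- function(gm, panel, populations = unique(panel$population),
                                site_mask = NULL, n_blocks = 1000,
                                n_reps = 1000, seed = 1) {
  idx <- resolve_mask(gm, site_mask)
  out <- list()
  for (pop in populations) {
    rows <- pop_rows(gm, panel, pop)
    sc <- site_counts(gm, rows)
    pi_site <- per_site_pi(gm, panel, pop, idx)
    seg <- sc$dac[idx] > 0 & sc$dac[idx] < sc$an[idx]
    a1 <- harmonic(2 * length(rows) - 1)
    n_hap <- 2 * length(rows)
    stats_fns <- list(
      theta_pi = function(j) sum(pi_site[j], na.rm = TRUE),
      theta_w  = function(j) sum(seg[j]) / a1,
      pi_var   = function(j) if (any(seg[j])) mean(pi_site[j][seg[j]], na.rm = TRUE) else NA_real_,
      tajimas_d = function(j) {
        S <- sum(seg[j])
        if (S == 0) return(NA_real_)
        (sum(pi_site[j], na.rm = TRUE) - S / a1) / sqrt(tajima_var(n_hap, S))
      })
    for (nm in names(stats_fns)) {
      b <- block_bootstrap(function(j) stats_fns[[nm]](j), length(idx),
                           n_blocks = n_blocks, n_reps = n_reps, seed = seed)
      out[[length(out) + 1L]] <- data.frame(
        population = pop, statistic = nm, estimate = b$estimate,
        lo = b$lo, hi = b$hi, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}
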