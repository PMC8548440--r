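#' Deleteriousness categorization schemes
#'
#' Maps per-site scores to ordered deleteriousness classes. The `gerp`
#' scheme uses left-closed conservation-score intervals: "neutral"
#' (< 2), "moderate" [2, 4), "large" [4, 6), "extreme" (>= 6). The
#' `polyphen` scheme uses the predictor's labels (benign /
#' possibly_damaging / probably_damaging), excluding "unknown". The
#' `cadd` scheme splits at a configurable phred-score cut.
#'
#' @param name one of `"gerp"`, `"polyphen"`, `"cadd"`.
#' @param cadd_cut phred-score threshold for the `cadd` scheme.
#' @return A `category_scheme` object with `$levels` (ordered labels) and
#'   `$classify(sites)` returning a label per site (`NA` for unscored).
#' @export
category_scheme <- function(name = c("gerp", "polyphen", "cadd"), cadd_cut = 15) {
  name <- match.arg(name)
  scheme <- switch(name,
    gerp = list(
      levels = c("neutral", "moderate", "large", "extreme"),
      classify = function(sites) {
        g <- sites$gerp_rs
        cut_labels(g, breaks = c(-Inf, 2, 4, 6, Inf),
                   labels = c("neutral", "moderate", "large", "extreme"))
      }),
    polyphen = list(
      levels = c("benign", "possibly_damaging", "probably_damaging"),
      classify = function(sites) {
        p <- as.character(sites$polyphen)
        p[!p %in% c("benign", "possibly_damaging", "probably_damaging")] <- NA
        p
      }),
    cadd = list(
      levels = c("tolerated", "deleterious"),
      classify = function(sites) {
        cut_labels(sites$cadd, breaks = c(-Inf, cadd_cut, Inf),
                   labels = c("tolerated", "deleterious"))
      }))
  structure(c(scheme, list(name = name)), class = "category_scheme")
}

# left-closed right-open binning with the last interval closed above
cut_labels <- function(x, breaks, labels) {
  out <- rep(NA_character_, length(x))
  ok <- !is.na(x)
  bin <- findInterval(x[ok], breaks[-c(1, length(breaks))], left.open = FALSE) + 1L
  out[ok] <- labels[bin]
  out
}

# seeded uniform subsample of population rows; shared across categories
draw_subsample <- function(gm, panel, population, n_sub, seed, replace = FALSE) {
  rows <- pop_rows(gm, panel, population)
  if (!replace && length(rows) < n_sub)
    stop(sprintf("population %s has %d individuals; reduce n_sub (= %d)",
                 population, length(rows), n_sub))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  sample(rows, n_sub, replace = replace)
}

#' Unfolded site frequency spectrum for one population
#'
#' Subsamples `n_sub` individuals uniformly without replacement, drops
#' sites with any missing genotype in the subsample, tallies derived
#' allele counts, removes the two fixed bins (0 and `2 n_sub`) and
#' normalizes the rest to densities.
#'
#' @param gm polarized [geno_matrix()].
#' @param panel panel data frame.
#' @param population population label.
#' @param n_sub diploid subsample size.
#' @param seed RNG seed for the subsample draw.
#' @param site_mask mask over sites (default all).
#' @param rows optional pre-drawn row indices (overrides the seeded
#'   draw; used to share one subsample across categories).
#' @return An `sfs` object: `n_sub`, `counts`/`densities` over bins
#'   `1 .. 2 n_sub - 1`, `n_sites` (polymorphic, in-spectrum),
#'   `n_missing_dropped`, `n_fixed_dropped`, `category`.
#' @export
build_sfs <- function(gm, panel, population, n_sub = 8, seed = 1,
                      site_mask = NULL, rows = NULL) {
  if (is.null(rows)) rows <- draw_subsample(gm, panel, population, n_sub, seed)
  idx <- resolve_mask(gm, site_mask)
  d <- gm$dosage[rows, idx, drop = FALSE]
  complete <- colSums(is.na(d)) == 0L
  dac <- colSums(d[, complete, drop = FALSE], na.rm = TRUE)
  nb <- 2L * n_sub
  fixed <- dac == 0L | dac == nb
  tab <- tabulate(dac[!fixed], nbins = nb - 1L)
  counts <- stats::setNames(tab, seq_len(nb - 1L))
  total <- sum(counts)
  structure(list(n_sub = n_sub, counts = counts,
                 densities = if (total > 0) counts / total else counts * NA_real_,
                 n_sites = total,
                 n_missing_dropped = sum(!complete),
                 n_fixed_dropped = sum(fixed),
                 category = NA_character_, rows = rows),
            class = "sfs")
}

#' @export
print.sfs <- function(x, ...) {
  cat(sprintf("unfolded SFS: 2n = %d, %d sites%s\n", 2 * x$n_sub, x$n_sites,
              if (is.na(x$category)) "" else paste0(" [", x$category, "]")))
  print(x$counts)
  invisible(x)
}

#' Per-category site frequency spectra
#'
#' One SFS per deleteriousness class, all built on a single subsample of
#' individuals (one seeded draw) so spectra are comparable across
#' classes.
#'
#' @inheritParams build_sfs
#' @param sites site table aligned with `gm`.
#' @param scheme a [category_scheme()].
#' @return Named list of `sfs` objects, one per scheme level.
#' @export
sfs_by_category <- function(gm, panel, population, sites, scheme = category_scheme("gerp"),
                            n_sub = 8, seed = 1, rows = NULL) {
  if (is.null(rows)) rows <- draw_subsample(gm, panel, population, n_sub, seed)
  labels <- scheme$classify(sites)
  out <- lapply(scheme$levels, function(lv) {
    s <- build_sfs(gm, panel, population, n_sub = n_sub,
                   site_mask = which(!is.na(labels) & labels == lv), rows = rows)
    s$category <- lv
    s
  })
  stats::setNames(out, scheme$levels)
}

#' Bootstrap test of SFS density differences across deleteriousness classes
#'
#' Each replicate resamples `n_sub` individuals per population with
#' replacement, rebuilds the per-category SFS, and records the density
#' difference (`popB` minus `popA`) in the first `length(bins)` spectrum
#' bins. Sequential classes are then compared by Welch t-tests on the
#' replicate-wise mean absolute differences (signed means are tested
#' too), asking whether the spectrum distortion grows with predicted
#' deleteriousness.
#'
#' @inheritParams sfs_by_category
#' @param popA,popB population labels; differences are `popB - popA`.
#' @param bins spectrum bins compared (default first 10).
#' @param n_reps replicate count.
#' @return List: `mean_diff` / `sd_diff` (category x bin matrices),
#'   `rep_abs` / `rep_signed` (replicate x category summaries), `tests`
#'   (data frame with sequential comparisons, `p_abs`, `p_signed`).
#' @export
density_difference_test <- function(gm, panel, popA, popB, sites,
                                    scheme = category_scheme("gerp"),
                                    n_sub = 18, bins = 1:10,
                                    n_reps = 1000, seed = 1) {
  if (max(bins) > 2 * n_sub - 1)
    stop("requested bins beyond the spectrum (2 n_sub - 1)")
  labels <- scheme$classify(sites)
  cat_idx <- lapply(scheme$levels, function(lv) which(!is.na(labels) & labels == lv))
  names(cat_idx) <- scheme$levels
  rowsA <- pop_rows(gm, panel, popA)
  rowsB <- pop_rows(gm, panel, popB)

  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  nb <- length(bins)
  k <- length(scheme$levels)
  diffs <- array(NA_real_, c(n_reps, k, nb),
                 dimnames = list(NULL, scheme$levels, bins))
  for (r in seq_len(n_reps)) {
    ra <- sample(rowsA, n_sub, replace = TRUE)
    rb <- sample(rowsB, n_sub, replace = TRUE)
    for (ci in seq_len(k)) {
      idx <- cat_idx[[ci]]
      da <- sfs_densities_quick(gm, ra, idx, n_sub)
      db <- sfs_densities_quick(gm, rb, idx, n_sub)
      diffs[r, ci, ] <- db[bins] - da[bins]
    }
  }
  rep_abs <- apply(abs(diffs), c(1, 2), mean)
  rep_signed <- apply(diffs, c(1, 2), mean)
  seqs <- if (k >= 2) data.frame(from = scheme$levels[-k], to = scheme$levels[-1],
                                 stringsAsFactors = FALSE) else NULL
  tests <- do.call(rbind, lapply(seq_len(nrow(seqs)), function(i) {
    a <- rep_abs[, seqs$from[i]]; b <- rep_abs[, seqs$to[i]]
    sa <- rep_signed[, seqs$from[i]]; sb <- rep_signed[, seqs$to[i]]
    data.frame(from = seqs$from[i], to = seqs$to[i],
               p_abs = welch_p(a, b), p_signed = welch_p(sa, sb),
               stringsAsFactors = FALSE)
  }))
  list(mean_diff = apply(diffs, c(2, 3), mean, na.rm = TRUE),
       sd_diff = apply(diffs, c(2, 3), stats::sd, na.rm = TRUE),
       rep_abs = rep_abs, rep_signed = rep_signed, tests = tests)
}

welch_p <- function(a, b) {
  a <- a[is.finite(a)]; b <- b[is.finite(b)]
  if (length(a) < 2 || length(b) < 2) return(NA_real_)
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
  stats::t.test(a, b)$p.value
}

# density vector over bins 1..2m-1 for given rows / site indices
sfs_densities_quick <- function(gm, rows, idx, n_sub) {
  d <- gm$dosage[rows, idx, drop = FALSE]
  complete <- colSums(is.na(d)) == 0L
  dac <- colSums(d[, complete, drop = FALSE])
  nb <- 2L * n_sub
  dac <- dac[dac > 0L & dac < nb]
  tab <- tabulate(dac, nbins = nb - 1L)
  if (sum(tab) == 0) rep(NA_real_, nb - 1L) else tab / sum(tab)
}

#' Low-frequency versus common deleterious variants
#'
#' Among deleterious sites carrying at least one derived allele in a
#' seeded subsample, classifies each as LOW (derived count 1-2:
#' singletons and doubletons) or COMMON (count >= 3) and reports the
#' proportions with Wald 95% confidence intervals.
#'
#' @inheritParams build_sfs
#' @param sites site table (used for the default deleterious mask).
#' @param deleterious_mask logical/index mask; default: conservation
#'   score >= 2.
#' @return One-row data frame: `population, m, n_low, n_common, p_low,
#'   p_common, lo, hi` (CI for `p_common`, clipped to [0, 1]).
#' @export
low_vs_common_proportions <- function(gm, panel, population, sites = NULL,
                                      deleterious_mask = NULL,
                                      n_sub = 8, seed = 1, rows = NULL) {
  if (is.null(deleterious_mask)) {
    if (is.null(sites)) stop("need sites or an explicit deleterious_mask")
    deleterious_mask <- !is.na(sites$gerp_rs) & sites$gerp_rs >= 2
  }
  idx <- resolve_mask(gm, deleterious_mask)
  if (is.null(rows)) rows <- draw_subsample(gm, panel, population, n_sub, seed)
  d <- gm$dosage[rows, idx, drop = FALSE]
  complete <- colSums(is.na(d)) == 0L
  dac <- colSums(d[, complete, drop = FALSE])
  dac <- dac[dac >= 1L]
  m <- length(dac)
  if (m == 0)
    return(data.frame(population = population, m = 0L, n_low = 0L,
                      n_common = 0L, p_low = NA_real_, p_common = NA_real_,
                      lo = NA_real_, hi = NA_real_))
  n_low <- sum(dac <= 2L)
  n_com <- m - n_low
  p <- n_com / m
  half <- 1.96 * sqrt(p * (1 - p) / m)
  data.frame(population = population, m = m, n_low = n_low, n_common = n_com,
             p_low = n_low / m, p_common = p,
             lo = max(0, p - half), hi = min(1, p + half),
             stringsAsFactors = FALSE)
}
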