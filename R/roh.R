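#' Runs-of-homozygosity detection parameters
#'
#' Defaults mirror common exome ROH practice: LD pruning at r2 0.8 in
#' 50 kb windows stepping 5 SNPs; a ROH requires at least 50 consecutive
#' homozygous SNPs with zero heterozygotes, spans at least 1 Mb, and is
#' split wherever consecutive SNPs are more than `max_gap` apart. Length
#' classes 1-2.5 Mb, 2.5-5 Mb and > 5 Mb separate older background
#' autozygosity from recent inbreeding.
#'
#' @param r2_prune LD pruning r-squared threshold.
#' @param prune_window_kb pruning window size (kb).
#' @param prune_step_snps pruning step (SNPs).
#' @param min_snps minimum homozygous SNPs per run.
#' @param het_allowed heterozygotes tolerated inside a run (0: strict).
#' @param miss_allowed missing calls tolerated inside a run (0: strict).
#' @param min_length minimum run span (bp).
#' @param max_gap maximum distance between consecutive run SNPs (bp).
#' @param length_classes lower class boundaries (bp); the last class is
#'   open above.
#' @return A `roh_params` list.
#' @export
roh_params <- function(r2_prune = 0.8, prune_window_kb = 50, prune_step_snps = 5,
                       min_snps = 50, het_allowed = 0, miss_allowed = 0,
                       min_length = 1e6, max_gap = 1e6,
                       length_classes = c(1e6, 2.5e6, 5e6)) {
  stopifnot(min_snps > 0, min_length > 0, max_gap > 0,
            !is.unsorted(length_classes, strictly = TRUE))
  structure(list(r2_prune = r2_prune, prune_window_kb = prune_window_kb,
                 prune_step_snps = prune_step_snps, min_snps = min_snps,
                 het_allowed = het_allowed, miss_allowed = miss_allowed,
                 min_length = min_length, max_gap = max_gap,
                 length_classes = length_classes),
            class = "roh_params")
}

#' Greedy LD pruning of sites
#'
#' Left-to-right scan per chromosome: within each window of
#' `window_kb`, one site of every pair whose dosage squared correlation
#' (over pairwise-complete samples) exceeds the threshold is removed,
#' keeping the earlier site; the scan then advances by `step_snps` kept
#' sites. Deterministic.
#'
#' @param gm a [geno_matrix()].
#' @param sites site table sorted by (`chrom`, `pos`).
#' @param window_kb window span in kb.
#' @param step_snps scan advance in SNPs.
#' @param r2_threshold squared-correlation removal threshold.
#' @return Logical keep-mask over sites.
#' @export
ld_prune <- function(gm, sites, window_kb = 50, step_snps = 5, r2_threshold = 0.8) {
  n <- nrow(sites)
  keep <- rep(TRUE, n)
  for (chr in unique(sites$chrom)) {
    cidx <- which(sites$chrom == chr)
    pos <- sites$pos[cidx]
    i <- 1L
    while (i <= length(cidx)) {
      if (!keep[cidx[i]]) { i <- i + 1L; next }
      win <- which(pos >= pos[i] & pos <= pos[i] + window_kb * 1000 &
                     keep[cidx] & seq_along(cidx) >= i)
      if (length(win) > 1) {
        d <- gm$dosage[, cidx[win], drop = FALSE]
        r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
        for (a in seq_len(length(win) - 1)) {
          if (!keep[cidx[win[a]]]) next
          for (b in seq((a + 1), length(win))) {
            if (!keep[cidx[win[b]]]) next
            if (!is.na(r2[a, b]) && r2[a, b] > r2_threshold)
              keep[cidx[win[b]]] <- FALSE
          }
        }
      }
      # advance by step_snps kept sites from i
      ahead <- which(keep[cidx] & seq_along(cidx) > i)
      i <- if (length(ahead) >= step_snps) ahead[step_snps] else length(cidx) + 1L
    }
  }
  keep
}

#' Detect runs of homozygosity for one sample
#'
#' Maximal runs of consecutive non-missing homozygous calls (dosage 0 or
#' 2), split at heterozygous or missing calls and wherever consecutive
#' SNPs are further apart than `max_gap`; runs are reported when they
#' contain at least `min_snps` SNPs and span at least `min_length` bp
#' (positions of first and last SNP, 1-based inclusive).
#'
#' @param gm a [geno_matrix()] (pruned sites recommended).
#' @param sites site table sorted by (`chrom`, `pos`), aligned with `gm`.
#' @param sample sample id or row index.
#' @param params a [roh_params()].
#' @return Data frame: `sample_id, chrom, start, end, length, n_snps`.
#' @export
detect_rohs <- function(gm, sites, sample, params = roh_params()) {
  row <- if (is.character(sample)) match(sample, gm$sample_ids) else sample
  if (is.na(row)) stop("unknown sample: ", sample)
  d <- gm$dosage[row, ]
  out <- list()
  for (chr in unique(sites$chrom)) {
    cidx <- which(sites$chrom == chr)
    pos <- sites$pos[cidx]
    hom <- !is.na(d[cidx]) & d[cidx] != 1L
    # break runs at non-homozygous calls and at large gaps
    gap_break <- c(FALSE, diff(pos) > params$max_gap)
    grp <- cumsum(!hom | gap_break)
    runs <- which(hom)
    if (!length(runs)) next
    for (g in split(runs, grp[runs])) {
      n_snps <- length(g)
      span <- pos[g[n_snps]] - pos[g[1]] + 1L
      if (n_snps >= params$min_snps && span >= params$min_length)
        out[[length(out) + 1L]] <- data.frame(
          sample_id = gm$sample_ids[row], chrom = chr,
          start = pos[g[1]], end = pos[g[n_snps]],
          length = span, n_snps = n_snps, stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(sample_id = character(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), n_snps = integer(0)))
  do.call(rbind, out)
}

#' Detect ROHs for every sample
#'
#' @inheritParams detect_rohs
#' @return Row-bound data frame over all samples (possibly zero rows).
#' @export
detect_rohs_all <- function(gm, sites, params = roh_params()) {
  do.call(rbind, lapply(seq_len(nrow(gm$dosage)),
                        function(i) detect_rohs(gm, sites, i, params)))
}

# class label per ROH; runs below the first boundary get NA and only
# count toward the "all" aggregate
roh_class_of <- function(length, class_bounds) {
  idx <- findInterval(length, class_bounds)
  ifelse(idx == 0, NA_integer_, idx)
}

class_labels <- function(class_bounds) {
  lo <- class_bounds / 1e6
  hi <- c(class_bounds[-1] / 1e6, Inf)
  ifelse(is.finite(hi), sprintf("%g-%g Mb", lo, hi), sprintf(">%g Mb", lo))
}

#' Per-individual ROH summaries and population comparisons
#'
#' Counts, total length and mean length of ROHs per individual, overall
#' and per length class; Welch t-tests compare designated population
#' pairs per class, with significance tiers at 0.05 / 0.01 / 0.001.
#'
#' @param rohs ROH data frame from [detect_rohs_all()].
#' @param panel panel data frame (defines the full individual set:
#'   individuals without ROHs enter with zeros).
#' @param params a [roh_params()] (for the length classes).
#' @param pairs optional 2-column matrix/data frame of population pairs
#'   to test; default: all pairs.
#' @return List: `per_individual` (sample, population, class, n, total,
#'   mean), `tests` (popA, popB, class, metric, p, tier).
#' @export
roh_summaries <- function(rohs, panel, params = roh_params(), pairs = NULL) {
  bounds <- params$length_classes
  labels <- c("all", class_labels(bounds))
  per <- expand.grid(sample_id = panel$sample_id, class = labels,
                     stringsAsFactors = FALSE)
  per$population <- panel$population[match(per$sample_id, panel$sample_id)]
  per$n <- 0L; per$total <- 0; per$mean <- NA_real_
  if (nrow(rohs)) {
    rohs$class <- class_labels(bounds)[roh_class_of(rohs$length, bounds)]
    for (i in seq_len(nrow(per))) {
      sel <- rohs$sample_id == per$sample_id[i] &
        (per$class[i] == "all" |
           (!is.na(rohs$class) & rohs$class == per$class[i]))
      per$n[i] <- sum(sel)
      per$total[i] <- sum(rohs$length[sel])
      per$mean[i] <- if (any(sel)) mean(rohs$length[sel]) else NA_real_
    }
  }
  pops <- unique(panel$population)
  if (is.null(pairs) && length(pops) >= 2)
    pairs <- t(utils::combn(pops, 2))
  tests <- list()
  if (!is.null(pairs)) {
    for (k in seq_len(nrow(pairs))) for (cl in labels) for (metric in c("n", "total")) {
      a <- per[per$population == pairs[k, 1] & per$class == cl, metric]
      b <- per[per$population == pairs[k, 2] & per$class == cl, metric]
      p <- if (sum(a) + sum(b) == 0) NA_real_ else welch_p(a, b)
      tests[[length(tests) + 1L]] <- data.frame(
        popA = pairs[k, 1], popB = pairs[k, 2], class = cl, metric = metric,
        p = p, tier = sig_tier(p), stringsAsFactors = FALSE)
    }
  }
  list(per_individual = per,
       tests = if (length(tests)) do.call(rbind, tests) else NULL)
}

sig_tier <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

# per-sample logical mask of sites inside that sample's ROHs
sites_in_rohs <- function(sites, rohs_sample) {
  inside <- rep(FALSE, nrow(sites))
  if (!nrow(rohs_sample)) return(inside)
  for (i in seq_len(nrow(rohs_sample)))
    inside <- inside | (sites$chrom == rohs_sample$chrom[i] &
                          sites$pos >= rohs_sample$start[i] &
                          sites$pos <= rohs_sample$end[i])
  inside
}

#' Missense/synonymous homozygote ratio inside and outside ROHs
#'
#' Per individual and region (inside all ROHs, outside, and inside each
#' ROH length class), the count of homozygous-derived genotypes at
#' missense sites of each deleterious conservation class divided by the
#' count of homozygous-derived genotypes at synonymous neutral sites
#' (score < 2) in the same region. Individuals with a zero denominator
#' are excluded from tests and counted. Population-level inside-versus-
#' outside contrasts use paired t-tests.
#'
#' @param gm polarized [geno_matrix()].
#' @param sites site table with `consequence` and `gerp_rs`.
#' @param rohs ROH data frame from [detect_rohs_all()].
#' @param panel panel data frame.
#' @param params a [roh_params()].
#' @param scheme a [category_scheme()] ("gerp" expected).
#' @return List: `ratios` (sample, population, region, category, n_num,
#'   n_den, ratio), `tests` (population, category, p, n_pairs).
#' @export
roh_zygosity_ratio <- function(gm, sites, rohs, panel, params = roh_params(),
                               scheme = category_scheme("gerp")) {
  labels <- scheme$classify(sites)
  del_levels <- setdiff(scheme$levels, scheme$levels[1])
  syn_mask <- mask_synonymous(sites) & !is.na(labels) & labels == scheme$levels[1]
  num_masks <- lapply(del_levels, function(lv)
    mask_missense(sites) & !is.na(labels) & labels == lv)
  names(num_masks) <- del_levels
  bounds <- params$length_classes
  cls_lab <- class_labels(bounds)
  out <- list()
  for (s in panel$sample_id) {
    row <- match(s, gm$sample_ids)
    if (is.na(row)) next
    hom <- !is.na(gm$dosage[row, ]) & gm$dosage[row, ] == 2L
    rs <- rohs[rohs$sample_id == s, , drop = FALSE]
    if (nrow(rs)) rs$class <- cls_lab[roh_class_of(rs$length, bounds)]
    inside <- sites_in_rohs(sites, rs)
    regions <- c(list(inside = inside, outside = !inside),
                 stats::setNames(lapply(cls_lab, function(cl) {
                   pick <- if (nrow(rs)) !is.na(rs$class) & rs$class == cl
                           else logical(0)
                   sites_in_rohs(sites, rs[pick, , drop = FALSE])
                 }), paste0("inside_", cls_lab)))
    for (rg in names(regions)) for (lv in del_levels) {
      n_num <- sum(hom & num_masks[[lv]] & regions[[rg]])
      n_den <- sum(hom & syn_mask & regions[[rg]])
      out[[length(out) + 1L]] <- data.frame(
        sample_id = s,
        population = panel$population[panel$sample_id == s],
        region = rg, category = lv, n_num = n_num, n_den = n_den,
        ratio = if (n_den > 0) n_num / n_den else NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  ratios <- do.call(rbind, out)
  tests <- list()
  for (pop in unique(panel$population)) for (lv in del_levels) {
    ri <- ratios[ratios$population == pop & ratios$category == lv &
                   ratios$region == "inside", ]
    ro <- ratios[ratios$population == pop & ratios$category == lv &
                   ratios$region == "outside", ]
    m <- match(ri$sample_id, ro$sample_id)
    a <- ri$ratio; b <- ro$ratio[m]
    ok <- is.finite(a) & is.finite(b)
    p <- if (sum(ok) >= 2 && stats::sd(a[ok] - b[ok]) > 0)
      stats::t.test(a[ok], b[ok], paired = TRUE)$p.value else NA_real_
    tests[[length(tests) + 1L]] <- data.frame(
      population = pop, category = lv, p = p, n_pairs = sum(ok),
      stringsAsFactors = FALSE)
  }
  list(ratios = ratios, tests = do.call(rbind, tests))
}
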