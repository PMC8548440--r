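#' Build high-Fst deleterious candidate subsets
#'
#' Applies the filter cascade in order: (i) missense sites, (ii) the
#' deleteriousness category (three conservation-score classes and two
#' damaging PolyPhen labels), (iii) sites in the top 5% of that subset's
#' own (defined) Fst distribution, inclusive of ties at the threshold. A
#' sixth subset, `all_categories`, merges the five post-(ii) site sets
#' and takes its own top 5%. Finally every subset keeps only sites whose
#' derived allele frequency is strictly higher in `target_pop` than in
#' `other_pop`, and maps survivors to unique non-empty gene symbols.
#'
#' @param gm polarized [geno_matrix()].
#' @param sites site table (consequence, gerp_rs, polyphen, gene).
#' @param fst per-site Fst vector aligned with `sites` (NA = undefined;
#'   excluded before the quantile).
#' @param panel panel data frame.
#' @param target_pop population whose elevated derived frequencies define
#'   candidates; `other_pop` the comparison population.
#' @param other_pop see above.
#' @param top_fraction upper Fst tail kept within each subset.
#' @return Named list of subsets, each a list with `sites` (indices) and
#'   `genes` (character).
#' @export
build_candidate_subsets <- function(gm, sites, fst, panel, target_pop, other_pop,
                                    top_fraction = 0.05) {
  missense <- mask_missense(sites)
  gerp <- category_scheme("gerp")$classify(sites)
  base <- list(
    moderate = missense & !is.na(gerp) & gerp == "moderate",
    large = missense & !is.na(gerp) & gerp == "large",
    extreme = missense & !is.na(gerp) & gerp == "extreme",
    polyphen_possibly = missense & !is.na(sites$polyphen) &
      sites$polyphen == "possibly_damaging",
    polyphen_probably = missense & !is.na(sites$polyphen) &
      sites$polyphen == "probably_damaging")
  base$all_categories <- Reduce(`|`, base)

  q_target <- derived_freq(gm, panel, target_pop)
  q_other <- derived_freq(gm, panel, other_pop)
  lapply(base, function(mask) {
    idx <- which(mask & !is.na(fst))
    if (!length(idx)) return(list(sites = integer(0), genes = character(0)))
    thr <- stats::quantile(fst[idx], 1 - top_fraction, names = FALSE)
    idx <- idx[fst[idx] >= thr]
    idx <- idx[!is.na(q_target[idx]) & !is.na(q_other[idx]) &
                 q_target[idx] > q_other[idx]]
    genes <- unique(sites$gene[idx])
    list(sites = idx, genes = genes[!is.na(genes) & genes != ""])
  })
}

#' Hypergeometric over-representation analysis
#'
#' Per gene set: upper-tail hypergeometric p for the overlap between the
#' query genes and the set within the universe; Benjamini-Hochberg FDR
#' across tested sets; `enrichment_ratio = observed / expected` with
#' `expected = set_size * |query| / |universe|`. Significance tiers:
#' tier 1, FDR < 0.05; tier 2, p < 0.05 and ratio above the mean ratio of
#' the tested sets; tier 3, remaining p < 0.05.
#'
#' @param genes query gene symbols (subset of `universe`).
#' @param universe background gene symbols.
#' @param catalog named list, set name -> gene vector.
#' @return Data frame: `set_name, set_size, observed, expected,
#'   enrichment_ratio, p, fdr, tier` (0 = not significant); sets with no
#'   universe overlap are skipped and reported via the
#'   `n_skipped` attribute.
#' @export
ora <- function(genes, universe, catalog) {
  genes <- unique(genes); universe <- unique(universe)
  if (!all(genes %in% universe)) stop("query genes must be a subset of the universe")
  rows <- list(); skipped <- 0L
  for (nm in names(catalog)) {
    set <- unique(intersect(catalog[[nm]], universe))
    if (!length(set)) { skipped <- skipped + 1L; next }
    obs <- length(intersect(genes, set))
    expd <- length(set) * length(genes) / length(universe)
    p <- stats::phyper(obs - 1, length(set), length(universe) - length(set),
                       length(genes), lower.tail = FALSE)
    rows[[nm]] <- data.frame(set_name = nm, set_size = length(set),
                             observed = obs, expected = expd,
                             enrichment_ratio = obs / expd, p = p,
                             stringsAsFactors = FALSE)
  }
  if (!length(rows)) stop("no catalog set overlaps the universe")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$fdr <- stats::p.adjust(out$p, method = "BH")
  mean_ratio <- mean(out$enrichment_ratio)
  out$tier <- ifelse(out$fdr < 0.05, 1L,
                     ifelse(out$p < 0.05 & out$enrichment_ratio > mean_ratio, 2L,
                            ifelse(out$p < 0.05, 3L, 0L)))
  attr(out, "n_skipped") <- skipped
  out
}

#' Bootstrap-null trait enrichment (Q95 flagging)
#'
#' Counts, per trait, the query genes associated with the trait; then
#' draws `n_reps` random gene lists of the same size (without
#' replacement) from a source list (the catalog's own genes or the
#' dataset universe), recounts, and flags a trait when the observed count
#' is at or above the 95th percentile (Q95) of its replicate counts.
#'
#' @param genes query gene symbols.
#' @param trait_catalog named list, trait -> gene vector.
#' @param source_genes the pool replicates are drawn from (e.g.
#'   `unique(unlist(trait_catalog))` or the dataset universe).
#' @param n_reps replicate count.
#' @param seed RNG seed.
#' @return Data frame: `trait, observed, q95, flagged`.
#' @export
catalog_bootstrap_enrichment <- function(genes, trait_catalog, source_genes,
                                         n_reps = 1000, seed = 1) {
  genes <- unique(genes)
  source_genes <- unique(source_genes)
  if (!length(genes)) stop("empty query gene list")
  if (length(genes) > length(source_genes))
    stop("query larger than the source gene list")
  traits <- names(trait_catalog)
  obs <- vapply(trait_catalog, function(g) length(intersect(genes, g)),
                integer(1))
  # trait membership matrix over source genes for fast recounting
  memb <- vapply(trait_catalog, function(g) source_genes %in% g,
                 logical(length(source_genes)))
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(seed)
  counts <- matrix(0L, n_reps, length(traits))
  for (r in seq_len(n_reps)) {
    pick <- sample.int(length(source_genes), length(genes))
    counts[r, ] <- colSums(memb[pick, , drop = FALSE])
  }
  q95 <- apply(counts, 2, stats::quantile, probs = 0.95, names = FALSE, type = 1)
  data.frame(trait = traits, observed = obs, q95 = q95,
             flagged = obs >= q95 & obs > 0, row.names = NULL,
             stringsAsFactors = FALSE)
}
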