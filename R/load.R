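#' Per-individual derived-allele and homozygote burdens
#'
#' For each sample over the masked sites: `n_alleles` (summed derived
#' dosage; the additive-model burden) and `n_hom` (count of homozygous
#' derived genotypes; the recessive-model burden). Missing genotypes
#' contribute zero and are counted per sample.
#'
#' @param gm polarized [geno_matrix()].
#' @param site_mask mask over sites (default all).
#' @return Data frame: `sample_id, n_alleles, n_hom, n_missing`.
#' @export
per_individual_burden <- function(gm, site_mask = NULL) {
  idx <- resolve_mask(gm, site_mask)
  if (!length(idx)) stop("empty site mask")
  d <- gm$dosage[, idx, drop = FALSE]
  data.frame(sample_id = gm$sample_ids,
             n_alleles = rowSums(d, na.rm = TRUE),
             n_hom = rowSums(d == 2L, na.rm = TRUE),
             n_missing = rowSums(is.na(d)),
             stringsAsFactors = FALSE)
}

#' Population load ratio with block-bootstrap inference
#'
#' Ratio of per-individual mean burdens `mean_A(N) / mean_B(N)`, with `N`
#' either `n_alleles` (additive model) or `n_hom` (recessive model), over
#' the sites of one deleteriousness category, optionally restricted by
#' consequence label (missense for deleterious categories, synonymous for
#' the neutral one). Inference is by block bootstrap over sites; the
#' two-sided p is the replicate distribution's position relative to 1,
#' with significance conventionally declared at p < 0.001.
#'
#' @param gm polarized [geno_matrix()].
#' @param panel panel data frame.
#' @param popA,popB population labels (ratio is A over B).
#' @param sites site table aligned with `gm`.
#' @param category scheme level to restrict to, or `NULL` for all sites.
#' @param scheme a [category_scheme()].
#' @param model `"additive"` (n_alleles) or `"recessive"` (n_hom).
#' @param consequence_filter if `TRUE`, intersect deleterious categories
#'   with missense sites and the neutral category with synonymous sites.
#' @param n_blocks,n_reps,seed bootstrap controls.
#' @return A `boot_result` (see [block_bootstrap()]) with `p_value`
#'   relative to a ratio of 1.
#' @export
load_ratio <- function(gm, panel, popA, popB, sites = NULL, category = NULL,
                       scheme = category_scheme("gerp"),
                       model = c("additive", "recessive"),
                       consequence_filter = FALSE,
                       n_blocks = 1000, n_reps = 1000, seed = 1) {
  model <- match.arg(model)
  idx <- category_mask(sites, category, scheme, consequence_filter,
                       n_total = ncol(gm$dosage))
  if (!length(idx)) stop("no sites in category ", category)
  burden_site <- function(rows) {
    d <- gm$dosage[rows, idx, drop = FALSE]
    if (model == "additive") colMeans(d, na.rm = TRUE)
    else colMeans(d == 2L, na.rm = TRUE)
  }
  # per-site mean burden per population: the per-individual mean burden
  # over a site set is the sum of these per-site means
  msA <- burden_site(pop_rows(gm, panel, popA))
  msB <- burden_site(pop_rows(gm, panel, popB))
  msA[is.nan(msA)] <- 0; msB[is.nan(msB)] <- 0
  statistic <- function(j) {
    den <- sum(msB[j])
    if (den == 0) return(NA_real_)
    sum(msA[j]) / den
  }
  block_bootstrap(statistic, length(idx), n_blocks = n_blocks,
                  n_reps = n_reps, seed = seed, null_value = 1)
}

# sites belonging to one deleteriousness category (with optional
# consequence intersection); NULL category = all sites
category_mask <- function(sites, category, scheme, consequence_filter, n_total) {
  if (is.null(category) || is.null(sites)) return(seq_len(n_total))
  labels <- scheme$classify(sites)
  keep <- !is.na(labels) & labels == category
  if (consequence_filter) {
    neutral <- category == scheme$levels[1]
    keep <- keep & if (neutral) mask_synonymous(sites) else mask_missense(sites)
  }
  which(keep)
}

#' Selection coefficients per deleteriousness category
#'
#' The conventional mapping from conservation-score class to selection
#' coefficient: s = 4.5e-4 for the "moderate" class [2, 4), 4.5e-3 for
#' "large" [4, 6), 1e-2 for "extreme" (>= 6); the neutral class carries
#' no coefficient. Dominance h is 0.5 under the additive model and 0
#' under the recessive model.
#'
#' @param s named numeric vector of selection coefficients per category.
#' @return Named numeric vector (class -> s).
#' @export
selection_coefficients <- function(s = c(moderate = 4.5e-4, large = 4.5e-3,
                                         extreme = 1e-2)) {
  stopifnot(all(s > 0), all(s < 1))
  s
}

#' Per-site selection load from genotype frequencies
#'
#' `load = 1 - w = 2 q (1 - q) s h + s q^2`, with `q` the derived allele
#' frequency, `s` the selection coefficient, and `h` the dominance
#' coefficient (0.5 additive, 0 recessive).
#'
#' @param q derived allele frequency (vectorized).
#' @param s selection coefficient (vectorized).
#' @param h dominance coefficient.
#' @return Numeric per-site load.
#' @export
site_load <- function(q, s, h) 2 * q * (1 - q) * s * h + s * q^2

#' Conservation-score selection load per population
#'
#' Assigns each deleterious site its category's selection coefficient,
#' computes its per-site load from the population's derived allele
#' frequency via [site_load()], and sums within categories and overall.
#' Neutral-class and unscored sites are excluded and counted.
#'
#' @inheritParams load_ratio
#' @param population population label.
#' @param coeffs category -> s map from [selection_coefficients()].
#' @param model `"additive"` (h = 0.5) or `"recessive"` (h = 0).
#' @return List: `total`, `per_category` (named numeric), `n_sites`
#'   (named counts), `n_excluded`.
#' @export
gerp_score_load <- function(gm, panel, population, sites,
                            coeffs = selection_coefficients(),
                            model = c("additive", "recessive"),
                            scheme = category_scheme("gerp")) {
  model <- match.arg(model)
  h <- if (model == "additive") 0.5 else 0
  labels <- scheme$classify(sites)
  q <- derived_freq(gm, panel, population)
  per_cat <- numeric(0); n_cat <- integer(0)
  for (cat in names(coeffs)) {
    idx <- which(!is.na(labels) & labels == cat & !is.na(q))
    per_cat[cat] <- sum(site_load(q[idx], coeffs[[cat]], h))
    n_cat[cat] <- length(idx)
  }
  excluded <- sum(is.na(labels) | !labels %in% names(coeffs) | is.na(q))
  list(total = sum(per_cat), per_category = per_cat, n_sites = n_cat,
       n_excluded = excluded, model = model, population = population)
}

#' Load-ratio table across categories, models and population pairs
#'
#' @inheritParams load_ratio
#' @param categories scheme levels to evaluate (default all).
#' @param models models to evaluate.
#' @return Data frame: `popA, popB, category, model, estimate, lo, hi,
#'   p_value`.
#' @export
load_ratio_table <- function(gm, panel, popA, popB, sites,
                             scheme = category_scheme("gerp"),
                             categories = scheme$levels,
                             models = c("additive", "recessive"),
                             consequence_filter = FALSE,
                             n_blocks = 1000, n_reps = 1000, seed = 1) {
  out <- list()
  for (cat in categories) for (model in models) {
    b <- load_ratio(gm, panel, popA, popB, sites, category = cat,
                    scheme = scheme, model = model,
                    consequence_filter = consequence_filter,
                    n_blocks = n_blocks, n_reps = n_reps, seed = seed)
    out[[length(out) + 1L]] <- data.frame(
      popA = popA, popB = popB, category = cat, model = model,
      estimate = b$estimate, lo = b$lo, hi = b$hi, p_value = b$p_value,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
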