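#' Parameters for the two-population isolate-vs-reference scenario
#'
#' The generator emulates the qualitative demographic contrast between a
#' recently bottlenecked, inbred isolate and a larger panmictic
#' reference: ancestral derived-allele frequencies follow the neutral
#' equilibrium 1/i law, deleterious classes are down-weighted in
#' frequency, the isolate's frequencies drift through a short
#' Wright-Fisher bottleneck, and isolate genotypes carry explicit
#' autozygous tracts (so ROH ground truth is exact). Defaults are the
#' study conditions the package is exercised under: 18 isolate vs 46
#' reference diploids, a 25-diploid bottleneck lasting 40 generations,
#' autozygosity fraction 0.125 with 2.5-Mb mean tracts, and 40,000 exome
#' SNPs on eight 25-Mb chromosomes.
#'
#' @param n_sites number of background SNPs (planted sites are added).
#' @param chrom_lengths named vector of chromosome lengths (bp).
#' @param n_ref,n_iso diploid sample counts.
#' @param bottleneck_size isolate bottleneck size (diploids).
#' @param bottleneck_generations generations of Wright-Fisher drift.
#' @param inbreeding_f expected autozygous genome fraction in `[0, 1)`.
#' @param tract_mean_length mean autozygous tract length (bp).
#' @param sel_class_probs class mixture (must sum to 1).
#' @param sel_coeffs per-class selection coefficient s.
#' @param freq_penalty_c constant C in the deterministic frequency
#'   down-weighting `q / (1 + C s)` applied to deleterious classes.
#' @param consequence_leakage fraction of neutral sites labelled
#'   missense (and of deleterious sites labelled "other") so consequence
#'   and score class are correlated but not identical.
#' @param ancestral_unknown_frac fraction of sites with unknown
#'   ancestral state (removed at polarization).
#' @param ancestral_alt_frac fraction of sites where the ancestral
#'   allele is the ALT base (exercising dosage flipping).
#' @param sfs_grid haplotype grid for the 1/i frequency law.
#' @param planted_region optional list (`chrom, start, end, n_sites,
#'   genes, anc_freq_range, iso_shift`) planting a high-drift missense
#'   gene region of extreme-class sites; `NULL` disables.
#' @param seed RNG seed; identical parameters and seed give
#'   byte-identical output files.
#' @return A `scenario_params` list.
#' @export
scenario_params <- function(n_sites = 40000,
                            chrom_lengths = stats::setNames(rep(25e6, 8), paste0("chr", 1:8)),
                            n_ref = 46, n_iso = 18,
                            bottleneck_size = 25, bottleneck_generations = 40,
                            inbreeding_f = 0.125, tract_mean_length = 2.5e6,
                            sel_class_probs = c(neutral = 0.63, moderate = 0.25,
                                                large = 0.09, extreme = 0.03),
                            sel_coeffs = c(neutral = 0, moderate = 4.5e-4,
                                           large = 4.5e-3, extreme = 1e-2),
                            freq_penalty_c = 1000,
                            consequence_leakage = 0.10,
                            ancestral_unknown_frac = 0.02,
                            ancestral_alt_frac = 0.25,
                            sfs_grid = 100,
                            planted_region = list(chrom = "chr1", start = 5e6,
                                                  end = 5.5e6, n_sites = 30,
                                                  genes = c("PLANTA", "PLANTB", "PLANTC"),
                                                  anc_freq_range = c(0.2, 0.4),
                                                  iso_shift = 0.5),
                            seed = 1) {
  chrom_lengths <- unlist(chrom_lengths)           # lists arrive via YAML
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  sel_class_probs <- unlist(sel_class_probs)
  sel_coeffs <- unlist(sel_coeffs)
  if (!is.null(planted_region))
    planted_region <- lapply(planted_region, function(x)
      if (is.list(x) && is.null(names(x))) unlist(x) else x)
  stopifnot(abs(sum(sel_class_probs) - 1) < 1e-9,
            bottleneck_size >= 2 || bottleneck_generations == 0,
            inbreeding_f >= 0, inbreeding_f < 1,
            n_sites > 0, n_ref > 0, n_iso > 0, all(chrom_lengths > 0))
  structure(as.list(environment()), class = "scenario_params")
}

#' Simulate the two-population scenario to disk
#'
#' Generates genotypes, annotation, panel and ground truth under the
#' scenario in `params` and writes plain-text VCF 4.2, annotation TSV,
#' panel TSV and truth JSON into `dir`.
#'
#' @param params a [scenario_params()].
#' @param dir output directory (created if needed).
#' @return List: `paths` (vcf, annotation, panel, truth), `truth` (the
#'   in-memory truth record), `monomorphic_fraction`.
#' @export
simulate_scenario <- function(params = scenario_params(), dir = tempfile("scenario")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old <- get_rng_state(); on.exit(restore_rng_state(old))
  set.seed(params$seed)
  p <- params

  chroms <- names(p$chrom_lengths)
  n_chr_sites <- round(p$n_sites * p$chrom_lengths / sum(p$chrom_lengths))
  site_list <- lapply(seq_along(chroms), function(ci) {
    data.frame(chrom = chroms[ci],
               pos = sort(sample.int(p$chrom_lengths[ci], n_chr_sites[ci])),
               planted = FALSE, stringsAsFactors = FALSE)
  })
  sites <- do.call(rbind, site_list)

  n <- nrow(sites)
  classes <- sample(names(p$sel_class_probs), n, replace = TRUE,
                    prob = p$sel_class_probs)
  gerp <- numeric(n)
  gerp[classes == "neutral"] <- stats::runif(sum(classes == "neutral"), -3, 2)
  gerp[classes == "moderate"] <- stats::runif(sum(classes == "moderate"), 2, 4)
  gerp[classes == "large"] <- stats::runif(sum(classes == "large"), 4, 6)
  gerp[classes == "extreme"] <- stats::runif(sum(classes == "extreme"), 6, 10)

  neutral <- classes == "neutral"
  leak <- stats::runif(n) < p$consequence_leakage
  consequence <- ifelse(neutral,
                        ifelse(leak, "missense", "synonymous"),
                        ifelse(leak, "other", "missense"))

  # ancestral frequency: 1/i law on a haplotype grid, then deterministic
  # class down-weighting so more deleterious classes are rarer
  i_grid <- seq_len(p$sfs_grid - 1)
  i_draw <- sample(i_grid, n, replace = TRUE, prob = 1 / i_grid)
  q_anc <- i_draw / p$sfs_grid
  s_site <- p$sel_coeffs[classes]
  q_anc <- q_anc / (1 + p$freq_penalty_c * s_site)

  # plant a high-drift missense gene region of extreme-class sites
  if (!is.null(p$planted_region)) {
    pr <- p$planted_region
    # background sites inside the planted window are replaced outright
    drop_bg <- sites$chrom == pr$chrom & sites$pos >= pr$start & sites$pos <= pr$end
    sites <- sites[!drop_bg, ]; classes <- classes[!drop_bg]
    gerp <- gerp[!drop_bg]; consequence <- consequence[!drop_bg]
    q_anc <- q_anc[!drop_bg]
    extra <- data.frame(chrom = pr$chrom,
                        pos = sort(sample(seq.int(pr$start, pr$end), pr$n_sites)),
                        planted = TRUE, stringsAsFactors = FALSE)
    sites <- rbind(sites, extra)
    ord <- order(match(sites$chrom, chroms), sites$pos)
    classes <- c(classes, rep("extreme", pr$n_sites))[ord]
    gerp <- c(gerp, stats::runif(pr$n_sites, 6, 10))[ord]
    consequence <- c(consequence, rep("missense", pr$n_sites))[ord]
    q_anc <- c(q_anc, stats::runif(pr$n_sites, pr$anc_freq_range[1],
                                   pr$anc_freq_range[2]))[ord]
    sites <- sites[ord, ]
    n <- nrow(sites)
  }
  rownames(sites) <- NULL

  # isolate frequencies: binomial Wright-Fisher through the bottleneck
  q_iso <- q_anc
  if (p$bottleneck_generations > 0) {
    nb2 <- 2 * p$bottleneck_size
    for (g in seq_len(p$bottleneck_generations))
      q_iso <- stats::rbinom(n, nb2, q_iso) / nb2
  }
  if (!is.null(p$planted_region))
    q_iso[sites$planted] <- pmin(0.95, q_anc[sites$planted] +
                                   p$planted_region$iso_shift)

  ref_ids <- sprintf("REF%03d", seq_len(p$n_ref))
  iso_ids <- sprintf("ISO%03d", seq_len(p$n_iso))
  dos_ref <- matrix(stats::rbinom(p$n_ref * n, 2, rep(q_anc, each = p$n_ref)),
                    nrow = p$n_ref, dimnames = list(ref_ids, NULL))

  # isolate genotypes: explicit autozygous tracts; homozygous inside
  tracts <- list()
  dos_iso <- matrix(0L, p$n_iso, n, dimnames = list(iso_ids, NULL))
  for (si in seq_len(p$n_iso)) {
    tr <- if (p$inbreeding_f > 0)
      draw_tracts(p$chrom_lengths, p$inbreeding_f, p$tract_mean_length)
    else empty_tracts()
    tracts[[iso_ids[si]]] <- tr
    inside <- rep(FALSE, n)
    if (nrow(tr))
      for (k in seq_len(nrow(tr)))
        inside <- inside | (sites$chrom == tr$chrom[k] &
                              sites$pos >= tr$start[k] & sites$pos <= tr$end[k])
    g <- integer(n)
    g[!inside] <- stats::rbinom(sum(!inside), 2, q_iso[!inside])
    g[inside] <- 2L * stats::rbinom(sum(inside), 1, q_iso[inside])
    dos_iso[si, ] <- g
  }
  derived <- rbind(dos_iso, dos_ref)

  mono_frac <- mean(colSums(derived) %in% c(0L, 2L * nrow(derived)))
  if (mono_frac > 0.9)
    warning(sprintf("%.0f%% of simulated sites are monomorphic; consider a larger bottleneck", 100 * mono_frac))

  # allele/ancestral bookkeeping: VCF is alt-coded, so flip dosages at
  # sites whose ancestral allele is the ALT base
  bases <- c("A", "C", "G", "T")
  ref_base <- sample(bases, n, replace = TRUE)
  alt_base <- vapply(ref_base, function(b) sample(setdiff(bases, b), 1), "")
  u <- stats::runif(n)
  anc_state <- ifelse(u < p$ancestral_unknown_frac, "unknown",
                      ifelse(u < p$ancestral_unknown_frac + p$ancestral_alt_frac,
                             "alt", "ref"))
  ancestral <- ifelse(anc_state == "unknown", ".",
                      ifelse(anc_state == "alt", alt_base, ref_base))
  alt_dosage <- derived
  flip <- anc_state == "alt"
  alt_dosage[, flip] <- 2L - alt_dosage[, flip]

  gene <- sprintf("G_%s_%03d", sites$chrom, sites$pos %/% 100000)
  if (!is.null(p$planted_region)) {
    pi_ <- which(sites$planted)
    gene[pi_] <- rep_len(p$planted_region$genes, length(pi_))
  }
  polyphen <- simulate_polyphen(classes)
  cadd <- pmax(0, 3 * gerp + stats::rnorm(n, 5, 2))

  vcf_sites <- data.frame(chrom = sites$chrom, pos = sites$pos,
                          ref = ref_base, alt = alt_base,
                          stringsAsFactors = FALSE)
  gm <- geno_matrix(alt_dosage, c(iso_ids, ref_ids), polarized = FALSE)

  paths <- list(vcf = file.path(dir, "scenario.vcf"),
                annotation = file.path(dir, "annotation.tsv"),
                panel = file.path(dir, "panel.tsv"),
                truth = file.path(dir, "truth.json"))
  write_vcf(gm, vcf_sites, paths$vcf)
  annot <- data.frame(chrom = sites$chrom, pos = sites$pos,
                      ref = ref_base, alt = alt_base, ancestral = ancestral,
                      gene = gene, consequence = consequence,
                      gerp_rs = round(gerp, 4), cadd = round(cadd, 3),
                      polyphen = polyphen, stringsAsFactors = FALSE)
  utils::write.table(annot, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  panel <- data.frame(sample_id = c(iso_ids, ref_ids),
                      population = c(rep("ISO", p$n_iso), rep("REF", p$n_ref)),
                      stringsAsFactors = FALSE)
  utils::write.table(panel, paths$panel, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  truth <- list(anc_freq = q_anc, iso_freq = q_iso, class = classes,
                planted = sites$planted,
                planted_genes = if (is.null(p$planted_region)) character(0)
                                else p$planted_region$genes,
                tracts = tracts)
  jsonlite::write_json(truth, paths$truth, auto_unbox = TRUE, digits = NA)
  list(paths = paths, truth = truth, monomorphic_fraction = mono_frac)
}

simulate_polyphen <- function(classes) {
  prob <- list(neutral = c(0.85, 0.05, 0.02, 0.08),
               moderate = c(0.55, 0.30, 0.07, 0.08),
               large = c(0.25, 0.40, 0.27, 0.08),
               extreme = c(0.10, 0.30, 0.52, 0.08))
  labs <- c("benign", "possibly_damaging", "probably_damaging", "unknown")
  vapply(classes, function(cl) sample(labs, 1, prob = prob[[cl]]), "",
         USE.NAMES = FALSE)
}

# alternating-renewal tract placement: exponential tract lengths with
# mean L, exponential gaps with mean L (1 - f) / f, stationary start
draw_tracts <- function(chrom_lengths, f, L) {
  gap_mean <- L * (1 - f) / f
  out <- list()
  for (ci in seq_along(chrom_lengths)) {
    len <- chrom_lengths[ci]
    pos <- 0
    in_tract <- stats::runif(1) < f
    while (pos < len) {
      seg <- stats::rexp(1, 1 / (if (in_tract) L else gap_mean))
      if (in_tract) {
        start <- max(1, round(pos) + 1)
        end <- min(len, round(pos + seg))
        if (end >= start)
          out[[length(out) + 1L]] <- data.frame(
            chrom = names(chrom_lengths)[ci], start = start, end = end,
            stringsAsFactors = FALSE)
      }
      pos <- pos + seg
      in_tract <- !in_tract
    }
  }
  if (!length(out)) return(empty_tracts())
  do.call(rbind, out)
}

empty_tracts <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0))
}

#' Load a simulated scenario back through the variant store
#'
#' Reads the files written by [simulate_scenario()], annotates and
#' polarizes; QC is not applied (the generator emits clean data) unless
#' `qc = TRUE`.
#'
#' @param paths the `paths` element returned by [simulate_scenario()].
#' @param qc apply [qc_filter_sites()] with default thresholds.
#' @return List: polarized `gm`, annotated `sites`, `panel`, and the
#'   polarization `report`.
#' @export
load_scenario <- function(paths, qc = FALSE) {
  panel <- read_panel(paths$panel)
  rv <- read_vcf(paths$vcf, panel)
  annot <- read_annotation(paths$annotation)
  sites <- annotate_sites(rv$sites, annot)
  gm <- rv$gm
  if (qc) {
    f <- qc_filter_sites(gm, sites, panel)
    gm <- f$gm; sites <- f$sites
  }
  pol <- polarize(gm, sites)
  list(gm = pol$gm, sites = pol$sites, panel = panel, report = pol$report)
}
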