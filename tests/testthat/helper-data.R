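# shared in-code fixtures: no data files, everything built at test time

make_gm <- function(dosage, ids = NULL, polarized = TRUE) {
  dosage <- as.matrix(dosage)
  if (is.null(ids)) ids <- sprintf("S%02d", seq_len(nrow(dosage)))
  geno_matrix(dosage, ids, polarized = polarized)
}

make_panel <- function(ids, pops) {
  data.frame(sample_id = ids, population = pops, stringsAsFactors = FALSE)
}

two_pop_panel <- function(gm, n_a) {
  make_panel(gm$sample_ids,
             rep(c("A", "B"), c(n_a, nrow(gm$dosage) - n_a)))
}

# a site table with uninformative annotation, n sites on one chromosome
plain_sites <- function(n, chrom = "1", spacing = 1e4) {
  data.frame(chrom = chrom, pos = spacing * seq_len(n),
             ref = "A", alt = "G", ancestral = "A", gene = "",
             consequence = "synonymous", gerp_rs = 0,
             cadd = NA_real_, polyphen = NA_character_,
             stringsAsFactors = FALSE)
}

# small two-population scenario for statistical tests; returns loaded data
small_scenario <- function(seed, n_sites = 1500, n_ref = 15, n_iso = 15,
                           null = TRUE, ...) {
  args <- list(n_sites = n_sites, n_ref = n_ref, n_iso = n_iso,
               chrom_lengths = stats::setNames(rep(10e6, 4), paste0("chr", 1:4)),
               planted_region = NULL, ancestral_unknown_frac = 0,
               seed = seed, ...)
  if (null) args <- c(args, list(bottleneck_generations = 0, inbreeding_f = 0))
  dir <- withr::local_tempdir(.local_envir = parent.frame())
  sim <- simulate_scenario(do.call(scenario_params, args), dir)
  c(load_scenario(sim$paths), list(truth = sim$truth))
}

# QC fixture: sites violating exactly one rule each, plus clean sites.
# Authored expected counts: monomorphic 1, missingness 1, hwe 1, and two
# genotypes masked by the DP/GQ sub-filters (driving one extra
# missingness removal); 2 clean survivors plus the DP/GQ-masked-but-
# still-complete site.
qc_fixture <- function() {
  n_s <- 40                                   # 20 per population
  ids <- sprintf("S%02d", seq_len(n_s))
  panel <- make_panel(ids, rep(c("P1", "P2"), each = 20))
  set.seed(42)
  clean <- function() rbinom(n_s, 2, 0.4)
  d <- cbind(
    mono = rep(0L, n_s),                      # monomorphic
    miss = {x <- clean(); x[1:3] <- NA; x},   # 3/40 = 7.5% missing
    hwe  = rep(1L, n_s),                      # all heterozygous
    ok1  = clean(),
    ok2  = clean())
  gm <- make_gm(d, ids, polarized = FALSE)
  # DP low for two genotypes of site ok2 -> masked but under 5% missing
  gm$dp <- matrix(99, n_s, ncol(d)); gm$dp[1, 5] <- 2
  gm$gq <- matrix(99, n_s, ncol(d)); gm$gq[2, 5] <- 5
  sites <- plain_sites(ncol(d))
  list(gm = gm, sites = sites, panel = panel,
       expected = list(removed = c(monomorphic = 1L, missingness = 1L,
                                   hwe = 1L),
                       genotypes_masked = 2L, n_out = 2L))
}
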