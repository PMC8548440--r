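#' Deterministic worked micro-fixture
#'
#' An 8-sample (4 isolate + 4 reference), 80-site, two-chromosome
#' dataset built from fixed rules (no RNG) with hand-checkable
#' structure: one planted 60-SNP homozygous tract spanning 1.475 Mb in
#' sample ISO1 on chromosome 1; one fixed difference (per-site Fst
#' exactly 1) at chr2:100000; one site with the ALT base ancestral
#' (exercising dosage flipping) and one with unknown ancestral state
#' (removed at polarization). The returned manifest carries expected
#' values computed at authoring time with independent brute-force
#' oracles.
#'
#' @param dir output directory for `fixture.vcf`, `annotation.tsv`,
#'   `panel.tsv` (created if needed).
#' @return List: `paths`, `manifest` (expected downstream values),
#'   `derived` (the derived-coded dosage matrix the files encode).
#' @export
worked_fixture <- function(dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sites <- data.frame(
    chrom = rep(c("1", "2"), c(60, 20)),
    pos = c(25000L * 1:60, 100000L * 1:20),
    stringsAsFactors = FALSE)
  n <- 80L
  ids <- c(paste0("ISO", 1:4), paste0("REF", 1:4))
  d <- matrix(0L, 8, n, dimnames = list(ids, NULL))
  d[1, seq(2, 60, 2)] <- 2L                    # ISO1: 60-SNP homozygous run
  d[2:8, c(10, 30, 50)] <- 1L                  # run-breaking heterozygotes
  for (j in 2:8) for (i in seq(1, 59, 2))      # scattered low-frequency alleles
    if ((i + 3 * j) %% 11 == 0) d[j, i] <- 1L
  d[1:4, 61] <- 2L                             # fixed difference, Fst = 1
  for (j in 1:8) for (i in 62:80) {            # chr2 diversity pattern
    v <- (i * j) %% 5
    d[j, i] <- if (v == 0) 2L else if (v <= 2) 1L else 0L
  }

  ref_base <- rep(c("A", "C", "G", "T"), length.out = n)
  alt_base <- rep(c("G", "T", "A", "C"), length.out = n)
  ancestral <- ref_base
  ancestral[5] <- alt_base[5]                  # ALT-ancestral site (flip)
  ancestral[70] <- "."                         # unknown ancestral (dropped)
  gerp <- ifelse(seq_len(n) %% 2 == 1, -1,
                 c(3, 5, 7)[(seq_len(n) %/% 2 - 1) %% 3 + 1])
  consequence <- ifelse(seq_len(n) %% 2 == 1, "synonymous", "missense")
  annot <- data.frame(
    chrom = sites$chrom, pos = sites$pos, ref = ref_base, alt = alt_base,
    ancestral = ancestral,
    gene = paste0("FG", ceiling(seq_len(n) / 10)),
    consequence = consequence, gerp_rs = gerp,
    cadd = 3 * gerp + 5,
    polyphen = ifelse(gerp >= 6, "probably_damaging", "benign"),
    stringsAsFactors = FALSE)

  alt_dosage <- d
  alt_dosage[, 5] <- 2L - alt_dosage[, 5]      # VCF is alt-coded
  gm <- geno_matrix(alt_dosage, ids, polarized = FALSE)
  paths <- list(vcf = file.path(dir, "fixture.vcf"),
                annotation = file.path(dir, "annotation.tsv"),
                panel = file.path(dir, "panel.tsv"))
  write_vcf(gm, sites[, c("chrom", "pos")] |>
              cbind(ref = ref_base, alt = alt_base), paths$vcf)
  utils::write.table(annot, paths$annotation, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = ids, population = rep(c("ISO", "REF"), each = 4)),
    paths$panel, sep = "\t", quote = FALSE, row.names = FALSE)

  manifest <- fixture_manifest()
  list(paths = paths, manifest = manifest, derived = d, annot = annot)
}

# expected values for the worked fixture, frozen from brute-force
# oracles (exhaustive haplotype-pair differences for theta-pi, direct
# tallies for the rest) at authoring time
fixture_manifest <- function() {
  list(
    n_sites_polarized = 79L,
    flipped_sites = 1L,
    theta_pi_syn = c(ISO = 5, REF = 6.8571428571428568),
    theta_w_syn = c(ISO = 5.7851239669421481, REF = 7.327823691460055),
    s_seg_syn = c(ISO = 15L, REF = 19L),
    sfs_counts_iso_all = c(`1` = 8L, `2` = 42L, `3` = 0L, `4` = 0L,
                           `5` = 3L, `6` = 0L, `7` = 0L),
    fst_fixed_site = 1.0,
    roh = list(sample_id = "ISO1", chrom = "1", start = 25000L,
               end = 1500000L, n_snps = 60L, length = 1475001L),
    n_rohs_total = 1L,
    mean_burden_iso = c(n_alleles = 34.75, n_hom = 11.5)
  )
}
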