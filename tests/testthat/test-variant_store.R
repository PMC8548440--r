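write_test_vcf <- function(path, records,
                           samples = c("S01", "S02", "S03", "S04")) {
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    records), path)
}

rec <- function(chrom, pos, ref, alt, gts)
  paste(c(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT", gts),
        collapse = "\t")

test_that("read_vcf keeps biallelic autosomal SNPs and codes dosages", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, c(
    rec("1", 100, "A", "G", c("0/0", "0/1", "1/1", "./.")),
    rec("1", 200, "A", "AT", c("0/0", "0/0", "0/1", "0/0")),   # indel
    rec("1", 300, "C", "G,T", c("0/0", "0/1", "0/2", "0/0")),  # multiallelic
    rec("chrX", 400, "C", "T", c("0/0", "0/1", "0/0", "0/0")), # sex chrom
    rec("2", 500, "T", "C", c("0|1", "1|1", "0/0", "0/1"))))
  rv <- read_vcf(path)
  expect_equal(ncol(rv$gm$dosage), 2)
  expect_equal(unname(rv$dropped),
               c(1L, 1L, 1L))
  expect_equal(unname(rv$gm$dosage[, 1]), c(0L, 1L, 2L, NA))
  expect_equal(unname(rv$gm$dosage[, 2]), c(1L, 2L, 0L, 1L))
  expect_false(rv$gm$polarized)
})

test_that("read_vcf errors name the missing panel sample", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_test_vcf(path, rec("1", 100, "A", "G", c("0/0", "0/1", "1/1", "0/0")))
  panel <- make_panel(c("S01", "GHOST"), c("A", "B"))
  expect_error(read_vcf(path, panel), "GHOST")
})

test_that("VCF round trip preserves records and genotypes", {
  path <- withr::local_tempfile(fileext = ".vcf")
  set.seed(11)
  d <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5)
  gm <- make_gm(d, polarized = FALSE)
  sites <- plain_sites(12)
  write_vcf(gm, sites, path)
  rv <- read_vcf(path)
  expect_equal(unname(rv$gm$dosage), unname(d))
  expect_equal(rv$sites$pos, sites$pos)
  expect_equal(rv$sites$ref, sites$ref)
  expect_equal(rv$sites$alt, sites$alt)
})

test_that("exact HWE test matches closed-form small cases", {
  # all 50 individuals heterozygous: exact p is far below 1e-3
  expect_lt(hwe_exact_test(0, 50, 0), 1e-3)
  # perfect proportions at p = 0.5, n = 8: (2,4,2) is the modal table
  expect_gt(hwe_exact_test(2, 4, 2), 0.5)
  # monomorphic: p = 1
  expect_equal(hwe_exact_test(10, 0, 0), 1)
  # n = 2, one het one hom-alt: enumeration over het in {0, 2} given
  # 3 copies of the rare allele... rare = 3, hets in {1, 3}
  # P(h=1) = C * 3!/ (1! 1! 0!) ... verify symmetry instead: labels swap
  expect_equal(hwe_exact_test(3, 2, 5), hwe_exact_test(5, 2, 3))
})

test_that("site QC removes each authored violation once", {
  fx <- qc_fixture()
  out <- qc_filter_sites(fx$gm, fx$sites, fx$panel)
  expect_equal(out$report$removed[names(fx$expected$removed)],
               fx$expected$removed)
  expect_equal(out$report$genotypes_masked, fx$expected$genotypes_masked)
  expect_equal(ncol(out$gm$dosage), fx$expected$n_out)
})

test_that("site QC is idempotent", {
  fx <- qc_fixture()
  once <- qc_filter_sites(fx$gm, fx$sites, fx$panel)
  twice <- qc_filter_sites(once$gm, once$sites, fx$panel)
  expect_equal(sum(twice$report$removed), 0)
  expect_equal(ncol(twice$gm$dosage), ncol(once$gm$dosage))
})

test_that("sample QC drops high-missingness and het outliers", {
  set.seed(7)
  n_site <- 200
  d <- matrix(rbinom(20 * n_site, 2, 0.3), nrow = 20)
  d[1, 1:40] <- NA                      # 20% missing
  d[2, ] <- 1L                          # heterozygosity far above the rest
  gm <- make_gm(d, polarized = FALSE)
  panel <- make_panel(gm$sample_ids, rep("P", 20))
  out <- qc_filter_samples(gm, panel)
  expect_setequal(names(out$report$dropped), gm$sample_ids[1:2])
  expect_equal(unname(out$report$dropped[gm$sample_ids[1]]), "missingness")
  expect_equal(unname(out$report$dropped[gm$sample_ids[2]]), "heterozygosity")
  # all-identical heterozygosity: zero SD flags nobody
  d2 <- matrix(rep(c(0L, 1L), each = 10 * 6), nrow = 12)
  gm2 <- make_gm(d2, polarized = FALSE)
  out2 <- qc_filter_samples(gm2, make_panel(gm2$sample_ids, rep("P", 12)))
  expect_equal(length(out2$report$dropped), 0)
})

test_that("polarization flips ALT-ancestral sites and drops unknowns", {
  d <- rbind(c(1L, 0L, 2L, 1L), c(0L, 2L, NA, 0L))
  gm <- make_gm(d, polarized = FALSE)
  sites <- plain_sites(4)
  sites$ancestral <- c("A", "G", ".", "T")   # ref, alt, unknown, mismatch
  expect_warning(out <- polarize(gm, sites), "neither REF nor ALT")
  expect_equal(ncol(out$gm$dosage), 2)
  expect_equal(unname(out$gm$dosage[, 1]), c(1L, 0L))     # unchanged
  expect_equal(unname(out$gm$dosage[, 2]), c(2L, 0L))     # flipped
  expect_true(out$gm$polarized)
  expect_equal(unname(out$report["unknown_ancestral"]), 1L)
  expect_equal(unname(out$report["ancestral_mismatch"]), 1L)
  # involution: flipping twice restores the original dosages
  flip_once <- 2L - d[, 2]
  expect_equal(2L - flip_once, d[, 2])
})

test_that("derived frequency follows its definition and missing rules", {
  gm <- make_gm(matrix(c(2L, 1L, 0L, 1L), ncol = 1))
  panel <- make_panel(gm$sample_ids, rep("P", 4))
  expect_equal(derived_freq(gm, panel, "P"), 0.5)
  gm2 <- make_gm(matrix(c(0L, 0L, NA), ncol = 1))
  panel2 <- make_panel(gm2$sample_ids, rep("P", 3))
  expect_equal(derived_freq(gm2, panel2, "P"), 0)
  gm3 <- make_gm(matrix(c(NA_integer_, NA_integer_), ncol = 1))
  panel3 <- make_panel(gm3$sample_ids, rep("P", 2))
  expect_true(is.na(derived_freq(gm3, panel3, "P")))
})

test_that("dataset q is the diploid-count-weighted mean of population q", {
  set.seed(3)
  d <- matrix(sample(c(0:2, NA), 30 * 25, replace = TRUE,
                     prob = c(0.4, 0.3, 0.2, 0.1)), nrow = 30)
  gm <- make_gm(d)
  panel <- two_pop_panel(gm, 12)
  qa <- derived_freq(gm, panel, "A"); qb <- derived_freq(gm, panel, "B")
  na <- 2 * colSums(!is.na(d[1:12, , drop = FALSE]))
  nb <- 2 * colSums(!is.na(d[13:30, , drop = FALSE]))
  qall <- derived_freq(gm)
  w <- ifelse(na + nb > 0,
              (ifelse(na > 0, qa * na, 0) + ifelse(nb > 0, qb * nb, 0)) / (na + nb),
              NA_real_)
  expect_equal(qall, w, tolerance = 1e-12)
  expect_true(all(qall >= 0 & qall <= 1, na.rm = TRUE))
})
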