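test_that("identical seeds give byte-identical output files", {
  p <- scenario_params(n_sites = 300, n_ref = 6, n_iso = 6,
                       chrom_lengths = c(chr1 = 8e6, chr2 = 8e6), seed = 77)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  s1 <- simulate_scenario(p, d1)
  s2 <- simulate_scenario(p, d2)
  for (k in names(s1$paths))
    expect_identical(unname(tools::md5sum(s1$paths[[k]])),
                     unname(tools::md5sum(s2$paths[[k]])))
  # a different seed changes the genotype file
  s3 <- simulate_scenario(scenario_params(n_sites = 300, n_ref = 6, n_iso = 6,
                                          chrom_lengths = c(chr1 = 8e6, chr2 = 8e6),
                                          seed = 78),
                          withr::local_tempdir())
  expect_false(identical(unname(tools::md5sum(s1$paths$vcf)),
                         unname(tools::md5sum(s3$paths$vcf))))
})

test_that("emitted files parse back with no losses when QC is off", {
  dir <- withr::local_tempdir()
  sim <- simulate_scenario(scenario_params(n_sites = 400, n_ref = 8, n_iso = 8,
                                           chrom_lengths = c(chr1 = 10e6),
                                           ancestral_unknown_frac = 0,
                                           planted_region = NULL, seed = 5),
                           dir)
  sc <- load_scenario(sim$paths)
  expect_equal(ncol(sc$gm$dosage), 400)
  expect_equal(unname(sc$report["unknown_ancestral"]), 0L)
  expect_true(sc$gm$polarized)
  expect_equal(nrow(sc$gm$dosage), 16)
})

test_that("the null scenario is exchangeable between populations", {
  sc <- small_scenario(501, n_sites = 2000, n_ref = 20, n_iso = 20)
  bI <- per_individual_burden(gm_subset(sc$gm, pop_rows(sc$gm, sc$panel, "ISO")))
  bR <- per_individual_burden(gm_subset(sc$gm, pop_rows(sc$gm, sc$panel, "REF")))
  expect_equal(mean(bI$n_hom) / mean(bR$n_hom), 1, tolerance = 0.1)
  expect_equal(mean(bI$n_alleles) / mean(bR$n_alleles), 1, tolerance = 0.05)
})

test_that("autozygous tract coverage matches the inbreeding fraction", {
  # closed form: expected total tract length per genome = f x genome size
  dir <- withr::local_tempdir()
  sim <- simulate_scenario(
    scenario_params(n_sites = 100, n_ref = 2, n_iso = 60,
                    chrom_lengths = c(chr1 = 30e6, chr2 = 30e6),
                    inbreeding_f = 0.5, tract_mean_length = 2e6,
                    bottleneck_generations = 0, planted_region = NULL,
                    seed = 13), dir)
  tot <- vapply(sim$truth$tracts, function(tr)
    if (nrow(tr)) sum(tr$end - tr$start + 1) else 0, numeric(1))
  expect_equal(mean(tot) / 60e6, 0.5, tolerance = 0.08)
  # tracts are non-overlapping within a sample
  for (tr in sim$truth$tracts) {
    if (nrow(tr) < 2) next
    for (ch in unique(tr$chrom)) {
      t2 <- tr[tr$chrom == ch, ]; t2 <- t2[order(t2$start), ]
      if (nrow(t2) > 1) expect_true(all(t2$start[-1] > t2$end[-nrow(t2)]))
    }
  }
})

test_that("bottleneck drift removes heterozygosity at the closed-form rate", {
  # expected retained heterozygosity: (1 - 1/(2N))^g
  dir <- withr::local_tempdir()
  sim <- simulate_scenario(
    scenario_params(n_sites = 3000, n_ref = 2, n_iso = 2,
                    chrom_lengths = c(chr1 = 30e6),
                    bottleneck_size = 25, bottleneck_generations = 40,
                    inbreeding_f = 0, planted_region = NULL, seed = 17), dir)
  h_anc <- 2 * sim$truth$anc_freq * (1 - sim$truth$anc_freq)
  h_iso <- 2 * sim$truth$iso_freq * (1 - sim$truth$iso_freq)
  retained <- sum(h_iso) / sum(h_anc)
  expect_equal(retained, (1 - 1 / 50)^40, tolerance = 0.08)
})

test_that("mean derived frequency decreases with deleteriousness class", {
  sc <- small_scenario(601, n_sites = 4000, n_ref = 25, n_iso = 5)
  q <- derived_freq(sc$gm, sc$panel, "REF")
  cls <- category_scheme("gerp")$classify(sc$sites)
  m <- tapply(q, cls, mean)
  expect_true(m["neutral"] >= m["moderate"])
  expect_true(m["moderate"] >= m["large"])
  expect_true(m["large"] >= m["extreme"])
})

test_that("homozygosity responds monotonically to the inbreeding dial", {
  hom_mean <- function(f, seed) {
    sc <- small_scenario(seed, n_sites = 500, n_ref = 2, n_iso = 10,
                         null = FALSE, bottleneck_generations = 0,
                         inbreeding_f = f, tract_mean_length = 2e6)
    rows <- pop_rows(sc$gm, sc$panel, "ISO")
    mean(sc$gm$dosage[rows, ] != 1L, na.rm = TRUE)
  }
  lo <- vapply(1:10, function(i) hom_mean(0, 700 + i), numeric(1))
  hi <- vapply(1:10, function(i) hom_mean(0.4, 700 + i), numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("the worked fixture reproduces its authored manifest", {
  fx <- worked_fixture(withr::local_tempdir())
  man <- fx$manifest
  sc <- load_scenario(fx$paths)
  expect_equal(ncol(sc$gm$dosage), man$n_sites_polarized)
  expect_equal(unname(sc$report["flipped"]), man$flipped_sites)
  syn <- mask_synonymous(sc$sites)
  for (pop in c("ISO", "REF")) {
    expect_equal(theta_pi(sc$gm, sc$panel, pop, syn),
                 unname(man$theta_pi_syn[pop]), tolerance = 1e-12)
    expect_equal(watterson_theta(sc$gm, sc$panel, pop, syn),
                 unname(man$theta_w_syn[pop]), tolerance = 1e-12)
  }
  s <- build_sfs(sc$gm, sc$panel, "ISO", n_sub = 4, seed = 1)
  expect_equal(unname(s$counts), unname(man$sfs_counts_iso_all))
  f <- per_site_fst(sc$gm, sc$panel, "ISO", "REF")
  i_fixed <- which(sc$sites$chrom == "2" & sc$sites$pos == 100000)
  expect_equal(f$fst[i_fixed], man$fst_fixed_site)
  rohs <- detect_rohs_all(sc$gm, sc$sites)
  expect_equal(nrow(rohs), man$n_rohs_total)
  expect_equal(rohs$sample_id, man$roh$sample_id)
  expect_equal(rohs$n_snps, man$roh$n_snps)
  expect_equal(rohs$length, man$roh$length)
  b <- per_individual_burden(gm_subset(sc$gm, pop_rows(sc$gm, sc$panel, "ISO")))
  expect_equal(mean(b$n_alleles), unname(man$mean_burden_iso["n_alleles"]))
  expect_equal(mean(b$n_hom), unname(man$mean_burden_iso["n_hom"]))
})
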