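test_that("a planted homozygous tract is called as exactly one run", {
  n <- 60
  pos <- as.integer(seq(25000, by = 25000, length.out = n))  # 1.475 Mb span
  sites <- plain_sites(n)
  sites$pos <- pos
  d <- matrix(sample(c(0L, 2L), n, replace = TRUE), nrow = 1)
  gm <- make_gm(d, "S1")
  rohs <- detect_rohs(gm, sites, "S1")
  expect_equal(nrow(rohs), 1)
  expect_equal(rohs$n_snps, 60)
  expect_equal(rohs$start, 25000)
  expect_equal(rohs$end, 25000 * 60)
  expect_equal(rohs$length, rohs$end - rohs$start + 1L)
  # one heterozygote in the middle: both fragments fall under 50 SNPs
  d2 <- d; d2[1, 30] <- 1L
  expect_equal(nrow(detect_rohs(make_gm(d2, "S1"), sites, "S1")), 0)
  # a gap beyond max_gap splits the run
  sites3 <- sites; sites3$pos[31:60] <- sites3$pos[31:60] + 2e6
  expect_equal(nrow(detect_rohs(gm, sites3, "S1")), 0)  # fragments < 50 SNPs
})

test_that("run detection matches the independent scanner on random data", {
  set.seed(23)
  for (trial in 1:30) {
    n <- 400
    pos <- sort(sample.int(5e6, n))
    d <- sample(c(0L, 1L, 2L, NA), n, replace = TRUE,
                prob = c(0.55, 0.07, 0.35, 0.03))
    params <- roh_params(min_snps = sample(5:30, 1),
                         min_length = sample(c(1e4, 1e5, 5e5), 1),
                         max_gap = sample(c(5e4, 2e5, 1e6), 1))
    sites <- data.frame(chrom = "1", pos = pos)
    got <- detect_rohs(make_gm(matrix(d, 1), "S1"), sites, "S1", params)
    want <- oracle_roh_scan(d, pos, params$min_snps, params$min_length,
                            params$max_gap)
    expect_equal(nrow(got), nrow(want))
    if (nrow(want)) {
      expect_equal(got$start, unname(want$start))
      expect_equal(got$end, unname(want$end))
      expect_equal(got$n_snps, unname(want$n_snps))
    }
  }
})

test_that("detection ignores appended non-qualifying sites", {
  n <- 60
  sites <- plain_sites(n); sites$pos <- as.integer(seq(25000, by = 25000, length.out = n))
  d <- matrix(0L, 1, n)
  base <- detect_rohs(make_gm(d, "S1"), sites, "S1")
  # append a distant het site on the same chromosome
  sites2 <- rbind(sites, within(plain_sites(1), pos <- 20e6))
  d2 <- cbind(d, 1L)
  again <- detect_rohs(make_gm(d2, "S1"), sites2, "S1")
  expect_equal(base$start, again$start)
  expect_equal(base$end, again$end)
})

test_that("LD pruning removes later duplicates and keeps independents", {
  set.seed(29)
  x <- rbinom(30, 2, 0.5)
  y <- rbinom(30, 2, 0.5)
  d <- cbind(x, x, y)               # sites 1-2 identical, site 3 independent
  gm <- make_gm(d, polarized = FALSE)
  sites <- plain_sites(3, spacing = 1000)
  keep <- ld_prune(gm, sites)
  expect_equal(keep, c(TRUE, FALSE, TRUE))
  # single site passes through untouched
  expect_equal(ld_prune(gm_subset(gm, sites = 1), sites[1, , drop = FALSE]),
               TRUE)
})

test_that("windowed pruning equals all-pairs pruning when one window covers all", {
  set.seed(37)
  for (trial in 1:10) {
    n_site <- 40
    d <- matrix(rbinom(25 * n_site, 2, runif(n_site, 0.2, 0.8)),
                nrow = 25, byrow = FALSE)
    # duplicate a few columns to create high-LD pairs
    d[, sample(n_site, 8)] <- d[, sample(n_site, 8)]
    gm <- make_gm(d, polarized = FALSE)
    sites <- plain_sites(n_site, spacing = 100)   # all within one 50-kb window
    keep <- ld_prune(gm, sites, window_kb = 50, step_snps = 1,
                     r2_threshold = 0.8)
    expect_equal(keep, oracle_prune_all_pairs(d, 0.8))
  }
})

test_that("ROH summaries bin lengths and aggregate per individual", {
  rohs <- data.frame(sample_id = "S1", chrom = "1",
                     start = c(1, 1, 1), end = c(1.2e6, 3e6, 6e6),
                     length = c(1.2e6, 3e6, 6e6), n_snps = c(60, 80, 120),
                     stringsAsFactors = FALSE)
  panel <- make_panel(c("S1", "S2"), c("A", "B"))
  rs <- roh_summaries(rohs, panel)
  per <- rs$per_individual
  get <- function(cl) per[per$sample_id == "S1" & per$class == cl, ]
  expect_equal(get("all")$n, 3L)
  expect_equal(get("all")$total, 10.2e6)
  expect_equal(get("all")$mean, 3.4e6)
  expect_equal(get("1-2.5 Mb")$n, 1L)
  expect_equal(get("2.5-5 Mb")$n, 1L)
  expect_equal(get(">5 Mb")$n, 1L)
  expect_equal(per[per$sample_id == "S2" & per$class == "all", ]$n, 0L)
})

test_that("zygosity ratios count homozygotes by region and class", {
  # 10 alternating missense-moderate / synonymous-neutral sites; one
  # sample with a ROH covering sites 1..5 (3 missense + 2 synonymous)
  sites <- plain_sites(10, spacing = 1e5)
  sites$consequence <- rep(c("missense", "synonymous"), 5)
  sites$gerp_rs <- rep(c(3, 0), 5)
  d <- matrix(2L, 1, 10)
  d[1, 6] <- 1L                      # one het synonymous outside
  gm <- make_gm(d, "S1")
  panel <- make_panel("S1", "P")
  rohs <- data.frame(sample_id = "S1", chrom = "1", start = 1e5, end = 5e5,
                     length = 4e5 + 1, n_snps = 5, stringsAsFactors = FALSE)
  zr <- roh_zygosity_ratio(gm, sites, rohs, panel)
  inside <- zr$ratios[zr$ratios$region == "inside" &
                        zr$ratios$category == "moderate", ]
  expect_equal(inside$n_num, 3); expect_equal(inside$n_den, 2)
  expect_equal(inside$ratio, 1.5)
  outside <- zr$ratios[zr$ratios$region == "outside" &
                         zr$ratios$category == "moderate", ]
  expect_equal(outside$n_num, 2)     # missense sites 7 and 9
  expect_equal(outside$n_den, 2)     # site 6 is het, not counted
  # zero denominator flagged as NA, not zero
  gm2 <- make_gm(rbind(matrix(rep(c(2L, 1L), 5), 1)), "S1")
  zr2 <- roh_zygosity_ratio(gm2, sites, rohs[0, ], panel)
  out2 <- zr2$ratios[zr2$ratios$region == "outside" &
                       zr2$ratios$category == "moderate", ]
  expect_true(is.na(out2$ratio))
})

test_that("every emitted ROH satisfies the parameter constraints", {
  sc <- small_scenario(401, n_sites = 3000, n_ref = 5, n_iso = 8,
                       null = FALSE, inbreeding_f = 0.3,
                       tract_mean_length = 3e6)
  params <- roh_params(min_snps = 20, min_length = 5e5)
  rohs <- detect_rohs_all(sc$gm, sc$sites, params)
  expect_gt(nrow(rohs), 0)
  expect_true(all(rohs$n_snps >= params$min_snps))
  expect_true(all(rohs$length >= params$min_length))
  expect_true(all(rohs$length == rohs$end - rohs$start + 1))
  # runs for one sample on one chromosome do not overlap
  for (key in unique(paste(rohs$sample_id, rohs$chrom))) {
    r <- rohs[paste(rohs$sample_id, rohs$chrom) == key, ]
    r <- r[order(r$start), ]
    if (nrow(r) > 1) expect_true(all(r$start[-1] > r$end[-nrow(r)]))
  }
})
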