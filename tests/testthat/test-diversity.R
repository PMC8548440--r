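# brute_theta_pi / brute_tajima_d oracles live in helper-oracles.R

test_that("theta-pi matches hand-computed per-site values and is additive", {
  gm <- make_gm(rbind(c(1L, 1L), c(1L, 1L)))      # c = 2, 2n = 4 twice
  panel <- make_panel(gm$sample_ids, c("P", "P"))
  expect_equal(theta_pi(gm, panel, "P", 1), 2 * 2 * 2 / (4 * 3))
  expect_equal(theta_pi(gm, panel, "P"), 4 / 3, tolerance = 1e-12)
  # monomorphic site contributes zero
  gm0 <- make_gm(rbind(c(0L, 1L), c(0L, 1L)))
  expect_equal(theta_pi(gm0, make_panel(gm0$sample_ids, c("P", "P")), "P", 1), 0)
})

test_that("theta-pi equals the exhaustive pairwise oracle on random data", {
  set.seed(21)
  for (trial in 1:5) {
    d <- matrix(sample(c(0:2, NA), 4 * 80, replace = TRUE,
                       prob = c(0.45, 0.25, 0.2, 0.1)), nrow = 4)
    gm <- make_gm(d)
    panel <- make_panel(gm$sample_ids, rep("P", 4))
    expect_equal(theta_pi(gm, panel, "P"), brute_theta_pi(d),
                 tolerance = 1e-12)
  }
})

test_that("Watterson's estimator follows the harmonic-sum definition", {
  # 2 diploids (2n = 4), 11 segregating sites: a = 1 + 1/2 + 1/3
  d <- rbind(rep(1L, 11), rep(0L, 11))
  gm <- make_gm(d)
  panel <- make_panel(gm$sample_ids, c("P", "P"))
  expect_equal(watterson_theta(gm, panel, "P"), 11 / (1 + 1/2 + 1/3),
               tolerance = 1e-12)
  # no segregating sites
  gm0 <- make_gm(rbind(c(0L, 2L), c(0L, 2L)))
  expect_equal(watterson_theta(gm0, make_panel(gm0$sample_ids, c("P", "P")), "P"), 0)
  expect_error(watterson_theta(make_gm(matrix(1L, 1, 3)),
                               make_panel("S01", "P"), "P"), "2 diploids")
})

test_that("pi-var averages heterozygosity over variable sites only", {
  # site 1: c=2, 2n=4 -> 2/3; site 2: c=1 -> 1/2; site 3 monomorphic
  gm <- make_gm(rbind(c(1L, 1L, 0L), c(1L, 0L, 0L)))
  panel <- make_panel(gm$sample_ids, c("P", "P"))
  expect_equal(pi_var(gm, panel, "P"), mean(c(2/3, 1/2)), tolerance = 1e-12)
  gm0 <- make_gm(matrix(0L, 2, 4))
  expect_true(is.na(pi_var(gm0, make_panel(gm0$sample_ids, c("P", "P")), "P")))
})

test_that("Tajima's D matches the literal-formula oracle and sign logic", {
  # all singletons: D negative
  d_sing <- rbind(rep(1L, 10), rep(0L, 10))
  gm <- make_gm(d_sing)
  panel <- make_panel(gm$sample_ids, c("P", "P"))
  D <- tajimas_d(gm, panel, "P")
  expect_lt(D, 0)
  expect_equal(D, brute_tajima_d(4, 10, theta_pi(gm, panel, "P")),
               tolerance = 1e-10)
  # all doubletons at intermediate frequency: D positive
  d_doub <- rbind(rep(1L, 10), rep(1L, 10))
  gm2 <- make_gm(d_doub)
  expect_gt(tajimas_d(gm2, make_panel(gm2$sample_ids, c("P", "P")), "P"), 0)
  # random matrices against the oracle
  set.seed(5)
  for (trial in 1:5) {
    d <- matrix(rbinom(4 * 60, 2, 0.25), nrow = 4)
    gm3 <- make_gm(d)
    p3 <- make_panel(gm3$sample_ids, rep("P", 4))
    sc <- site_counts(gm3)
    S <- sum(sc$dac > 0 & sc$dac < sc$an)
    if (S == 0) next
    expect_equal(tajimas_d(gm3, p3, "P"),
                 brute_tajima_d(8, S, theta_pi(gm3, p3, "P")),
                 tolerance = 1e-10)
  }
})

test_that("segregating-site summaries count private and carried alleles", {
  # pop A (2 samples), pop B (2 samples)
  d <- rbind(c(1L, 0L, 2L), c(0L, 0L, 2L),   # A
             c(0L, 1L, 0L), c(0L, 1L, 0L))   # B
  gm <- make_gm(d)
  panel <- two_pop_panel(gm, 2)
  s <- segregating_site_summaries(gm, panel)
  # site 1 segregates only in A (private); site 2 only in B (private);
  # site 3 fixed derived in A (not segregating), absent in B
  expect_equal(s$s_seg[s$population == "A"], 1L)
  expect_equal(s$s_private[s$population == "A"], 1L)
  expect_equal(s$s_seg[s$population == "B"], 1L)
  expect_equal(s$s_private[s$population == "B"], 1L)
  # individual carrying dosages 0,1,2 over 3 segregating sites carries 2
  d2 <- rbind(c(0L, 1L, 2L), c(1L, 1L, 1L), c(1L, 0L, 0L))
  gm2 <- make_gm(d2)
  panel2 <- make_panel(gm2$sample_ids, rep("P", 3))
  s2 <- segregating_site_summaries(gm2, panel2)
  expect_equal(s2$mean_carried, mean(c(2, 3, 1)))
})

test_that("block bootstrap is deterministic and degenerate on constants", {
  b <- block_bootstrap(function(i) 42, n_site = 100, n_blocks = 10,
                       n_reps = 50, seed = 9)
  expect_equal(b$lo, 42); expect_equal(b$hi, 42); expect_equal(b$estimate, 42)
  x <- rnorm(200)
  b1 <- block_bootstrap(function(i) mean(x[i]), 200, 50, 100, seed = 4)
  b2 <- block_bootstrap(function(i) mean(x[i]), 200, 50, 100, seed = 4)
  expect_identical(b1$reps, b2$reps)
  expect_warning(block_bootstrap(function(i) 1, n_site = 5, n_blocks = 10,
                                 n_reps = 5, seed = 1), "fewer sites")
})

test_that("block bootstrap interval width tracks the i.i.d. closed form", {
  set.seed(31)
  x <- rnorm(5000)
  b <- block_bootstrap(function(i) mean(x[i]), 5000, n_blocks = 1000,
                       n_reps = 400, seed = 2)
  expect_equal(b$hi - b$lo, 2 * 1.96 * sd(x) / sqrt(5000), tolerance = 0.15)
})
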