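# independent reference implementations used to cross-check the package

# brute-force theta-pi: explicit haplotype expansion and enumeration of
# every haplotype pair, per site, over the non-missing subset
brute_theta_pi <- function(d) {
  total <- 0
  for (j in seq_len(ncol(d))) {
    g <- d[, j]; g <- g[!is.na(g)]
    hap <- unlist(lapply(g, function(x) c(rep(1, x), rep(0, 2 - x))))
    m <- length(hap)
    if (m < 2) next
    diffs <- 0
    for (a in seq_len(m - 1)) for (b in seq(a + 1, m))
      diffs <- diffs + (hap[a] != hap[b])
    total <- total + diffs / choose(m, 2)
  }
  total
}

# literal transcription of the 1989 variance-constants formula
brute_tajima_d <- function(n, S, tp) {
  a1 <- sum(1 / seq_len(n - 1)); a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1; c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (tp - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# straightforward run scanner over one chromosome: walks site by site,
# extending a run while calls stay homozygous and gaps stay small, and
# emits it when it meets the SNP-count and span thresholds
oracle_roh_scan <- function(dosage, pos, min_snps, min_length, max_gap) {
  runs <- list()
  start_i <- NA
  prev_i <- NA
  flush <- function(a, b) {
    if (!is.na(a)) {
      n <- b - a + 1
      span <- pos[b] - pos[a] + 1
      if (n >= min_snps && span >= min_length)
        runs[[length(runs) + 1]] <<- c(start = pos[a], end = pos[b], n_snps = n)
    }
  }
  for (i in seq_along(pos)) {
    hom <- !is.na(dosage[i]) && dosage[i] != 1
    if (hom) {
      if (is.na(start_i)) {
        start_i <- i
      } else if (pos[i] - pos[prev_i] > max_gap) {
        flush(start_i, prev_i)
        start_i <- i
      }
      prev_i <- i
    } else {
      flush(start_i, prev_i)
      start_i <- NA
    }
  }
  flush(start_i, prev_i)
  if (!length(runs))
    return(data.frame(start = numeric(0), end = numeric(0), n_snps = numeric(0)))
  as.data.frame(do.call(rbind, runs))
}

# literal transcription of the two-population variance-component Fst
# estimator, scalar, from genotype counts of one site
oracle_wc_fst <- function(gA, gB) {
  gA <- gA[!is.na(gA)]; gB <- gB[!is.na(gB)]
  n1 <- length(gA); n2 <- length(gB)
  p1 <- sum(gA) / (2 * n1); p2 <- sum(gB) / (2 * n2)
  h1 <- mean(gA == 1); h2 <- mean(gB == 1)
  r <- 2
  nbar <- mean(c(n1, n2))
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (n1 + n2)
  ssq <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (n1 + n2)
  a <- nbar / nc * (ssq - 1 / (nbar - 1) *
                      (pbar * (1 - pbar) - (r - 1) / r * ssq - hbar / 4))
  b <- nbar / (nbar - 1) * (pbar * (1 - pbar) - (r - 1) / r * ssq -
                              (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  if (a + b + cc <= 0) return(NA_real_)
  a / (a + b + cc)
}

# exhaustive all-pairs greedy pruning on a small window-free toy: remove
# the later of any pair above the threshold, scanning pairs left to right
oracle_prune_all_pairs <- function(d, r2_threshold) {
  n <- ncol(d)
  keep <- rep(TRUE, n)
  for (a in seq_len(n - 1)) {
    if (!keep[a]) next
    for (b in seq(a + 1, n)) {
      if (!keep[b]) next
      ok <- !is.na(d[, a]) & !is.na(d[, b])
      if (sum(ok) < 2) next
      r <- suppressWarnings(stats::cor(d[ok, a], d[ok, b]))
      if (!is.na(r) && r^2 > r2_threshold) keep[b] <- FALSE
    }
  }
  keep
}
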