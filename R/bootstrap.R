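#' Block bootstrap over genomic sites
#'
#' Partitions the (genomically ordered) sites into `n_blocks` contiguous
#' near-equal blocks; each replicate draws `n_blocks` blocks with
#' replacement, concatenates their site indices and recomputes the
#' statistic. This resamples linked stretches of the exome together and
#' so carries demographic (not just sampling) variance into the interval.
#'
#' @param statistic function taking an integer vector of site indices and
#'   returning a scalar.
#' @param n_site number of sites (indices `1:n_site`, in genomic order).
#' @param n_blocks number of contiguous blocks (reduced, with a warning,
#'   if it exceeds `n_site`).
#' @param n_reps bootstrap replicate count.
#' @param seed RNG seed.
#' @param null_value optional reference value; when given, a two-sided
#'   p-value is computed as `2 * min(Pr(rep <= null), Pr(rep >= null))`.
#' @return A `boot_result` list: `estimate` (full-data statistic), `lo`,
#'   `hi` (0.025/0.975 replicate quantiles), `n_reps`, `p_value` (or
#'   `NA`), and the replicate vector `reps`.
#' @export
block_bootstrap <- function(statistic, n_site, n_blocks = 1000,
                            n_reps = 1000, seed = 1, null_value = NULL) {
  if (n_blocks > n_site) {
    warning("fewer sites than blocks; using one block per site")
    n_blocks <- n_site
  }
  blocks <- block_partition(n_site, n_blocks)
  est <- statistic(seq_len(n_site))
  old <- get_rng_state()
  on.exit(restore_rng_state(old))
  set.seed(seed)
  reps <- vapply(seq_len(n_reps), function(r) {
    pick <- sample.int(n_blocks, n_blocks, replace = TRUE)
    statistic(unlist(blocks[pick], use.names = FALSE))
  }, numeric(1))
  q <- stats::quantile(reps, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  p <- if (is.null(null_value)) NA_real_ else
    min(1, 2 * min(mean(reps <= null_value, na.rm = TRUE),
                   mean(reps >= null_value, na.rm = TRUE)))
  structure(list(estimate = est, lo = q[1], hi = q[2], n_reps = n_reps,
                 p_value = p, reps = reps),
            class = "boot_result")
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("estimate %.6g  [%.6g, %.6g]  (%d reps%s)\n", x$estimate,
              x$lo, x$hi, x$n_reps,
              if (is.na(x$p_value)) "" else sprintf(", p = %.3g", x$p_value)))
  invisible(x)
}

# contiguous near-equal partition of 1:n into k blocks
block_partition <- function(n, k) {
  cuts <- floor(seq(0, n, length.out = k + 1))
  lapply(seq_len(k), function(i) seq.int(cuts[i] + 1L, cuts[i + 1L]))
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", state, envir = globalenv())
  invisible(NULL)
}
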