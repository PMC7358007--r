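# Small configs and independent brute-force oracles used across tests.

tiny_config <- function(seed = 1L, n_pcg = 20L, n_npcg = 0L, n_krtap = 0L,
                        chrom_start = 1e6, chrom_end = 2e6,
                        planted_deletions = tibble::tibble(start = integer(),
                                                           end = integer()),
                        n_host_genes = 50L, ...) {
  sim_config(seed = seed, n_pcg = n_pcg, n_npcg = n_npcg, n_krtap = n_krtap,
             chrom_start = chrom_start, chrom_end = chrom_end,
             planted_deletions = planted_deletions,
             gene_length_min = 1e3, gene_length_max = 5e3,
             bin_size = 1e4, n_host_genes = n_host_genes, ...)
}

# per-base enumeration: does [start, end] share any base with any interval?
oracle_overlap <- function(start, end, intervals) {
  vapply(seq_along(start), function(i) {
    bases <- seq(start[i], end[i])
    hit <- FALSE
    for (j in seq_len(nrow(intervals))) {
      hit <- hit || any(bases >= intervals$start[j] & bases <= intervals$end[j])
    }
    hit
  }, logical(1))
}

# exhaustive run-scan over bins: independent of the rle/split implementation
oracle_call_deletions <- function(norm, threshold, min_bins, gap) {
  low <- norm < threshold
  calls <- list()
  i <- 1L
  n <- length(low)
  while (i <= n) {
    if (!low[i]) { i <- i + 1L; next }
    first <- i
    last <- i
    j <- i + 1L
    run_gap <- 0L
    while (j <= n) {
      if (low[j]) {
        last <- j
        run_gap <- 0L
      } else {
        run_gap <- run_gap + 1L
        if (run_gap > gap) break
      }
      j <- j + 1L
    }
    if (last - first + 1L >= min_bins) {
      calls[[length(calls) + 1L]] <- c(first = first, last = last)
    }
    i <- j + 1L
  }
  calls
}

# two-sided exact binomial p-value by exhaustive tail summation
oracle_exact_binom_p <- function(k, n, p0) {
  d <- stats::dbinom(0:n, n, p0)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# textbook Wilson closed form, written independently of the package version
oracle_wilson <- function(k, n, conf = 0.95) {
  z <- stats::qnorm(1 - (1 - conf) / 2)
  ph <- k / n
  a <- (ph + z^2 / (2 * n)) / (1 + z^2 / n)
  b <- z / (1 + z^2 / n) * sqrt(ph * (1 - ph) / n + z^2 / (4 * n^2))
  c(a - b, a + b)
}
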