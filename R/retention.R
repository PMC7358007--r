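#' Wilson score interval for a binomial proportion
#'
#' Closed-form Wilson interval; unlike the Wald interval it behaves sensibly
#' at the boundary p-hat near 1 where retention data live.
#'
#' @param n_positive,n_cells Successes and trials (vectorized).
#' @param conf Confidence level.
#' @return Tibble with ci_low and ci_high.
#' @keywords internal
wilson_interval <- function(n_positive, n_cells, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  p <- n_positive / n_cells
  denom <- 1 + z^2 / n_cells
  centre <- (p + z^2 / (2 * n_cells)) / denom
  half <- z * sqrt(p * (1 - p) / n_cells + z^2 / (4 * n_cells^2)) / denom
  tibble(ci_low = pmax(centre - half, 0), ci_high = pmin(centre + half, 1))
}

#' Estimate per-tissue transchromosome retention
#'
#' Retention is the fraction of assayed cells in which the transchromosome is
#' detected; the estimate is `n_positive / n_cells` with a Wilson score
#' interval.
#'
#' @param obs Tibble with columns n_cells and n_positive (one row per tissue;
#'   tissue/method columns are carried through).
#' @param conf Confidence level of the interval.
#' @return The input tibble (class `tc_retention`) with p_hat, ci_low,
#'   ci_high added.
#' @export
estimate_retention <- function(obs, conf = 0.95) {
  stopifnot(all(c("n_cells", "n_positive") %in% names(obs)))
  if (any(obs$n_cells <= 0)) abort("`n_cells` must be positive.")
  if (any(obs$n_positive < 0 | obs$n_positive > obs$n_cells)) {
    abort("`n_positive` must lie in [0, n_cells].")
  }
  ci <- wilson_interval(obs$n_positive, obs$n_cells, conf)
  out <- dplyr::mutate(obs, p_hat = .data$n_positive / .data$n_cells,
                       ci_low = ci$ci_low, ci_high = ci$ci_high)
  class(out) <- c("tc_retention", class(out))
  out
}

#' Pool retention observations across tissues
#'
#' Sums cells and positives over all tissues, estimates the pooled retention,
#' and attaches per-tissue estimates.
#'
#' @param obs Tibble of per-tissue counts (n_cells, n_positive).
#' @param conf Confidence level.
#' @return List with `pooled` (one-row `tc_retention`) and `per_tissue`.
#' @export
pool_retention <- function(obs, conf = 0.95) {
  if (nrow(obs) == 0) abort("no tissues to pool.")
  pooled <- estimate_retention(
    tibble(n_cells = sum(obs$n_cells), n_positive = sum(obs$n_positive)),
    conf = conf)
  list(pooled = pooled, per_tissue = estimate_retention(obs, conf = conf))
}

#' Summarize per-cell detections into per-tissue counts
#'
#' @param cells Tibble with tissue and detected (0/1) columns, as from
#'   [sim_cells()] or [read_cells()].
#' @return Tibble with tissue, n_cells, n_positive.
#' @export
tally_cells <- function(cells) {
  dplyr::summarise(cells, n_cells = dplyr::n(),
                   n_positive = sum(.data$detected), .by = "tissue")
}

#' Exact binomial screen for mosaic tissues
#'
#' One-sided exact binomial test of retention below `threshold` in each
#' tissue; a tissue is flagged mosaic-suspect when the null p >= threshold is
#' rejected downward at level `alpha`. The source data make no formal
#' mosaicism claim; this is an exploratory screen.
#'
#' @param obs Tibble of per-tissue counts (n_cells, n_positive).
#' @param threshold Retention below which a tissue counts as mosaic.
#' @param alpha Rejection level.
#' @return The input tibble with p_value and mosaic_suspect columns.
#' @export
test_mosaicism <- function(obs, threshold = 0.9, alpha = 0.05) {
  stopifnot(threshold >= 0, threshold <= 1)
  p <- purrr::map2_dbl(obs$n_positive, obs$n_cells, function(k, n) {
    binom.test(k, n, p = threshold, alternative = "less")$p.value
  })
  dplyr::mutate(obs, p_value = p, mosaic_suspect = p < alpha)
}

#' @exportS3Method generics::tidy
tidy.tc_retention <- function(x, ...) as_tibble(unclass_first(x))

#' @exportS3Method generics::glance
glance.tc_retention <- function(x, ...) {
  tibble(n_tissues = nrow(x), min_p_hat = min(x$p_hat),
         pooled_p_hat = sum(x$n_positive) / sum(x$n_cells))
}
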