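#' Plot a binned depth profile with deletion calls
#'
#' @param depth Depth tibble (optionally normalized).
#' @param calls Optional `tc_deletions` tibble to shade.
#' @return A ggplot.
#' @export
plot_depth <- function(depth, calls = NULL) {
  ycol <- if ("norm_depth" %in% names(depth)) "norm_depth" else "depth"
  p <- ggplot2::ggplot(depth,
                       ggplot2::aes(x = .data$start / 1e6,
                                    y = .data[[ycol]])) +
    ggplot2::geom_step(linewidth = 0.3) +
    ggplot2::labs(x = "position (Mb)",
                  y = if (ycol == "norm_depth") "normalized depth" else
                    "reads per bin") +
    ggplot2::theme_minimal()
  if (!is.null(calls) && nrow(calls) > 0) {
    p <- p + ggplot2::geom_rect(
      data = as_tibble(unclass_first(calls)),
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "red", alpha = 0.2)
  }
  p
}

#' Plot per-pair dosage ratios
#'
#' Shows R_h (human/euploid), R_m (ortholog trisomic/euploid) and R_tot per
#' pair, with the 1.3-1.7 expected band for R_tot.
#'
#' @param records A `tc_dosage` table.
#' @return A ggplot.
#' @export
plot_dosage <- function(records) {
  long <- records |>
    as_tibble() |>
    dplyr::mutate(idx = dplyr::row_number()) |>
    tidyr::pivot_longer(c("r_h", "r_m", "r_tot"),
                        names_to = "metric", values_to = "ratio")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$idx, y = .data$ratio,
                                     colour = .data$metric)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = 1.3, ymax = 1.7,
                      alpha = 0.15, fill = "grey50") +
    ggplot2::geom_point(size = 0.8, alpha = 0.7) +
    ggplot2::labs(x = "ortholog pair", y = "ratio to euploid ortholog") +
    ggplot2::theme_minimal()
}

#' Plot per-tissue retention estimates with Wilson intervals
#'
#' @param estimates A `tc_retention` table (see [estimate_retention()]).
#' @return A ggplot.
#' @export
plot_retention <- function(estimates) {
  ggplot2::ggplot(as_tibble(unclass_first(estimates)),
                  ggplot2::aes(x = .data$tissue, y = .data$p_hat)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "retention rate") +
    ggplot2::theme_minimal()
}

#' Plot group retained-memory trajectories
#'
#' @param ... Named probe-trial tibbles, one per group.
#' @param zone Zone label to analyse.
#' @return A ggplot.
#' @export
plot_retained_memory <- function(..., zone = "SE") {
  groups <- list(...)
  stopifnot(length(groups) > 0, !is.null(names(groups)))
  long <- purrr::imap(groups, function(tr, nm) {
    dplyr::mutate(retained_memory_summary(tr, zone = zone), group = nm)
  }) |> dplyr::bind_rows()
  ggplot2::ggplot(long, ggplot2::aes(x = .data$day,
                                     y = .data$mean_retained_pct,
                                     colour = .data$group)) +
    ggplot2::geom_hline(yintercept = 100, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "reversal day", y = "retained memory (%)") +
    ggplot2::theme_minimal()
}
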