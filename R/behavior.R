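#' Probe-trial chance level in a circular tank
#'
#' Fraction of a circular water-maze tank covered by the largest circle
#' inscribed in one quadrant (the target zone of a probe trial). The circle
#' tangent to both bounding radii and the arc of a quarter-disc of radius R
#' has radius `R (sqrt(2) - 1)`, so the area fraction is
#' `(sqrt(2) - 1)^2 = 3 - 2 sqrt(2)`, about 0.1716, i.e. a 17% chance level.
#' Dimensionless: independent of tank diameter.
#'
#' @return The area fraction (~0.1716).
#' @examples
#' round(100 * chance_level_circular())  # 17
#' @export
chance_level_circular <- function() {
  3 - 2 * sqrt(2)
}

#' Centre-zone chance level in a square open field
#'
#' Fraction of a square arena covered by a centred square zone:
#' `(zone_side / field_side)^2`. With a 37 cm field and a 21.6 cm centre zone
#' this is ~34%.
#'
#' @param field_side Arena side length.
#' @param zone_side Centre-zone side length; must not exceed `field_side`.
#' @return The area fraction.
#' @export
chance_level_square <- function(field_side, zone_side) {
  if (field_side <= 0 || zone_side <= 0) abort("dimensions must be positive.")
  if (zone_side > field_side) abort("zone must fit inside the arena.")
  (zone_side / field_side)^2
}

#' Per-animal retained-memory percentages across reversal days
#'
#' Normalizes each animal's time fraction in the old target zone to its own
#' day-1 (pre-reversal) value: day 1 is 100% and day d is
#' `fraction(day d) / fraction(day 1) * 100`. Values may exceed 100%. A zero
#' day-1 baseline makes the normalization undefined and is an error.
#'
#' @param trials Tibble with animal_id, day, time_fraction and optionally
#'   zone_label columns (trial 1 of each reversal day).
#' @param zone Zone to analyse when a zone_label column is present.
#' @return Tibble with animal_id, day, retained_pct.
#' @export
retained_memory <- function(trials, zone = "SE") {
  if ("zone_label" %in% names(trials)) {
    trials <- dplyr::filter(trials, .data$zone_label == zone)
  }
  stopifnot(all(c("animal_id", "day", "time_fraction") %in% names(trials)))
  base <- trials |>
    dplyr::slice_min(.data$day, n = 1, by = "animal_id", with_ties = FALSE) |>
    dplyr::select("animal_id", baseline = "time_fraction")
  if (any(base$baseline <= 0)) {
    abort("day-1 baseline fraction is 0 for some animal; retained memory undefined.")
  }
  trials |>
    dplyr::left_join(base, by = "animal_id") |>
    dplyr::mutate(retained_pct = .data$time_fraction / .data$baseline * 100) |>
    dplyr::select("animal_id", "day", "retained_pct")
}

#' Group-mean retained memory per day
#'
#' @param trials Probe-trial tibble (see [retained_memory()]).
#' @param zone Zone label to analyse.
#' @return Tibble with day, mean_retained_pct, n.
#' @export
retained_memory_summary <- function(trials, zone = "SE") {
  retained_memory(trials, zone = zone) |>
    dplyr::summarise(mean_retained_pct = mean(.data$retained_pct),
                     n = dplyr::n(), .by = "day") |>
    dplyr::arrange(.data$day)
}

#' Germline transmission rate of the transchromosome
#'
#' Proportion of offspring carrying the transchromosome, with a Wilson 95%
#' interval and a two-sided exact binomial test against the Mendelian 50%
#' expectation for a freely segregating chromosome.
#'
#' @param n_offspring Total pups scored.
#' @param n_positive Transchromosome-positive pups.
#' @param conf Confidence level.
#' @return One-row tibble with n_offspring, n_positive, proportion, ci_low,
#'   ci_high, p_value.
#' @export
transmission_rate <- function(n_offspring, n_positive, conf = 0.95) {
  if (n_offspring <= 0) abort("`n_offspring` must be positive.")
  if (n_positive < 0 || n_positive > n_offspring) {
    abort("`n_positive` must lie in [0, n_offspring].")
  }
  ci <- wilson_interval(n_positive, n_offspring, conf)
  tibble(n_offspring = n_offspring, n_positive = n_positive,
         proportion = n_positive / n_offspring,
         ci_low = ci$ci_low, ci_high = ci$ci_high,
         p_value = binom.test(n_positive, n_offspring, 0.5)$p.value)
}
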