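# Spore-grid survival percentages, statistical errors, and colony sizes.

#' Per-genotype spore survival and colony-size summary
#'
#' For each genotype in a spore-grid table: the percentage of surviving
#' colonies, `100 * n_observed / n_expected`; its statistical error,
#' `pct / sqrt(n_observed)` (the printed error formula — a binomial standard
#' error is also provided as `pct_error_binomial` for comparison); and the
#' mean and SD of the colony radius over surviving colonies only.
#'
#' @param spore_table Data frame with columns `genotype`, `survived`
#'   (logical), `radius` (NA for non-survivors), e.g. from
#'   [gen_spore_grid()].
#' @param expected_per_genotype Expected number of spores per genotype
#'   (default 50: ~810 positions over 16 genotypes).
#' @return A tibble with one row per genotype: `genotype`, `n_observed`,
#'   `n_expected`, `pct_surviving`, `pct_error` (NA and flagged when no
#'   colony was observed), `pct_error_undefined`, `pct_error_binomial`,
#'   `mean_radius`, `sd_radius`.
#' @export
#' @examples
#' grid <- gen_spore_grid(synth_config(seed = 1))
#' survival_summary(grid)
survival_summary <- function(spore_table, expected_per_genotype = 50) {
  if (expected_per_genotype <= 0) abort("expected_per_genotype must be > 0")
  d <- as_tibble(spore_table)
  stopifnot(all(c("genotype", "survived", "radius") %in% names(d)))
  d |>
    group_by(.data$genotype) |>
    summarise(
      n_observed = sum(.data$survived),
      n_expected = expected_per_genotype,
      mean_radius = if (any(.data$survived))
        mean(.data$radius[.data$survived]) else NA_real_,
      sd_radius = if (sum(.data$survived) > 1)
        sd(.data$radius[.data$survived]) else NA_real_,
      .groups = "drop"
    ) |>
    mutate(
      pct_surviving = 100 * .data$n_observed / .data$n_expected,
      pct_error = ifelse(.data$n_observed > 0,
                         .data$pct_surviving / sqrt(.data$n_observed),
                         NA_real_),
      pct_error_undefined = .data$n_observed == 0,
      # observed can exceed expected (genotype draws fluctuate around the
      # grid average), so the binomial proportion is clamped to [0, 1]
      p_hat = pmin(pmax(.data$n_observed / .data$n_expected, 0), 1),
      pct_error_binomial =
        100 * sqrt(.data$p_hat * (1 - .data$p_hat) / .data$n_expected)
    ) |>
    select("genotype", "n_observed", "n_expected", "pct_surviving",
           "pct_error", "pct_error_undefined", "pct_error_binomial",
           "mean_radius", "sd_radius") |>
    arrange(.data$genotype)
}

#' Colony-formation frequency with binomial standard error
#'
#' @param n_colonies Number of colonies observed.
#' @param n_plated Number of spores plated (> 0).
#' @return A one-row tibble: `frequency` (= `n_colonies / n_plated`) and
#'   `se` (= `sqrt(f * (1 - f) / n_plated)`).
#' @export
#' @examples
#' colony_count_frequency(6, 1e5) # 6e-05, the bem1-deletion scale
colony_count_frequency <- function(n_colonies, n_plated) {
  if (n_plated <= 0) abort("n_plated must be > 0")
  if (n_colonies < 0 || n_colonies > n_plated) {
    abort("n_colonies must be in [0, n_plated]")
  }
  f <- n_colonies / n_plated
  tibble(frequency = f, se = sqrt(f * (1 - f) / n_plated),
         n_colonies = n_colonies, n_plated = n_plated)
}
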