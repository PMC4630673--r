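# ggplot2 views of the main result types.

#' Plot a count-time series with its exponential fit
#'
#' @param data Tibble with `time_h` and `count` columns.
#' @param fit Optional `growth_fit` to overlay.
#' @return A ggplot.
#' @export
plot_growth_series <- function(data, fit = NULL) {
  p <- ggplot2::ggplot(data, ggplot2::aes(.data$time_h, .data$count)) +
    ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "time (h)", y = "cell count (log scale)")
  if (!is.null(fit)) {
    p <- p + ggplot2::geom_function(
      fun = function(t) exp(fit$intercept + fit$rate * t),
      colour = "firebrick"
    )
  }
  p
}

#' Plot a cell-size distribution with its log-normal fit
#'
#' @param samples Numeric vector of sizes.
#' @param fit Optional `size_fit` to overlay (density curve and mode line).
#' @return A ggplot.
#' @export
plot_size_distribution <- function(samples, fit = NULL) {
  d <- tibble(size = as.numeric(samples))
  p <- ggplot2::ggplot(d, ggplot2::aes(.data$size)) +
    ggplot2::geom_histogram(ggplot2::aes(y = ggplot2::after_stat(density)),
                            bins = 60, fill = "grey70") +
    ggplot2::labs(x = "cell size (a.u.)", y = "density")
  if (!is.null(fit)) {
    p <- p +
      ggplot2::geom_function(
        fun = function(x) stats::dlnorm(x, fit$mu, fit$sigma),
        colour = "firebrick"
      ) +
      ggplot2::geom_vline(xintercept = fit$mode, linetype = 2)
  }
  p
}

#' Plot clamped allele-fraction time courses per locus
#'
#' @param timecourse Tibble from [sanger_timecourse()] (columns `locus`,
#'   `generation`, `f`).
#' @return A ggplot of the sweep curves.
#' @export
plot_sweeps <- function(timecourse) {
  ggplot2::ggplot(timecourse,
                  ggplot2::aes(.data$generation, .data$f,
                               colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::labs(x = "generations", y = "mutant-allele fraction",
                  colour = "locus")
}

#' @export
autoplot.fitness_landscape <- function(object, ...) {
  d <- mutate(as_tibble(object),
              label = genotype_label(.data$genotype, landscape_loci(object)),
              n_deletions = vapply(.data$genotype,
                                   function(g) sum(genotype_bits(g)),
                                   numeric(1)))
  ggplot2::ggplot(d, ggplot2::aes(stats::reorder(.data$label, .data$rate),
                                  .data$rate)) +
    ggplot2::geom_col(ggplot2::aes(fill = factor(.data$n_deletions))) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$rate - .data$se,
                                        ymax = .data$rate + .data$se),
                           width = 0.3) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "growth rate (per h)", fill = "deletions")
}

#' @export
autoplot.evolution_sim <- function(object, ...) {
  ggplot2::ggplot(object$allele_freq,
                  ggplot2::aes(.data$passage, .data$frequency,
                               colour = .data$locus)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "passage", y = "mutant-allele frequency",
                  colour = "locus")
}

#' Plot cohort polarity time budgets as horizontal stacked bars
#'
#' @param cohorts Tibble with a `strain` column and the
#'   [summarize_cohort()] columns (one row per strain).
#' @return A ggplot: for each strain, the mean latency from cytokinesis to
#'   the first spot followed by the mean time with 0-3 spots.
#' @export
plot_polarity_budget <- function(cohorts) {
  long <- cohorts |>
    select("strain", "mean_t_fs_c", dplyr::starts_with("mean_time_")) |>
    tidyr::pivot_longer(-"strain", names_to = "segment",
                        values_to = "minutes") |>
    mutate(segment = factor(
      .data$segment,
      levels = rev(c("mean_t_fs_c", "mean_time_0_spots", "mean_time_1_spots",
                     "mean_time_2_spots", "mean_time_3_spots")),
      labels = rev(c("to first spot", "0 spots", "1 spot",
                     "2 spots", "3 spots"))
    ))
  ggplot2::ggplot(long, ggplot2::aes(.data$minutes, .data$strain,
                                     fill = .data$segment)) +
    ggplot2::geom_col(position = ggplot2::position_stack()) +
    ggplot2::labs(x = "mean time (min)", y = NULL, fill = NULL)
}
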