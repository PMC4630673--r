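#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter the synthetic-data module needs to emulate the
#' inputs of the evolution-experiment pipeline: exponential growth curves with
#' multiplicative counting noise, log-normal cell-size distributions,
#' logistic selective sweeps read out as Sanger peak heights, a toy annotated
#' genome with planted variants of every class, spore grids from a
#' four-locus heterozygous-diploid cross, and per-cell polarity-spot traces.
#' All randomness flows from `seed` through named substreams
#' (see [substream_seed()]), so any one generator can be re-run independently
#' and identical configurations produce identical outputs.
#'
#' Default parameters describe the study system: four loci
#' (BEM1, BEM2, BEM3, NRP1), a wild-type growth rate of 0.5/h with the
#' starting bem1-deleted genotype 12-fold slower, 5% multiplicative noise on
#' Coulter-style counts, wild-type cell sizes around mode 40 (arbitrary
#' positive units) versus large, broad bem1-deleted distributions, sweeps of
#' BEM3 then NRP1 then BEM2 over 1000 generations, and ten 9x9 spore plates.
#'
#' @param seed Integer root seed for all generator substreams.
#' @param locus_names Character vector of the four locus names, in bit order.
#' @param true_rates Named numeric vector of growth rates (per hour), one per
#'   genotype bit-string over `locus_names` (bit 1 = deleted). Defaults to the
#'   rates of [fixture_landscape()].
#' @param noise_cv Coefficient of variation of the multiplicative log-normal
#'   noise on simulated cell counts. Must be >= 0.
#' @param size_params Named list of populations, each `list(mu=, sigma=)` on
#'   the log scale for the log-normal size distribution.
#' @param sweep_times Named list mapping locus name to
#'   `list(midpoint=, steepness=)` of its logistic allele-frequency sweep
#'   (generations; steepness per generation).
#' @param sweep_background Additive background noise level on Sanger peak
#'   heights, as a fraction of the trace gain.
#' @param grid_plates,grid_dim Number of spore plates and grid dimension per
#'   plate (the cross deposits `grid_dim^2` spores per plate).
#' @param genome_length Toy genome length in bp.
#' @param cds_intervals Tibble (or data frame) with columns `start`, `end`,
#'   `strand`, `gene`: 1-based inclusive CDS coordinates on the toy genome.
#'   Must be non-overlapping, within the genome, and each at least 3 bp.
#' @param spore_survival Named numeric vector of per-genotype colony-formation
#'   probabilities. Defaults scale with genotype fitness.
#' @param polarity Named list of per-genotype polarity-trace parameters, each
#'   `list(p_polarize=, mean_tfsc=, mean_polarized=, spot_probs=)`:
#'   polarization probability within the observation window, mean
#'   cytokinesis-to-first-spot time (min), mean first-spot-to-bud time (min),
#'   and the per-frame probabilities of observing 0..3 polarity spots after
#'   the first spot has appeared.
#' @return An object of class `synth_config` (a validated named list).
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' cfg$true_rates[["0000"]] / cfg$true_rates[["1000"]] # ~12-fold
synth_config <- function(seed = 1L,
                         locus_names = c("BEM1", "BEM2", "BEM3", "NRP1"),
                         true_rates = NULL,
                         noise_cv = 0.05,
                         size_params = list(
                           wild_type = list(mu = log(40), sigma = 0.25),
                           bem1_early = list(mu = log(120), sigma = 0.60),
                           bem1_evolved = list(mu = log(45), sigma = 0.30)
                         ),
                         sweep_times = list(
                           BEM3 = list(midpoint = 150, steepness = 0.040),
                           NRP1 = list(midpoint = 450, steepness = 0.030),
                           BEM2 = list(midpoint = 650, steepness = 0.030)
                         ),
                         sweep_background = 0.05,
                         grid_plates = 10L,
                         grid_dim = 9L,
                         genome_length = 20000L,
                         cds_intervals = default_cds_intervals(),
                         spore_survival = NULL,
                         polarity = default_polarity_params()) {
  stopifnot(length(locus_names) == 4L, is.character(locus_names))
  if (is.null(true_rates)) {
    fl <- fixture_landscape(locus_names)
    true_rates <- setNames(fl$rate, fl$genotype)
  }
  if (noise_cv < 0) abort("noise_cv must be >= 0")
  for (p in size_params) {
    if (p$sigma <= 0) abort("size_sigma must be > 0")
  }
  cds <- as_tibble(cds_intervals)
  stopifnot(all(c("start", "end", "strand", "gene") %in% names(cds)))
  if (any(cds$end > genome_length) || any(cds$start < 1)) {
    abort("cds_intervals must lie within the genome")
  }
  if (any(cds$end - cds$start + 1 < 3)) abort("each CDS must be at least 3 bp")
  o <- order(cds$start)
  if (any(cds$start[o][-1] <= cds$end[o][-nrow(cds)])) {
    abort("cds_intervals must be non-overlapping")
  }
  if (is.null(spore_survival)) {
    # colony-formation probability tied to genotype fitness: the slowest
    # genotypes are least likely to form visible colonies
    w <- true_rates
    spore_survival <- setNames(pmin(0.97 * sqrt(w / max(w)), 0.97), names(w))
  }
  structure(
    list(
      seed = as.integer(seed),
      locus_names = locus_names,
      true_rates = true_rates,
      noise_cv = noise_cv,
      size_params = size_params,
      sweep_times = sweep_times,
      sweep_background = sweep_background,
      grid_plates = as.integer(grid_plates),
      grid_dim = as.integer(grid_dim),
      genome_length = as.integer(genome_length),
      cds_intervals = cds,
      spore_survival = spore_survival,
      polarity = polarity
    ),
    class = "synth_config"
  )
}

#' @export
print.synth_config <- function(x, ...) {
  cat("<synth_config> seed", x$seed, "| loci:", paste(x$locus_names, collapse = ", "), "\n")
  cat("  genotypes with true rates:", length(x$true_rates),
      "| noise_cv:", x$noise_cv, "\n")
  cat("  toy genome:", x$genome_length, "bp,", nrow(x$cds_intervals), "CDSs |",
      x$grid_plates, "plates of", x$grid_dim, "x", x$grid_dim, "spores\n")
  invisible(x)
}

# Toy genome annotation: three genes named for the recurrently mutated loci
# plus one extra minus-strand gene so strand-aware classification is exercised.
default_cds_intervals <- function() {
  tibble(
    start = c(1001L, 5001L, 13001L),
    end = c(2200L, 5900L, 13900L),
    strand = c("+", "+", "+"),
    gene = c("BEM3", "NRP1", "SYN1")
  ) |>
    bind_rows(tibble(start = 9001L, end = 9900L, strand = "-", gene = "BEM2")) |>
    arrange(.data$start)
}

# Per-genotype polarity-trace parameters. Wild-type-like cells polarize
# quickly and hold a single spot; bem1-deleted cells mostly fail to polarize
# within the window, wait long before the first spot and often show zero or
# multiple competing spots.
default_polarity_params <- function() {
  list(
    wild_type = list(
      p_polarize = 1.0, mean_tfsc = 30, mean_polarized = 20,
      spot_probs = c(`0` = 0.05, `1` = 0.90, `2` = 0.05, `3` = 0.00)
    ),
    bem1 = list(
      p_polarize = 0.20, mean_tfsc = 180, mean_polarized = 120,
      spot_probs = c(`0` = 0.45, `1` = 0.30, `2` = 0.17, `3` = 0.08)
    ),
    bem1_bem3 = list(
      p_polarize = 0.90, mean_tfsc = 60, mean_polarized = 60,
      spot_probs = c(`0` = 0.20, `1` = 0.50, `2` = 0.22, `3` = 0.08)
    ),
    bem1_bem3_nrp1 = list(
      p_polarize = 0.95, mean_tfsc = 35, mean_polarized = 45,
      spot_probs = c(`0` = 0.15, `1` = 0.60, `2` = 0.20, `3` = 0.05)
    ),
    bem1_bem3_nrp1_bem2 = list(
      p_polarize = 1.0, mean_tfsc = 32, mean_polarized = 30,
      spot_probs = c(`0` = 0.08, `1` = 0.75, `2` = 0.13, `3` = 0.04)
    )
  )
}
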