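# Generators for growth curves, size samples and Sanger sweep series.
# Each generator is deterministic in (config$seed, its substream name) and
# carries its ground truth alongside the data (columns or attributes), so
# downstream estimators can always be validated against what was planted.

#' Generate a Coulter-style count-time series for one genotype
#'
#' Emulates log-phase growth measurements: counts follow
#' `N0 * exp(r * t)` with multiplicative log-normal noise of coefficient of
#' variation `config$noise_cv`, where `r` is the configured true growth rate
#' of `genotype`.
#'
#' @param config A [synth_config()].
#' @param genotype Genotype bit-string; must be a name of `config$true_rates`.
#' @param n_points Number of time points (>= 3).
#' @param dt Sampling interval in hours (> 0).
#' @param n0 Expected count at time zero.
#' @param replicate Replicate index; distinct replicates use distinct
#'   random substreams.
#' @return A tibble with columns `time_h` and `count`, plus a `truth`
#'   attribute `list(rate, n0)`.
#' @export
#' @examples
#' gen_growth_series(synth_config(seed = 1), "0000", n_points = 12, dt = 0.5)
gen_growth_series <- function(config, genotype, n_points = 12L, dt = 0.5,
                              n0 = 1000, replicate = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (n_points < 3) abort("n_points must be >= 3")
  if (dt <= 0) abort("dt must be > 0")
  if (!genotype %in% names(config$true_rates)) {
    abort(paste0("unknown genotype '", genotype, "': not in config$true_rates"))
  }
  r <- config$true_rates[[genotype]]
  t <- seq(0, by = dt, length.out = n_points)
  mean_counts <- n0 * exp(r * t)
  cv <- config$noise_cv
  eps <- if (cv > 0) {
    sdlog <- sqrt(log(1 + cv^2))
    with_seed(
      substream_seed(config$seed, paste0("growth:", genotype, ":", replicate)),
      rlnorm(n_points, meanlog = -sdlog^2 / 2, sdlog = sdlog) # mean 1
    )
  } else {
    rep(1, n_points)
  }
  out <- tibble(time_h = t, count = mean_counts * eps)
  attr(out, "truth") <- list(rate = r, n0 = n0)
  out
}

#' Generate log-normal cell-size samples for one population
#'
#' Emulates a Coulter-counter size distribution: `n` i.i.d. draws from a
#' log-normal with the configured log-scale location and shape of
#' `population`.
#'
#' @param config A [synth_config()].
#' @param population Name of an entry of `config$size_params`.
#' @param n Number of particles to draw (>= 1).
#' @param replicate Replicate index (independent substream).
#' @return A numeric vector of positive sizes (arbitrary units), with a
#'   `truth` attribute `list(mu, sigma, mode)`.
#' @export
gen_size_samples <- function(config, population, n = 100000L, replicate = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (n <= 0) abort("n must be >= 1")
  p <- config$size_params[[population]]
  if (is.null(p)) abort(paste0("unknown population '", population, "'"))
  x <- with_seed(
    substream_seed(config$seed, paste0("size:", population, ":", replicate)),
    rlnorm(n, meanlog = p$mu, sdlog = p$sigma)
  )
  attr(x, "truth") <- list(mu = p$mu, sigma = p$sigma,
                           mode = exp(p$mu - p$sigma^2))
  x
}

# Logistic sweep curve in generations; handles infinite steepness as a step
# (value 0.5 exactly at the midpoint).
logistic_sweep <- function(t, midpoint, steepness) {
  x <- steepness * (t - midpoint)
  x[t == midpoint] <- 0
  stats::plogis(x)
}

#' Generate a Sanger peak-height time course for one sweeping locus
#'
#' The true mutant-allele fraction follows a logistic sweep with the
#' configured midpoint and steepness for `locus`. Each timepoint is read out
#' as a pair of peak heights `(f, 1 - f)` scaled by a random per-trace gain
#' (uniform in `[0.5, 2]`; only the height ratio carries information) plus
#' additive background noise at fraction `config$sweep_background` of the
#' gain, so that fully swept or unswept traces still show small spurious
#' peaks, as real chromatograms do.
#'
#' @param config A [synth_config()].
#' @param locus Name of an entry of `config$sweep_times`.
#' @param generations Sorted ascending vector of generation numbers.
#' @param replicate Replicate index (independent substream).
#' @return A tibble with columns `locus`, `generation`, `h_mut`, `h_anc`,
#'   and the planted `true_f`.
#' @export
gen_sweep_series <- function(config, locus, generations, replicate = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (is.unsorted(generations, strictly = FALSE)) {
    abort("generations must be sorted ascending")
  }
  sw <- config$sweep_times[[locus]]
  if (is.null(sw)) abort(paste0("unknown locus '", locus, "'"))
  f <- logistic_sweep(generations, sw$midpoint, sw$steepness)
  bg <- config$sweep_background
  with_seed(
    substream_seed(config$seed, paste0("sweep:", locus, ":", replicate)),
    {
      gain <- runif(length(f), 0.5, 2)
      tibble(
        locus = locus,
        generation = generations,
        h_mut = gain * (f + bg * runif(length(f))),
        h_anc = gain * ((1 - f) + bg * runif(length(f))),
        true_f = f
      )
    }
  )
}

#' Generate a spore grid from the four-locus heterozygous-diploid cross
#'
#' Emulates spotting single spores from a quadruply heterozygous diploid on
#' plates: each of `grid_plates * grid_dim^2` positions receives a spore
#' whose genotype is drawn uniformly from the 16 locus combinations (ideal
#' 1:1 Mendelian segregation, loci unlinked), survival is Bernoulli with the
#' per-genotype colony-formation probability, and surviving colonies get a
#' radius drawn around a genotype-specific mean that scales with growth
#' rate.
#'
#' @param config A [synth_config()].
#' @param replicate Replicate index (independent substream).
#' @return A tibble with columns `plate`, `row`, `col`, `genotype`,
#'   `survived`, `radius` (mm; NA for positions without a colony).
#' @export
gen_spore_grid <- function(config, replicate = 1L) {
  stopifnot(inherits(config, "synth_config"))
  gts <- all_genotypes(length(config$locus_names))
  n <- config$grid_plates * config$grid_dim^2
  surv_p <- config$spore_survival[gts]
  mean_radius <- 0.3 + 3.4 * config$true_rates[gts] # mm; ~2 mm for wild type
  with_seed(
    substream_seed(config$seed, paste0("spores:", replicate)),
    {
      g <- sample(gts, n, replace = TRUE)
      survived <- runif(n) < surv_p[g]
      radius <- ifelse(
        survived,
        pmax(0.05, rnorm(n, mean_radius[g], 0.1 * mean_radius[g])),
        NA_real_
      )
      tibble(
        plate = rep(seq_len(config$grid_plates), each = config$grid_dim^2),
        row = rep(rep(seq_len(config$grid_dim), each = config$grid_dim),
                  times = config$grid_plates),
        col = rep(seq_len(config$grid_dim),
                  times = config$grid_plates * config$grid_dim),
        genotype = g,
        survived = survived,
        radius = radius
      )
    }
  )
}

#' Generate per-cell polarity-spot traces for one strain
#'
#' Emulates manual scoring of polarity-marker movies: for each mother cell a
#' cytokinesis frame, an optional first-polarity-spot frame and bud frame,
#' and per-frame spot counts in 0..3 between first spot and budding. Cells
#' fail to polarize within the observation window with probability
#' `1 - p_polarize` for their strain; such cells are censored (no first-spot
#' or bud frame).
#'
#' @param config A [synth_config()].
#' @param strain Name of an entry of `config$polarity`
#'   (e.g. `"wild_type"`, `"bem1"`).
#' @param n_cells Number of mother cells (0 gives an empty table).
#' @param frame_interval Minutes between frames; must be 2 or 3 as in the
#'   imaging protocol.
#' @param replicate Replicate index (independent substream).
#' @return A tibble with one row per cell: `cell_id`, `frame_interval`,
#'   `cytokinesis_frame`, `first_spot_frame`, `bud_frame` (NA when
#'   censored), and `spot_counts` (list-column of integer counts for frames
#'   `first_spot_frame .. bud_frame - 1`). Carries a `truth` attribute with
#'   the strain parameters.
#' @export
gen_polarity_traces <- function(config, strain, n_cells,
                                frame_interval = 2, replicate = 1L) {
  stopifnot(inherits(config, "synth_config"))
  if (!frame_interval %in% c(2, 3)) abort("frame_interval must be 2 or 3 minutes")
  p <- config$polarity[[strain]]
  if (is.null(p)) abort(paste0("unknown strain '", strain, "'"))
  if (n_cells == 0) {
    out <- tibble(
      cell_id = character(), frame_interval = numeric(),
      cytokinesis_frame = integer(), first_spot_frame = integer(),
      bud_frame = integer(), spot_counts = list()
    )
    attr(out, "truth") <- p
    return(out)
  }
  with_seed(
    substream_seed(config$seed, paste0("polarity:", strain, ":", replicate)),
    {
      rows <- map(seq_len(n_cells), function(i) {
        cyto <- sample.int(5L, 1L)
        if (runif(1) >= p$p_polarize) {
          return(tibble(
            cell_id = sprintf("%s_c%03d", strain, i),
            frame_interval = frame_interval,
            cytokinesis_frame = cyto,
            first_spot_frame = NA_integer_, bud_frame = NA_integer_,
            spot_counts = list(integer())
          ))
        }
        # delay of >= 1 frame; mean delay = mean_tfsc / frame_interval frames
        delay <- 1L + rpois(1, max(0, p$mean_tfsc / frame_interval - 1))
        fs <- cyto + delay
        dur <- 1L + rpois(1, max(0, p$mean_polarized / frame_interval - 1))
        bud <- fs + dur
        counts <- sample(0:3, dur, replace = TRUE, prob = p$spot_probs)
        counts[1] <- max(1L, counts[1]) # the first-spot frame has a spot
        tibble(
          cell_id = sprintf("%s_c%03d", strain, i),
          frame_interval = frame_interval,
          cytokinesis_frame = cyto,
          first_spot_frame = as.integer(fs), bud_frame = as.integer(bud),
          spot_counts = list(as.integer(counts))
        )
      })
      out <- list_rbind(rows)
      attr(out, "truth") <- p
      out
    }
  )
}
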