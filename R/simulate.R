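# Serial-dilution evolution simulator on a genotype fitness landscape.
# Growth within a passage is deterministic exponential per genotype (the
# population never drops below ~5e5 cells in the protocol, so growth noise
# is negligible); stochasticity enters only through loss-of-function
# mutation (Poisson per division) and the dilution bottleneck (multinomial).

#' Generations of growth per serial-dilution passage
#'
#' A D-fold dilution regrows D-fold before the next passage, i.e.
#' `log2(D)` doublings; the protocol's 1000-fold dilution gives 10
#' generations per passage (100 passages = 1000 generations).
#'
#' @param dilution Fold-dilution per passage (> 1).
#' @return Integer number of doublings per passage, `round(log2(dilution))`.
#' @export
#' @examples
#' doublings_per_passage(1000) # 10
doublings_per_passage <- function(dilution) {
  if (dilution <= 1) abort("dilution must be > 1")
  as.integer(round(log2(dilution)))
}

#' Parameters for the serial-dilution evolution simulator
#'
#' Defaults follow the evolution protocol: 10 ul of saturated culture into
#' 10 ml fresh medium (1000-fold dilution), passaged once the density
#' reaches 5e7 cells/ml, 100 passages (1000 generations). Mutation supply is
#' a per-gene loss-of-function rate times a relative target size; by
#' default the target sizes of BEM3, NRP1 and BEM2 are proportional to the
#' observed recurrence counts (10:5:3) and BEM1 is excluded from the move
#' set (its gene is absent from the genome, so it can never revert).
#'
#' @param landscape A [fitness_landscape()] supplying per-genotype growth
#'   rates (per hour).
#' @param mu_lof Loss-of-function mutation rate per gene (unit target size)
#'   per cell division.
#' @param target_size Named numeric vector of relative mutational target
#'   sizes per locus; loci with target 0 never mutate.
#' @param n0 Cells founding each passage.
#' @param density_threshold Cells/ml at which a culture is passaged.
#' @param volume_ml Culture volume (ml).
#' @param dilution Fold-dilution per passage (> 1).
#' @param n_passages Number of passages to simulate.
#' @param start_genotype Founding genotype bit-string (default the
#'   bem1-deleted ancestor).
#' @param fixation_threshold Allele frequency above which a locus counts as
#'   fixed.
#' @param mode `"stochastic"` (Poisson mutation + multinomial bottleneck) or
#'   `"expectation"` (both replaced by their expectations; fully
#'   deterministic).
#' @param seed Integer seed for the stochastic mode.
#' @return A validated `sim_params` list.
#' @export
sim_params <- function(landscape,
                       mu_lof = 1e-7,
                       target_size = c(BEM1 = 0, BEM2 = 3, BEM3 = 10, NRP1 = 5),
                       n0 = 5e5,
                       density_threshold = 5e7,
                       volume_ml = 10,
                       dilution = 1000,
                       n_passages = 100L,
                       start_genotype = "1000",
                       fixation_threshold = 0.95,
                       mode = c("stochastic", "expectation"),
                       seed = 1L) {
  mode <- match.arg(mode)
  stopifnot(inherits(landscape, "fitness_landscape"))
  if (dilution <= 1) abort("dilution must be > 1")
  if (n0 < 1) abort("n0 must be >= 1")
  if (mu_lof < 0 || any(target_size < 0)) abort("mutation rates must be >= 0")
  loci <- landscape_loci(landscape)
  if (!all(loci %in% names(target_size))) {
    abort("target_size must name every landscape locus")
  }
  if (!start_genotype %in% landscape$genotype) {
    abort("start_genotype is not in the landscape")
  }
  structure(
    list(landscape = landscape, mu_lof = mu_lof,
         target_size = target_size[loci], n0 = n0,
         density_threshold = density_threshold, volume_ml = volume_ml,
         dilution = dilution, n_passages = as.integer(n_passages),
         start_genotype = start_genotype,
         fixation_threshold = fixation_threshold,
         mode = mode, seed = as.integer(seed)),
    class = "sim_params"
  )
}

# Time for the mixed population to grow from `counts` to total `n_final`,
# each genotype growing exponentially at its own rate. Newton-refined to
# machine precision so expectation-mode trajectories match closed forms.
growth_time <- function(counts, rates, n_final) {
  live <- counts > 0
  if (sum(counts) <= 0) abort("zero total cells: population lost")
  wmax <- max(rates[live])
  if (wmax <= 0) abort("no growing genotype present: culture never reaches threshold")
  f <- function(T) sum(counts[live] * exp(rates[live] * T)) - n_final
  hi <- log(n_final / sum(counts)) / wmax
  while (f(hi) < 0) hi <- hi * 2
  T <- uniroot(f, c(0, hi), tol = 1e-10)$root
  for (i in 1:4) { # Newton polish
    fp <- sum(counts[live] * rates[live] * exp(rates[live] * T))
    T <- T - f(T) / fp
  }
  T
}

#' Simulate one serial-dilution passage
#'
#' Grows each genotype exponentially at its landscape rate until the total
#' reaches `density_threshold * volume_ml` cells, introduces
#' loss-of-function mutations (0 -> 1 bit flips only) as Poisson draws with
#' mean `mu_lof * target_size * divisions` per gene, then bottlenecks the
#' culture to `n0` cells by multinomial sampling. In `"expectation"` mode
#' the Poisson and multinomial draws are replaced by their expectations.
#'
#' @param counts Named numeric vector of cell counts per genotype (names =
#'   genotype bit-strings of the landscape).
#' @param params A [sim_params()].
#' @return A list: `counts` (post-bottleneck), `counts_grown` (at the
#'   passage's end density, used for frequency records), `time_h` (hours of
#'   growth), `new_alleles` (loci whose mutant-allele count rose from zero
#'   this passage).
#' @export
simulate_passage <- function(counts, params) {
  lsc <- params$landscape
  loci <- landscape_loci(lsc)
  gts <- lsc$genotype
  rates <- setNames(lsc$rate, gts)
  if (any(counts < 0) || sum(counts) <= 0) abort("invalid state: zero total cells")
  n_final <- params$density_threshold * params$volume_ml
  T <- growth_time(counts[gts], rates[gts], n_final)
  grown <- counts[gts] * exp(rates[gts] * T)

  allele_before <- allele_counts(grown, loci)
  mu <- params$mu_lof * params$target_size
  if (any(mu > 0)) {
    for (g in gts[grown > 0]) {
      divisions <- max(grown[[g]] - counts[[g]], 0)
      bits <- genotype_bits(g)
      for (j in which(bits == 0 & mu > 0)) {
        lambda <- mu[[j]] * divisions
        m <- if (params$mode == "stochastic") rpois(1, lambda) else lambda
        m <- min(m, grown[[g]])
        if (m > 0) {
          tgt <- bits_genotype(replace(bits, j, 1L))
          if (!tgt %in% gts) next # genotype outside the declared landscape
          grown[[g]] <- grown[[g]] - m
          grown[[tgt]] <- grown[[tgt]] + m
        }
      }
    }
  }
  allele_after <- allele_counts(grown, loci)
  new_alleles <- loci[allele_before == 0 & allele_after > 0]

  freq <- grown / sum(grown)
  next_counts <- if (params$mode == "stochastic") {
    setNames(as.numeric(rmultinom(1, size = params$n0, prob = freq)), gts)
  } else {
    params$n0 * freq
  }
  list(counts = next_counts, counts_grown = grown, time_h = T,
       new_alleles = new_alleles)
}

# Mutant-allele count per locus given per-genotype counts.
allele_counts <- function(counts, loci) {
  bits <- do.call(rbind, lapply(names(counts), genotype_bits))
  setNames(as.numeric(crossprod(bits, counts)), loci)
}

#' Run the serial-dilution evolution simulation
#'
#' Starts `n0` cells of the founding genotype and simulates `n_passages`
#' passages, recording per-genotype and per-locus (mutant-allele) frequency
#' trajectories at the end density of each passage, the passage at which
#' each locus's allele first appeared and first exceeded the fixation
#' threshold, and the total number of generations
#' (`n_passages * doublings_per_passage(dilution)`).
#'
#' @param params A [sim_params()].
#' @return An `evolution_sim` object: a list with `trajectories` (tibble:
#'   `passage`, `genotype`, `frequency`), `allele_freq` (tibble: `passage`,
#'   `locus`, `frequency`), `appearance` and `fixation` (named vectors of
#'   passage times, NA when the event never happened), `fixation_order`
#'   (character vector of loci in fixation order), `generations`, `time_h`,
#'   and the `params`.
#' @export
#' @examples
#' p <- sim_params(fixture_landscape(), n_passages = 20, seed = 1)
#' sim <- simulate_evolution(p)
#' sim$fixation_order
simulate_evolution <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  lsc <- params$landscape
  loci <- landscape_loci(lsc)
  gts <- lsc$genotype
  run <- function() {
    counts <- setNames(numeric(length(gts)), gts)
    counts[params$start_genotype] <- params$n0
    appearance <- setNames(rep(NA_real_, length(loci)), loci)
    fixation <- setNames(rep(NA_real_, length(loci)), loci)
    start_bits <- genotype_bits(params$start_genotype)
    appearance[start_bits == 1] <- 0
    fixation[start_bits == 1] <- 0
    total_h <- 0
    freq_rec <- matrix(NA_real_, nrow = params$n_passages, ncol = length(gts),
                       dimnames = list(NULL, gts))
    af_rec <- matrix(NA_real_, nrow = params$n_passages, ncol = length(loci),
                     dimnames = list(NULL, loci))
    for (p in seq_len(params$n_passages)) {
      st <- simulate_passage(counts, params)
      counts <- st$counts
      total_h <- total_h + st$time_h
      freq <- st$counts_grown / sum(st$counts_grown)
      freq_rec[p, ] <- freq
      af <- allele_counts(st$counts_grown, loci) / sum(st$counts_grown)
      af_rec[p, ] <- af
      for (l in st$new_alleles) {
        if (is.na(appearance[[l]])) {
          # mutations arise at exchangeable random times within the passage
          appearance[[l]] <- p - if (params$mode == "stochastic") runif(1) else 0
        }
      }
      newly_fixed <- loci[is.na(fixation) & af > params$fixation_threshold]
      fixation[newly_fixed] <- p
    }
    list(freq_rec = freq_rec, af_rec = af_rec, appearance = appearance,
         fixation = fixation, total_h = total_h)
  }
  res <- if (params$mode == "stochastic") with_seed(params$seed, run()) else run()

  trajectories <- as_tibble(res$freq_rec) |>
    mutate(passage = seq_len(params$n_passages)) |>
    tidyr::pivot_longer(-"passage", names_to = "genotype",
                        values_to = "frequency")
  allele_freq <- as_tibble(res$af_rec) |>
    mutate(passage = seq_len(params$n_passages)) |>
    tidyr::pivot_longer(-"passage", names_to = "locus",
                        values_to = "frequency")
  fixed <- res$fixation[!is.na(res$fixation) & res$fixation > 0]
  # ties (same passage) broken by allele frequency at crossing, then name
  fixation_order <- names(fixed)[order(fixed, names(fixed))]
  structure(
    list(trajectories = trajectories, allele_freq = allele_freq,
         appearance = res$appearance, fixation = res$fixation,
         fixation_order = fixation_order,
         generations = params$n_passages * doublings_per_passage(params$dilution),
         time_h = res$total_h, params = params),
    class = "evolution_sim"
  )
}

#' @export
print.evolution_sim <- function(x, ...) {
  cat("<evolution_sim>", x$params$n_passages, "passages,",
      x$generations, "generations,", sprintf("%.1f h elapsed\n", x$time_h))
  cat("  fixation order:",
      if (length(x$fixation_order)) paste(x$fixation_order, collapse = " -> ")
      else "(none fixed)", "\n")
  invisible(x)
}

#' Mutational order realized in one simulation
#'
#' @param sim An `evolution_sim` result.
#' @param loci Loci to order (default: all that mutated during the run).
#' @param mode `"fixation"` orders loci by the passage their allele
#'   frequency first exceeded the fixation threshold; `"appearance"` by the
#'   time their allele first arose.
#' @return A single string such as `"BEM3>NRP1>BEM2"`, or `NA` if any
#'   requested locus never reached the event.
#' @export
locus_order <- function(sim, loci = NULL, mode = c("fixation", "appearance")) {
  mode <- match.arg(mode)
  times <- if (mode == "fixation") sim$fixation else sim$appearance
  times <- times[!names(times) %in% deleted_at_start(sim)]
  if (!is.null(loci)) times <- times[loci]
  if (anyNA(times)) return(NA_character_)
  paste(names(times)[order(times, names(times))], collapse = ">")
}

deleted_at_start <- function(sim) {
  loci <- landscape_loci(sim$params$landscape)
  loci[genotype_bits(sim$params$start_genotype) == 1]
}

#' Distribution of mutational orders over replicate simulations
#'
#' Empirical frequency of each realized order with a Wilson score
#' confidence interval.
#'
#' @param orders Character vector of order strings (e.g. from
#'   [locus_order()]); `NA` entries (incomplete runs) are dropped and
#'   reported in the `n_incomplete` attribute.
#' @param conf Confidence level for the Wilson interval.
#' @return A tibble with `order`, `n`, `frequency`, `conf_low`,
#'   `conf_high`, sorted by frequency descending.
#' @export
#' @examples
#' order_statistics(c("A>B", "A>B", "B>A"))
order_statistics <- function(orders, conf = 0.95) {
  if (length(orders) == 0) abort("at least one result is required")
  n_na <- sum(is.na(orders))
  orders <- orders[!is.na(orders)]
  n <- length(orders)
  z <- qnorm(1 - (1 - conf) / 2)
  out <- tibble(order = orders) |>
    count(.data$order, name = "n_order") |>
    mutate(
      frequency = .data$n_order / n,
      denom = 1 + z^2 / n,
      center = (.data$frequency + z^2 / (2 * n)) / .data$denom,
      half = z * sqrt(.data$frequency * (1 - .data$frequency) / n +
                        z^2 / (4 * n^2)) / .data$denom,
      conf_low = .data$center - .data$half,
      conf_high = .data$center + .data$half
    ) |>
    select(order = "order", n = "n_order", "frequency",
           "conf_low", "conf_high") |>
    arrange(dplyr::desc(.data$frequency), .data$order)
  attr(out, "n_incomplete") <- n_na
  out
}
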