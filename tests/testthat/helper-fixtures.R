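# Shared fixtures, built in code at test time.

test_config <- function(seed = 1L, ...) synth_config(seed = seed, ...)

# Flat (neutral) landscape with symmetric targets for the three mutable loci.
neutral_landscape <- function(rate = 0.3) {
  fitness_landscape(
    tibble::tibble(genotype = all_genotypes(4), rate = rate, se = 0)
  )
}

neutral_targets <- c(BEM1 = 0, BEM2 = 1, BEM3 = 1, NRP1 = 1)

# Noiseless exponential series.
exact_series <- function(r, n0 = 1000, t = 0:5) {
  tibble::tibble(time_h = t, count = n0 * exp(r * t))
}
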