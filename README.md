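# bemadapt

Quantitative analysis of experimental evolution in budding yeast lineages
recovering from deletion of the polarity scaffold gene *BEM1*.

`bem1∆` cells polarize so poorly that they barely proliferate, yet evolving
populations recover most of their ancestors' fitness within 1000 generations
of serial dilution — and they do so along a reproducible trajectory:
loss-of-function mutations in *BEM3*, then *NRP1*, then *BEM2*, in that
order, in independent lines. This package implements the analyses that
establish and explain that trajectory, plus a seeded synthetic-data module
that generates every input the pipeline consumes, with ground truth stored
alongside, so every estimator can be validated end to end.

## What the package computes

**Phenotypes.** Log-phase growth rates by least-squares regression of
ln(count) on time (`fit_growth_rate()`, with an `nls` cross-check), relative
fitness with delta-method errors (`relative_fitness()`), and cell-size
distributions by a log-normal fit (`fit_lognormal()`) reported as the mode
`exp(μ − σ²)` — the dominant cell size — and the linear-scale SD.

**Mutation identification.** `ancestor_delta()` keeps the variants present
in an evolved strain but absent from its ancestor; `classify_variants()`
applies the labeling rule — a variant is a candidate mutation if it causes a
non-synonymous substitution in a CDS (nonsense/missense, e.g. `Q61*`) or
falls within 500 bp upstream of a CDS start (promoter), strand-aware;
synonymous and far-intergenic changes are rejected. `recurrence()` counts,
per gene, the number of independent lines hit.

**Sweep dynamics.** `allele_fraction()` turns Sanger peak heights into
mutant-allele fractions, `h_mut / (h_mut + h_anc)`, clamped to 0 below the
background level and to 1 above 95%; `infer_order()` orders loci by sweep
onset with consistent-difference tie-breaking.

**Spore genetics.** `survival_summary()` computes per-genotype colony
survival `100·n_obs/n_exp` with its statistical error `pct/√N`, and
`colony_count_frequency()` the plating frequency with a binomial SE.

**The fitness hypercube.** A `fitness_landscape` maps each of the 2⁴
genotypes over {*BEM1*, *BEM2*, *BEM3*, *NRP1*} (bit 1 = deleted) to a
growth rate. `enumerate_paths()` lists all k! mutational orderings between
two genotypes; `accessible_paths()` keeps those along which every step
increases fitness (fixed margin or one-sided z on replicate SEs);
`epistasis_class()` labels pairwise interactions (none / magnitude / sign /
reciprocal sign); `bem1_dependence()` quantifies how the benefit of *BEM1*
flips sign as the other deletions accumulate.

**Evolution simulator.** `simulate_evolution()` reproduces the
serial-dilution protocol on a landscape: deterministic exponential growth to
5·10⁷ cells/ml in 10 ml, Poisson loss-of-function mutation per division
(relative target sizes per gene), a 1000-fold multinomial bottleneck
(≈ 10 generations per passage), and records allele-frequency trajectories
and fixation orders; `order_statistics()` summarizes orders over replicates
with Wilson intervals.

**Polarity dynamics.** `summarize_trace()`/`summarize_cohort()` compute the
cytokinesis-to-first-spot latency t_fs−c and the per-cycle time with 0–3
polarity spots; `polarization_probability()` the fraction of cells
polarizing within an observation window.

`run_pipeline()` chains all stages on synthetic inputs and emits a report
plus a manifest with reproducible digests.

## Worked example

```r
library(bemadapt)

cfg <- synth_config(seed = 1)            # the study conditions, seeded
wt  <- fit_growth_rate(gen_growth_series(cfg, "0000"))  # wild type
anc <- fit_growth_rate(gen_growth_series(cfg, "1000"))  # bem1∆ ancestor
wt
#> <growth_fit> rate 0.5062/h (SE 0.0072), doubling time 1.37 h, n = 12, R^2 = 0.9980
anc
#> <growth_fit> rate 0.0551/h (SE 0.0091), doubling time 12.57 h, n = 12, R^2 = 0.7872
relative_fitness(wt, anc)
#> # A tibble: 1 × 4
#>   ratio    se rate_a rate_b
#>   <dbl> <dbl>  <dbl>  <dbl>
#> 1  9.18  1.51  0.506 0.0551
```

One 12-point curve per strain recovers the planted ~12-fold fitness gap
only roughly (9.2 ± 1.5 here) because the slow strain grows just 26% over
the sampled 5.5 h; averaging replicate fits tightens this (see the
acceptance script below).

```r
accessible_paths(fixture_landscape(), "1000", "1111")[, c("order", "min_step_gain")]
#> # A tibble: 2 × 2
#>   order          min_step_gain
#>   <chr>                  <dbl>
#> 1 BEM3>NRP1>BEM2         0.13
#> 2 NRP1>BEM3>BEM2         0.038
```

Of the six possible orderings of the three deletions, only the two that add
*bem2∆* last are selectively accessible on the sign-epistatic landscape —
deleting *BEM2* only helps once *BEM3* and *NRP1* are already gone. The
simulator, which also sees the 10:5:3 mutational target sizes, picks the
observed order:

```r
simulate_evolution(sim_params(fixture_landscape(), seed = 1))
#> <evolution_sim> 100 passages, 1000 generations, 1840.0 h elapsed
#>   fixation order: BEM3 -> NRP1 -> BEM2
```

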