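---
title: "Methods: models, estimators and design choices in bemadapt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, estimators and design choices in bemadapt}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bemadapt)
```

# The system

Budding yeast polarizes by concentrating active Cdc42 at a single cortical
site. Bem1 is the scaffold that couples the GEF Cdc24 to Cdc42, and
`bem1∆` cells polarize so inefficiently that freshly germinated spores
rarely form colonies. Evolving `bem1∆` populations by serial dilution
nevertheless recovers near-ancestral growth within ~1000 generations, and
the recovery is channelled through a fixed sequence of loss-of-function
mutations — first in the Cdc42 GAP gene *BEM3*, then *NRP1*, then the GAP
gene *BEM2* — because of sign epistasis among the four loci. This package
implements the quantitative analyses of that system: phenotype estimation,
mutation identification and recurrence, allele-frequency time courses,
fitness-hypercube analysis, a protocol-faithful evolution simulator, and
polarity-dynamics summaries, together with a synthetic-data module that
generates every input with known ground truth.

Throughout, a genotype is a bit-string over the ordered loci
(*BEM1*, *BEM2*, *BEM3*, *NRP1*), bit 1 meaning deleted; `"1000"` is the
`bem1∆` founder and `"1111"` the quadruple mutant.

# Synthetic data: what is emulated, and what is not

Raw measurements (Coulter counts, chromatograms, plate images, movies) are
not desk-reproducible, so the package generates statistically equivalent
inputs from a seeded configuration, `synth_config()`. Every generator
derives its own random substream from the root seed via a stage name
(`substream_seed()`), so identical configurations give identical output and
regenerating one stage never perturbs another. Ground truth (planted rates,
fractions, labels) is stored alongside the data; the module's core property
— enforced by the test suite — is that each downstream estimator recovers
its planted truth within stated statistical tolerance.

* **Growth curves** follow `N0·exp(r·t)` with multiplicative log-normal
  noise of coefficient of variation `noise_cv`. The noise draw has mean 1
  (`meanlog = −sdlog²/2`), so counts are unbiased. Default CV is 5%: no
  noise magnitudes are reported for the original counters, and 5% is a
  realistic figure for repeated particle counts; it is a configuration
  default, not a claim about the instrument.
* **Cell sizes** are i.i.d. log-normal draws per population. Size units are
  arbitrary positive units; whether a Coulter "size" is a diameter or a
  volume is immaterial to the estimator, which is scale-equivariant.
* **Selective sweeps** are logistic in generations,
  `f(t) = 1/(1 + e^{−s(t − m)})`, the canonical single-sweep form; the
  experiments show sweep shapes but do not parameterize them. Defaults put
  the *BEM3* midpoint at generation 150, *NRP1* at 450 and *BEM2* at 650
  with steepness 0.03–0.04 per generation, reproducing an early, a middle
  and a late sweep within 1000 generations. Peak heights are `(f, 1 − f)`
  times a per-timepoint trace gain uniform in [0.5, 2] — only the height
  ratio is meaningful, matching the peak-ratio estimator — plus additive
  background at 5% of the gain, so unswept loci show small spurious peaks
  as real traces do.
* **The toy genome** (20 kb, four CDSs including one on the minus strand)
  is random sequence with reference codons planted so that nonsense
  (including the A-line-style *BEM3* `Q61*` stop), missense, synonymous,
  promoter and far-intergenic variants all exist, on both strands, with
  their expected labels saved. Ancestor "background" variants are shared by
  all strains so the ancestor-vs-evolved comparison has something to
  remove. No read-level or chromatogram-waveform simulation is attempted.
* **Spore grids** draw genotypes uniformly over the 16 combinations (ideal
  1:1 Mendelian segregation; the four loci are on different chromosomes in
  the reconstruction cross, so linkage is ignored), survival Bernoulli per
  genotype, and colony radii normal around a genotype mean that scales with
  growth rate. Default survival probabilities scale as
  `0.97·sqrt(w/w_max)` — a one-time modeling choice tying colony formation
  to fitness, qualitatively matching `bem1∆` spores being least viable.
* **Polarity traces** give each mother a cytokinesis frame, a geometric-like
  (1 + Poisson) frame delay to the first spot, a 1 + Poisson polarized
  duration, and per-frame spot counts in 0–3 drawn from strain-specific
  probabilities; a strain-specific fraction of cells never polarizes within
  the window and is emitted censored. The generator reproduces summary
  statistics of manual scoring, not spatial imaging.

What passing tests on these inputs shows is that the *estimators* are
correct and well-calibrated under the stated noise models; it does not
certify performance on pathologies the generators omit (clumping artifacts
beyond winsorization, per-trace Sanger backgrounds, uneven plating,
segmentation errors).

# Phenotype estimation

The "exponential fit" is implemented as least-squares regression of
ln(count) on time: under multiplicative log-normal noise this is the
maximum-likelihood estimator, closed-form and stable; a nonlinear
least-squares option (`method = "nls"`, started from the log-linear
estimates) is provided for comparison since the original fitting method is
not specified beyond "exponential". Noiseless series are recovered to
machine precision for any rate and intercept. Inputs with fewer than three
points, non-positive counts or non-increasing times are rejected.

`relative_fitness()` propagates errors to first order,
`se = ratio·sqrt((se_a/r_a)² + (se_b/r_b)²)`. A caveat the tests exercise:
when the denominator rate is poorly measured (a `bem1∆`-like strain grows
only ~26% over a 5.5 h sampling window), per-pair ratios are biased upward
by the reciprocal, so replicate rates should be averaged *before* forming a
ratio. The acceptance script does exactly that.

`fit_lognormal()` uses the mean and SD of log-samples (the SD with the
usual n−1 denominator; at the n ≥ 10³ sizes used the distinction from the
MLE is negligible) and reports the mode `exp(μ − σ²)` — the peak of the
size distribution, used as the dominant cell size — and the linear-scale SD
`sqrt((e^{σ²} − 1)·e^{2μ+σ²})`, in the same units as the mode, alongside
the log-scale parameters. An optional upper-quantile winsorization flag
(default off) caps clumped-particle tails before fitting.

# Mutation identification

`ancestor_delta()` treats variant records as sets keyed by
(chrom, pos, alt): candidates are evolved-strain records absent from the
ancestor. Duplicate keys within one strain are an input error, not silently
collapsed.

`classify_variants()` applies the acceptance rule with the standard nuclear
genetic code (via Biostrings' `GENETIC_CODE`): inside a CDS the affected
codon is translated before and after the substitution — same residue is
`rejected_synonymous`, a new stop is `nonsense`, any other change
`missense`, with amino-acid notation `refAA` + codon index + `altAA` and
`*` for stop. The promoter window is half-open and strand-aware: positions
`[start − 500, start − 1]` on the plus strand, `[end + 1, end + 500]` on
the minus strand; a position upstream of two divergent genes is reported
once per gene. Indels are not translated: inside a CDS they are flagged
`frameshift` (treated as accepted loss-of-function calls by recurrence),
elsewhere they fall through to the promoter/intergenic logic. Reference
mismatches between a variant record and the genome abort with the position
named. A property test confirms the classifier is invariant under
reverse-complementing the genome with coordinates and strands flipped.

`recurrence()` counts *lines*, not calls: a gene hit twice in one line
counts once for that line, and only accepted effects count. Genes in at
least `min_lines = 3` lines are flagged recurrent, sorted by count then
name.

# Allele fractions and sweep order

`allele_fraction()` is the peak-ratio estimator `h_mut/(h_mut + h_anc)`
with the published clamping: raw values below the background level are 0,
above 0.95 are 1. The background default is 0.05 — "approximate background"
is not quantified for the original traces, so it is a configuration
parameter, and per-trace backgrounds are deliberately not modeled. Clamping
before onset detection means sub-background noise can never create a
spurious early sweep onset.

`infer_order()` ranks loci by onset (first generation with clamped f > 0;
loci that never rise rank last with onset ∞). Exact onset ties are resolved
by the pointwise difference of the two series over shared generations — a
consistently higher fraction means the earlier sweep; a sign-changing or
everywhere-zero difference flags the adjacent pair `uncertain` rather than
forcing an order. Loci without any shared timepoints are an error.

# Spore statistics

`survival_summary()` reports the published quantities verbatim:
`pct = 100·n_obs/n_exp` and the statistical error `pct/√N` with
N = observed colonies — kept exactly as printed even though a binomial SE
differs; the binomial SE is offered as an extra column
(`pct_error_binomial`, with the proportion clamped to [0, 1] since
per-genotype draws can exceed the grid-average expectation). Zero observed
colonies yield pct 0 with a flagged, undefined error instead of a division
by zero. Radius statistics use surviving colonies only.

# The fitness hypercube

Growth rate is used directly as fitness; no additional transform is
applied, matching how the landscape is displayed in the source system.
`enumerate_paths()` enumerates the k! orderings of the k deletions
separating two genotypes (deletions are never reverted; unreachable
end-points are an error; k = 0 gives the single trivial path).
`accessible_paths()` offers two step criteria, because the statistical rule
used to call a step beneficial in the original analysis is unstated:

* `epsilon`: every step gain must exceed a margin Δ (Δ = 0 is plain
  monotone increase);
* `z` (default): a one-sided Welch z-test per step at α = 0.05 using the
  per-genotype SEs.

Paths crossing a genotype with no fitness value are flagged `unevaluable`
and retained, never dropped silently. Accessibility is monotone in Δ by
construction, which the tests verify.

`epistasis_class()` computes the four conditional effects on a fixed
background and classifies: additive within tolerance (`none`), same signs
but non-additive (`magnitude`), exactly one effect flipping sign (`sign`),
both flipping (`reciprocal_sign`). The numeric tolerance (default 1e−9)
treats sub-tolerance effects as zero, so a flip requires strictly opposite
signs. `bem1_dependence()` returns `w(BEM1 intact) − w(bem1∆)` per
background with SEs combined in quadrature, skipping (with a warning)
backgrounds missing either state.

**The fixture landscape.** Numeric per-genotype rates are not published, so
`fixture_landscape()` ships synthetic values — a fixture, not data —
encoding the qualitative statements the analyses rest on: wild type 0.5/h
with the founder 12-fold slower; each step of the observed
*BEM3* → *NRP1* → *BEM2* trajectory beneficial; deleting *BEM2* neutral or
deleterious in every other background; restoring *BEM1* strongly beneficial
on the wild-type background and slightly deleterious in the triple mutant.
On this landscape exactly two of the six orderings — those adding *bem2∆*
last — are accessible, which the tests check against a brute-force filter.

# The serial-dilution simulator

The protocol is modeled directly: cultures grow to
`density_threshold × volume_ml` = 5·10⁸ cells, are diluted 1000-fold
(≈ `log2(1000)` → 10 generations per passage; 100 passages = 1000
generations) to `n0` = 5·10⁵ founders. Growth within a passage is
deterministic and exponential per genotype — the population never drops
below ~5·10⁵ cells, so demographic growth noise is negligible relative to
the two retained noise sources: mutation (Poisson per division, rate
`mu_lof × target_size` per gene, bit flips 0 → 1 only) and the bottleneck
(multinomial over genotype frequencies). An `expectation` mode replaces
both draws by their means and is fully deterministic, which lets the tests
compare two-genotype dynamics to the logistic closed form
`odds(t) = odds(0)·e^{(r_A − r_B)·t}` at 1e−9: the growth time per passage
is solved by `uniroot` plus Newton polishing to machine precision.

Mutation-supply defaults: `mu_lof = 1e−7` per gene (unit target) per
division — no rates are published, so this is a configuration parameter
with the target sizes carrying the biology. Relative targets default to
10:5:3 for *BEM3*:*NRP1*:*BEM2*, proportional to the observed recurrence
counts across ten lines, which is the natural empirical proxy for relative
loss-of-function target size; *BEM1* has target 0 and is excluded from the
move set — its ORF was removed from the genome, so reversion is impossible.
Back-mutation generally is disallowed: the adaptive mutations are losses of
function.

Two event orders are recorded per locus: *appearance* (first passage with a
nonzero mutant-allele count; within a passage, ties are broken by an
exchangeable uniform draw, matching the fact that mutation events occur at
random times during growth) and *fixation* (first passage with allele
frequency above 0.95). The neutral-uniformity property — on a flat
landscape with symmetric targets, all six orders equally likely — is tested
on appearance order: in protocol-sized populations nothing sweeps to
fixation in a neutral run, while first appearances are exchangeable and
therefore exactly uniform. The test uses rate 0.3/h for all genotypes,
unit targets, `mu_lof = 1e−9` (so appearances are temporally resolvable
rather than all arriving in passage 1), 40 passages and 600 replicates,
χ² at α = 0.01. With selection on the fixture landscape and default
targets, replicate fixation orders are strongly modal at
*BEM3* → *NRP1* → *BEM2*.

`order_statistics()` summarizes replicate orders with Wilson score
intervals (never the Wald interval, which degenerates at frequencies near
0 or 1).

# Polarity dynamics

Per mother cell, `t_fs−c` is the frame difference from cytokinesis to the
first polarity spot times the frame interval (2 or 3 min, as imaged), and
the k-spot budgets count frames over the half-open window
`[t_fs, bud)` — endpoint handling is unstated in the source scoring, and
half-open makes the budgets partition the segment exactly:
`Σ_k time_k = (bud − first_spot) × interval`, an identity the tests assert
for every synthetic trace. Spot counts above three are clamped to 3 with a
warning, matching the 0–3 scoring scheme. Cells without an observed first
spot are censored: they contribute to censoring counts and to
`polarization_probability()` (budding within the window), never to the
averages. Only mother cells are modeled, minimizing cell-size effects, as
in the original scoring.

# Pipeline, sizes and budgets

`run_pipeline()` executes the stages in dependency order on synthetic
inputs, marks skipped stages absent, and emits a manifest (config digest,
per-stage substream seeds, output-file md5s); identical configurations
reproduce identical digests. Problem sizes are chosen so the full test
suite runs in well under a minute of simulation time per property: 12-point
growth curves, 10⁵-sample size fits where the 1% mode tolerance requires
it and 2·10⁴ elsewhere, 810-spore grids, 600 neutral simulator replicates,
and 10-replicate selective runs. These are the package's default
demonstration sizes; all are configuration parameters.

# Known limitations

* Only single-nucleotide substitutions are translated; indels get a
  pragmatic `frameshift` label without realignment, and multi-nucleotide
  substitutions are not supported.
* Heterozygous or low-frequency variant filtering is assumed done upstream;
  the pipeline expects haploid calls (the one diploidized line in the
  source system was excluded there too).
* The simulator resolves clonal interference only through its explicit
  genotype frequencies; there is no coalescent machinery, and fitness acts
  through growth rate only, not through germination survival.
* Sweep curves are exactly logistic; real sweeps in a 4-locus system can be
  distorted by hitchhiking among the loci, which the generator does not
  model (the inference functions are agnostic to the true shape).
* The fixture landscape is synthetic: analyses that depend on its numeric
  values (path accessibility margins, simulated fixation times) are
  demonstrations of method, not measurements.
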