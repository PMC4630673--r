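#' Fitness landscapes on the four-locus genotype hypercube
#'
#' A genotype is a bit-string over an ordered set of loci (default
#' `BEM1, BEM2, BEM3, NRP1`), with bit 1 meaning the locus is deleted; the
#' 2^L genotypes form a hypercube whose edges connect genotypes differing by
#' one deletion. A `fitness_landscape` attaches a growth rate (per hour,
#' used directly as fitness), its standard error and a replicate count to
#' each genotype.
#'
#' @param data Data frame with columns `genotype` (bit-string), `rate`
#'   (per hour), and optionally `se` (per hour) and `n_reps`.
#' @param loci Character vector of locus names, one per bit position.
#' @return A `fitness_landscape`: a tibble with columns `genotype`, `rate`,
#'   `se`, `n_reps` and a `loci` attribute.
#' @export
#' @examples
#' fl <- fixture_landscape()
#' landscape_rate(fl, "1000")
fitness_landscape <- function(data, loci = c("BEM1", "BEM2", "BEM3", "NRP1")) {
  d <- as_tibble(data)
  stopifnot(all(c("genotype", "rate") %in% names(d)))
  if (!"se" %in% names(d)) d$se <- 0
  if (!"n_reps" %in% names(d)) d$n_reps <- 1L
  d$genotype <- as.character(d$genotype)
  if (any(nchar(d$genotype) != length(loci)) ||
      any(!grepl("^[01]+$", d$genotype))) {
    abort("genotypes must be 0/1 bit-strings, one bit per locus")
  }
  if (anyDuplicated(d$genotype)) abort("duplicate genotypes in landscape")
  if (any(d$rate < 0)) abort("growth rates must be >= 0")
  d <- select(d, "genotype", "rate", "se", "n_reps")
  structure(d, class = c("fitness_landscape", class(d)), loci = loci)
}

#' @rdname fitness_landscape
#' @export
landscape_loci <- function(data) attr(data, "loci")

#' Look up the growth rate (and SE) of genotypes in a landscape
#'
#' @param landscape A [fitness_landscape()].
#' @param genotype Character vector of genotype bit-strings.
#' @return For `landscape_rate`, a numeric vector of rates (NA where the
#'   genotype is absent); `landscape_se` likewise for standard errors.
#' @export
landscape_rate <- function(landscape, genotype) {
  landscape$rate[match(genotype, landscape$genotype)]
}

#' @rdname landscape_rate
#' @export
landscape_se <- function(landscape, genotype) {
  landscape$se[match(genotype, landscape$genotype)]
}

#' Synthetic reference landscape for the bem1-deletion adaptation system
#'
#' A synthetic 16-genotype fixture encoding the qualitative structure of the
#' measured landscape: wild type grows at 0.5/h and the starting
#' bem1-deleted genotype about 12-fold slower; each mutation along the
#' observed BEM3 -> NRP1 -> BEM2 trajectory increases growth rate; deleting
#' BEM2 in any other background reduces (or leaves unchanged) the growth
#' rate; and restoring BEM1 is strongly beneficial in the wild-type
#' background but slightly deleterious once BEM2, BEM3 and NRP1 are all
#' deleted. The numeric values are fixture choices, not measurements.
#'
#' @param loci Locus names in bit order.
#' @param se Common per-genotype standard error (per hour).
#' @param n_reps Replicate count recorded per genotype.
#' @return A [fitness_landscape()] over all 16 genotypes.
#' @export
fixture_landscape <- function(loci = c("BEM1", "BEM2", "BEM3", "NRP1"),
                              se = 0.008, n_reps = 3L) {
  rates <- c(
    "0000" = 0.500, "0001" = 0.490, "0010" = 0.490, "0011" = 0.480,
    "0100" = 0.450, "0101" = 0.440, "0110" = 0.440, "0111" = 0.460,
    "1000" = 0.042, "1001" = 0.080, "1010" = 0.200, "1011" = 0.350,
    "1100" = 0.035, "1101" = 0.060, "1110" = 0.150, "1111" = 0.480
  )
  fitness_landscape(
    tibble(genotype = names(rates), rate = unname(rates),
           se = se, n_reps = n_reps),
    loci = loci
  )
}

#' All genotypes of an L-locus hypercube
#'
#' @param n_loci Number of loci.
#' @return Character vector of the `2^n_loci` genotype bit-strings.
#' @export
#' @examples
#' length(all_genotypes(4)) # 16
all_genotypes <- function(n_loci = 4L) {
  grid <- expand.grid(rep(list(0:1), n_loci))[, n_loci:1, drop = FALSE]
  apply(grid, 1L, paste, collapse = "")
}

genotype_bits <- function(genotype) {
  as.integer(strsplit(genotype, "")[[1]])
}

bits_genotype <- function(bits) paste(bits, collapse = "")

#' Human-readable genotype label
#'
#' @param genotype Genotype bit-string.
#' @param loci Locus names in bit order.
#' @return A label such as `"bem1∆ bem3∆"`, or `"wild type"` for the
#'   all-intact genotype.
#' @export
genotype_label <- function(genotype, loci = c("BEM1", "BEM2", "BEM3", "NRP1")) {
  vapply(genotype, function(g) {
    bits <- genotype_bits(g)
    if (all(bits == 0)) return("wild type")
    paste0(tolower(loci[bits == 1]), "∆", collapse = " ")
  }, character(1), USE.NAMES = FALSE)
}

# Locus indices deleted in `end` but not in `start`; errors if `start`
# carries a deletion that `end` lacks (deletions cannot revert).
added_loci <- function(start, end) {
  sb <- genotype_bits(start)
  eb <- genotype_bits(end)
  if (any(sb == 1 & eb == 0)) {
    abort("end genotype not reachable: deletions can only be added, not reverted")
  }
  which(sb == 0 & eb == 1)
}

# All permutations of a vector, as a list.
permutations <- function(x) {
  if (length(x) <= 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (p in permutations(x[-i])) out <- c(out, list(c(x[i], p)))
  }
  out
}

#' Enumerate all mutational paths between two genotypes
#'
#' Lists every trajectory from `start` to `end` on the hypercube that adds
#' one deletion per step (deletions are never reverted): with k loci to add
#' there are exactly k! paths, one per ordering.
#'
#' @param landscape A [fitness_landscape()].
#' @param start,end Genotype bit-strings; `end` must carry every deletion of
#'   `start`.
#' @return A tibble with one row per path: `path_id`, `order` (loci added,
#'   `">"`-separated), `genotypes` (list-column of the genotype sequence),
#'   `step_gains` (list-column of fitness increments per step),
#'   `min_step_gain`, and `unevaluable` (TRUE when any genotype on the path
#'   has no fitness value).
#' @export
#' @examples
#' enumerate_paths(fixture_landscape(), "1000", "1111")
enumerate_paths <- function(landscape, start, end) {
  loci <- landscape_loci(landscape)
  add <- added_loci(start, end)
  orders <- permutations(add)
  rows <- map(seq_along(orders), function(i) {
    ord <- orders[[i]]
    bits <- genotype_bits(start)
    gts <- bits_genotype(bits)
    for (l in ord) {
      bits[l] <- 1L
      gts <- c(gts, bits_genotype(bits))
    }
    w <- landscape_rate(landscape, gts)
    gains <- if (length(gts) > 1) diff(w) else numeric(0)
    tibble(
      path_id = i,
      order = paste(loci[ord], collapse = ">"),
      genotypes = list(gts),
      step_gains = list(gains),
      min_step_gain = if (length(gains) && !anyNA(gains)) min(gains) else NA_real_,
      unevaluable = anyNA(w)
    )
  })
  list_rbind(rows)
}

#' Selectively accessible paths under a fitness-increase criterion
#'
#' Filters the k! mutational orderings between two genotypes to those along
#' which every single-deletion step increases fitness, under either a fixed
#' margin (`criterion = "epsilon"`: each step gain must exceed `delta`) or a
#' one-sided Welch z-test on the per-genotype standard errors
#' (`criterion = "z"`: each step gain must be significantly positive at
#' level `alpha`). Paths touching a genotype with no fitness value are
#' flagged `unevaluable` and retained (never silently dropped).
#'
#' @inheritParams enumerate_paths
#' @param criterion `"z"` (default) or `"epsilon"`.
#' @param delta Margin for the epsilon criterion (rate units); `delta = 0`
#'   is plain monotone increase.
#' @param alpha One-sided level for the z criterion.
#' @return The [enumerate_paths()] tibble with an added logical `accessible`
#'   column, filtered to accessible or unevaluable paths.
#' @export
#' @examples
#' accessible_paths(fixture_landscape(), "1000", "1111", criterion = "epsilon")
accessible_paths <- function(landscape, start, end,
                             criterion = c("z", "epsilon"),
                             delta = 0, alpha = 0.05) {
  criterion <- match.arg(criterion)
  paths <- enumerate_paths(landscape, start, end)
  zcrit <- qnorm(1 - alpha)
  ok <- pmap(list(paths$genotypes, paths$step_gains), function(gts, gains) {
    if (length(gains) == 0) return(TRUE) # trivial path: start == end
    if (anyNA(gains)) return(NA)
    if (criterion == "epsilon") return(all(gains > delta))
    se_pair <- sqrt(landscape_se(landscape, gts[-length(gts)])^2 +
                      landscape_se(landscape, gts[-1])^2)
    z <- ifelse(se_pair > 0, gains / se_pair, ifelse(gains > 0, Inf, -Inf))
    all(z > zcrit)
  })
  paths$accessible <- vapply(ok, function(x) isTRUE(x), logical(1))
  filter(paths, .data$accessible | .data$unevaluable)
}

#' Classify pairwise epistasis between two loci on a common background
#'
#' Computes the fitness effect of deleting each locus with the other intact
#' and deleted, on a fixed background at the remaining loci, and classifies
#' the interaction: `none` (additive within `tol`), `magnitude` (same signs,
#' non-additive), `sign` (exactly one locus's effect switches sign across
#' the other's states), or `reciprocal_sign` (both switch).
#'
#' @param landscape A [fitness_landscape()].
#' @param locus_a,locus_b Locus names.
#' @param background Genotype bit-string giving the state of the remaining
#'   loci (bits at `locus_a`/`locus_b` positions are ignored and taken as 0).
#' @param tol Absolute tolerance (rate units) below which an effect or a
#'   deviation from additivity is treated as zero.
#' @return A one-row tibble: the four conditional effects
#'   (`effect_a_given_b_intact`, `effect_a_given_b_deleted`, and likewise
#'   for b), the deviation from additivity `epsilon`, and `class`.
#' @export
#' @examples
#' epistasis_class(fixture_landscape(), "BEM2", "NRP1", background = "1010")
epistasis_class <- function(landscape, locus_a, locus_b, background,
                            tol = 1e-9) {
  loci <- landscape_loci(landscape)
  ia <- match(locus_a, loci)
  ib <- match(locus_b, loci)
  if (is.na(ia) || is.na(ib) || ia == ib) abort("locus_a and locus_b must name two distinct loci")
  bits <- genotype_bits(background)
  bits[c(ia, ib)] <- 0L
  gt <- function(a, b) {
    x <- bits
    x[ia] <- a
    x[ib] <- b
    bits_genotype(x)
  }
  need <- c(gt(0, 0), gt(1, 0), gt(0, 1), gt(1, 1))
  w <- landscape_rate(landscape, need)
  if (anyNA(w)) {
    abort(paste("missing genotype fitness:", paste(need[is.na(w)], collapse = ", ")))
  }
  names(w) <- c("w00", "w10", "w01", "w11")
  da0 <- w[["w10"]] - w[["w00"]] # effect of deleting a, b intact
  da1 <- w[["w11"]] - w[["w01"]] # effect of deleting a, b deleted
  db0 <- w[["w01"]] - w[["w00"]]
  db1 <- w[["w11"]] - w[["w10"]]
  eps <- w[["w11"]] - w[["w10"]] - w[["w01"]] + w[["w00"]]
  zsign <- function(x) if (abs(x) <= tol) 0 else sign(x)
  flip_a <- zsign(da0) * zsign(da1) < 0
  flip_b <- zsign(db0) * zsign(db1) < 0
  cls <- if (flip_a && flip_b) {
    "reciprocal_sign"
  } else if (flip_a || flip_b) {
    "sign"
  } else if (abs(eps) <= tol) {
    "none"
  } else {
    "magnitude"
  }
  tibble(
    locus_a = locus_a, locus_b = locus_b, background = bits_genotype(bits),
    effect_a_given_b_intact = da0, effect_a_given_b_deleted = da1,
    effect_b_given_a_intact = db0, effect_b_given_a_deleted = db1,
    epsilon = eps, class = cls
  )
}

#' Effect of restoring BEM1 in each genetic background
#'
#' For every background over the non-BEM1 loci where both BEM1 states are
#' present in the landscape, returns the fitness change from restoring BEM1:
#' `w(BEM1 intact) - w(bem1 deleted)`, with the standard error propagated as
#' `sqrt(se_intact^2 + se_deleted^2)`. Backgrounds missing either state are
#' skipped with a warning.
#'
#' @param landscape A [fitness_landscape()] whose first locus is BEM1.
#' @return A tibble with columns `background` (states of the other loci),
#'   `background_label`, `effect`, `se`.
#' @export
#' @examples
#' bem1_dependence(fixture_landscape())
bem1_dependence <- function(landscape) {
  loci <- landscape_loci(landscape)
  backgrounds <- all_genotypes(length(loci) - 1L)
  rows <- map(backgrounds, function(bg) {
    intact <- paste0("0", bg)
    deleted <- paste0("1", bg)
    w1 <- landscape_rate(landscape, intact)
    w0 <- landscape_rate(landscape, deleted)
    if (is.na(w1) || is.na(w0)) {
      warn(paste("skipping background", bg, ": missing a BEM1 state"))
      return(NULL)
    }
    tibble(
      background = bg,
      background_label = genotype_label(paste0("0", bg), loci),
      effect = w1 - w0,
      se = sqrt(landscape_se(landscape, intact)^2 +
                  landscape_se(landscape, deleted)^2)
    )
  })
  list_rbind(rows)
}
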