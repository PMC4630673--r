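# Allele-fraction estimation from Sanger trace peak heights and temporal
# ordering of selective sweeps.

#' Mutant-allele fraction from Sanger peak heights
#'
#' The population fraction of a mutant allele is estimated as the height of
#' the mutant peak divided by the sum of mutant and ancestor peak heights,
#' then clamped: raw values below the background level are set to 0 and
#' values above 0.95 are set to 1, since chromatogram noise makes very small
#' and very large fractions unresolvable.
#'
#' @param h_mut,h_anc Non-negative peak heights (vectors recycle).
#' @param background Background level below which the raw fraction is
#'   assumed to be zero (default 0.05).
#' @return Numeric vector of clamped fractions in `{0} U [background, 0.95] U {1}`.
#' @export
#' @examples
#' allele_fraction(c(0, 97, 50), c(100, 3, 50)) # 0, 1, 0.5
allele_fraction <- function(h_mut, h_anc, background = 0.05) {
  if (any(h_mut < 0) || any(h_anc < 0)) abort("peak heights must be >= 0")
  tot <- h_mut + h_anc
  if (any(tot == 0)) abort("both peak heights are zero: fraction undefined")
  raw <- h_mut / tot
  dplyr::case_when(raw < background ~ 0, raw > 0.95 ~ 1, TRUE ~ raw)
}

#' Clamped allele-fraction time course per locus
#'
#' @param data Data frame with columns `locus`, `generation`, `h_mut`,
#'   `h_anc` (e.g. from [gen_sweep_series()]).
#' @param background Passed to [allele_fraction()].
#' @return The input with an added `f` column of clamped fractions.
#' @export
sanger_timecourse <- function(data, background = 0.05) {
  d <- as_tibble(data)
  stopifnot(all(c("locus", "generation", "h_mut", "h_anc") %in% names(d)))
  mutate(d, f = allele_fraction(.data$h_mut, .data$h_anc, background))
}

#' Infer the temporal order of mutations from allele-fraction time courses
#'
#' Orders loci by sweep onset: the first generation at which the clamped
#' fraction exceeds zero (clamping means sub-background noise cannot create
#' spurious early onsets). Ties in onset are broken by the pointwise
#' differences of the two time courses over their shared generations — the
#' locus with the consistently higher fraction swept earlier; if the
#' difference changes sign, the pair is flagged uncertain.
#'
#' @param data Data frame with columns `locus`, `generation`, and either
#'   `f` or the peak-height columns `h_mut`/`h_anc`.
#' @param background Passed to [allele_fraction()] when `f` is absent.
#' @return A tibble with one row per locus in inferred temporal order:
#'   `rank`, `locus`, `onset` (generation; `Inf` if the locus never rises),
#'   `uncertain` (TRUE when the ordering relative to an adjacent locus
#'   relied on a tie-break whose pointwise differences change sign or are
#'   all zero).
#' @export
#' @examples
#' cfg <- synth_config(seed = 1)
#' gens <- seq(0, 1000, by = 50)
#' tc <- dplyr::bind_rows(lapply(c("BEM3", "NRP1", "BEM2"), function(l)
#'   gen_sweep_series(cfg, l, gens)))
#' infer_order(tc)
infer_order <- function(data, background = 0.05) {
  d <- as_tibble(data)
  if (!"f" %in% names(d)) d <- sanger_timecourse(d, background)
  loci <- unique(d$locus)
  if (length(loci) < 2) abort("at least 2 loci are required")
  series <- map(setNames(loci, loci), function(l) {
    s <- filter(d, .data$locus == l) |> arrange(.data$generation)
    if (nrow(s) < 2) abort(paste0("locus '", l, "' has fewer than 2 timepoints"))
    s
  })
  for (i in seq_len(length(loci) - 1)) {
    for (j in seq(i + 1, length(loci))) {
      if (length(intersect(series[[loci[i]]]$generation,
                           series[[loci[j]]]$generation)) == 0) {
        abort(paste0("loci '", loci[i], "' and '", loci[j],
                     "' share no timepoints"))
      }
    }
  }
  onset <- map_dbl(series, function(s) {
    up <- which(s$f > 0)
    if (length(up) == 0) Inf else s$generation[up[1]]
  })
  # pairwise comparison used for onset ties: +1 if a swept before b,
  # -1 if after, 0/NA flagged uncertain
  pair_cmp <- function(a, b) {
    shared <- intersect(series[[a]]$generation, series[[b]]$generation)
    if (length(shared) == 0) {
      abort(paste0("loci '", a, "' and '", b, "' share no timepoints"))
    }
    fa <- series[[a]]$f[match(shared, series[[a]]$generation)]
    fb <- series[[b]]$f[match(shared, series[[b]]$generation)]
    dd <- fa - fb
    if (all(dd >= 0) && any(dd > 0)) return(1)
    if (all(dd <= 0) && any(dd < 0)) return(-1)
    0 # identical or sign-changing: uncertain
  }
  ord <- order(onset, loci)
  uncertain <- logical(length(loci))
  # resolve onset ties among adjacent loci in the onset ordering
  for (i in seq_len(length(ord) - 1)) {
    a <- loci[ord[i]]
    b <- loci[ord[i + 1]]
    if (onset[a] == onset[b]) {
      cmp <- pair_cmp(a, b)
      if (cmp < 0) ord[c(i, i + 1)] <- ord[c(i + 1, i)]
      if (cmp == 0) uncertain[c(i, i + 1)] <- TRUE
    }
  }
  tibble(
    rank = seq_along(ord),
    locus = loci[ord],
    onset = unname(onset[loci[ord]]),
    uncertain = uncertain
  )
}
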