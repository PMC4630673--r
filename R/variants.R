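# Mutation identification: compare variant tables between ancestor and
# evolved strains, classify candidates against the annotated genome, and
# count per-gene recurrence across lines.

ACCEPTED_EFFECTS <- c("nonsense", "missense", "promoter", "frameshift")

# Fetch len bases from a genome (DNAStringSet or named character vector).
genome_seq <- function(genome, chrom, pos, len = 1L) {
  if (inherits(genome, "DNAStringSet")) {
    if (!chrom %in% names(genome)) abort(paste0("unknown chromosome '", chrom, "'"))
    as.character(Biostrings::subseq(genome[[chrom]], pos, pos + len - 1L))
  } else {
    substr(genome[[chrom]], pos, pos + len - 1L)
  }
}

revcomp <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[[codon]]
  if (is.null(aa)) abort(paste0("cannot translate codon '", codon, "'"))
  aa
}

#' Variants present in an evolved strain but absent from its ancestor
#'
#' The hand-off from upstream variant calling: candidate adaptive mutations
#' are the variants that occur between the ancestor and an evolved strain,
#' i.e. present (same `chrom`, `pos`, `alt`) in the evolved table and absent
#' from the ancestor table. Reference-vs-ancestor differences shared by both
#' are thereby removed.
#'
#' @param evolved_variants,ancestor_variants Data frames with columns
#'   `chrom`, `pos`, `ref`, `alt` (and optionally `strain`).
#' @return A tibble of the evolved-only variants, same columns as
#'   `evolved_variants`.
#' @export
#' @examples
#' ev <- tibble::tibble(chrom = "c", pos = c(10, 20), ref = "A", alt = "T")
#' an <- ev[1, ]
#' ancestor_delta(ev, an) # only pos 20
ancestor_delta <- function(evolved_variants, ancestor_variants) {
  ev <- as_tibble(evolved_variants)
  an <- as_tibble(ancestor_variants)
  key <- c("chrom", "pos", "alt")
  for (tab in list(ev, an)) {
    grp <- if ("strain" %in% names(tab)) c("strain", key) else key
    if (nrow(tab) > 0 && anyDuplicated(tab[grp])) {
      abort("duplicate (chrom, pos, alt) records within one strain")
    }
  }
  if (nrow(an) == 0) return(ev)
  anti_join(ev, an, by = key)
}

classify_one <- function(chrom, pos, ref, alt, genome, annotation, promoter_bp) {
  ann <- annotation[annotation$chrom == chrom, , drop = FALSE]
  is_snv <- nchar(ref) == 1L && nchar(alt) == 1L
  if (is_snv) {
    gbase <- genome_seq(genome, chrom, pos, 1L)
    if (gbase != ref) {
      abort(sprintf("reference base mismatch at %s:%d (genome %s, variant ref %s)",
                    chrom, pos, gbase, ref))
    }
  }
  hit <- which(ann$start <= pos & pos <= ann$end)
  if (length(hit) == 1L) {
    g <- ann[hit, ]
    if (!is_snv) {
      # indel inside a CDS: nonsense-like loss of function, flagged as such
      return(tibble(gene = g$gene, effect = "frameshift",
                    aa_change = NA_character_))
    }
    coding_pos <- if (g$strand == "+") pos - g$start + 1L else g$end - pos + 1L
    codon_idx <- ((coding_pos - 1L) %/% 3L) + 1L
    offset <- coding_pos - 3L * (codon_idx - 1L)
    ref_codon <- if (g$strand == "+") {
      genome_seq(genome, chrom, g$start + 3L * (codon_idx - 1L), 3L)
    } else {
      revcomp(genome_seq(genome, chrom, g$end - 3L * codon_idx + 1L, 3L))
    }
    alt_base <- if (g$strand == "+") alt else chartr("ACGT", "TGCA", alt)
    alt_codon <- ref_codon
    substr(alt_codon, offset, offset) <- alt_base
    ref_aa <- translate_codon(ref_codon)
    alt_aa <- translate_codon(alt_codon)
    effect <- if (ref_aa == alt_aa) {
      "rejected_synonymous"
    } else if (alt_aa == "*") {
      "nonsense"
    } else {
      "missense"
    }
    return(tibble(gene = g$gene, effect = effect,
                  aa_change = paste0(ref_aa, codon_idx, alt_aa)))
  }
  # promoter: within promoter_bp upstream of a CDS start, strand-aware
  prom <- ann[(ann$strand == "+" &
                 pos >= ann$start - promoter_bp & pos <= ann$start - 1L) |
                (ann$strand == "-" &
                   pos >= ann$end + 1L & pos <= ann$end + promoter_bp), ]
  if (nrow(prom) > 0) {
    # a position can sit upstream of two divergent genes; report both
    return(tibble(gene = prom$gene, effect = "promoter",
                  aa_change = NA_character_))
  }
  tibble(gene = NA_character_, effect = "rejected_intergenic",
         aa_change = NA_character_)
}

#' Classify candidate variants against an annotated genome
#'
#' Applies the mutation-labeling rule: a variant is accepted as a mutation
#' if it (1) causes a non-synonymous substitution in a coding sequence
#' (`nonsense` when the new codon is a stop, else `missense`), or (2) falls
#' in a promoter region, defined as `promoter_bp` (default 500) bp upstream
#' of a CDS start, strand-aware. Synonymous coding changes are labeled
#' `rejected_synonymous` and anything else `rejected_intergenic`. Indels
#' inside a CDS are flagged `frameshift` (loss-of-function-like). Amino-acid
#' changes are reported as e.g. `"Q61*"` (`*` = stop).
#'
#' @param variants Data frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, and optionally `strain`.
#' @param genome Named [Biostrings::DNAStringSet] (or named character
#'   vector) of chromosome sequences.
#' @param annotation Data frame with columns `chrom`, `start`, `end`
#'   (1-based inclusive), `strand` (`"+"`/`"-"`), `gene`.
#' @param promoter_bp Promoter window size in bp upstream of the CDS start.
#' @return A tibble with one row per (variant, gene) combination: the input
#'   columns plus `gene`, `effect`, `aa_change`.
#' @export
#' @examples
#' toy <- gen_toy_genome_and_variants(synth_config(seed = 1))
#' classify_variants(toy$truth[1, 1:4], toy$genome, toy$annotation)
classify_variants <- function(variants, genome, annotation, promoter_bp = 500L) {
  v <- as_tibble(variants)
  stopifnot(all(c("chrom", "pos", "ref", "alt") %in% names(v)))
  if (any(v$pos < 1)) abort("positions must be >= 1")
  ann <- as_tibble(annotation)
  if (!all(ann$strand %in% c("+", "-"))) abort("annotation strand must be '+' or '-'")
  rows <- map(seq_len(nrow(v)), function(i) {
    res <- classify_one(v$chrom[i], v$pos[i], v$ref[i], v$alt[i],
                        genome, ann, promoter_bp)
    bind_rows(lapply(seq_len(nrow(res)), function(j) {
      dplyr::bind_cols(v[i, ], res[j, ])
    }))
  })
  list_rbind(rows)
}

#' Per-gene mutation recurrence across independent lines
#'
#' Counts, for each gene, the number of lines carrying at least one accepted
#' mutation call (`nonsense`, `missense`, `promoter`, or `frameshift`) in
#' that gene — multiple calls in one line count once — and flags genes hit
#' in at least `min_lines` lines as recurrent.
#'
#' @param calls Data frame of classified calls with columns `strain` (line
#'   identifier), `gene`, `effect`.
#' @param min_lines Recurrence threshold (default 3 lines).
#' @return A tibble with one row per mutated gene: `gene`, `n_lines`,
#'   `recurrent`, sorted by `n_lines` descending then gene name.
#' @export
#' @examples
#' calls <- tibble::tibble(strain = c("A1", "A2", "A1"),
#'                         gene = c("BEM3", "BEM3", "NRP1"),
#'                         effect = "nonsense")
#' recurrence(calls, min_lines = 2)
recurrence <- function(calls, min_lines = 3L) {
  d <- as_tibble(calls) |>
    filter(.data$effect %in% ACCEPTED_EFFECTS, !is.na(.data$gene)) |>
    distinct(.data$strain, .data$gene) |>
    count(.data$gene, name = "n_lines") |>
    mutate(recurrent = .data$n_lines >= min_lines) |>
    arrange(dplyr::desc(.data$n_lines), .data$gene)
  d
}

#' @rdname recurrence
#' @return For `recurrent_genes`, the character vector of recurrent genes.
#' @export
recurrent_genes <- function(calls, min_lines = 3L) {
  r <- recurrence(calls, min_lines)
  r$gene[r$recurrent]
}
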