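# Toy annotated genome with planted variants of every class the
# mutation-identification rule must distinguish. Ground-truth labels are
# returned alongside so the variant pipeline can be validated exactly.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# Write a coding codon into the genome character vector, strand-aware.
# codon_idx is 1-based along the coding sequence.
plant_codon <- function(genome, cds, codon_idx, codon) {
  b <- strsplit(codon, "")[[1]]
  stopifnot(length(b) == 3)
  if (cds$strand == "+") {
    pos <- cds$start + 3L * (codon_idx - 1L) + 0:2
    genome[pos] <- b
  } else {
    coding_pos <- 3L * (codon_idx - 1L) + 1:3
    pos <- cds$end - coding_pos + 1L
    genome[pos] <- unname(COMPLEMENT[b])
  }
  genome
}

# Genomic-coordinate variant record for a single-base codon change.
codon_variant <- function(cds, codon_idx, ref_codon, alt_codon) {
  rb <- strsplit(ref_codon, "")[[1]]
  ab <- strsplit(alt_codon, "")[[1]]
  j <- which(rb != ab)
  stopifnot(length(j) == 1)
  coding_pos <- 3L * (codon_idx - 1L) + j
  if (cds$strand == "+") {
    list(pos = cds$start + coding_pos - 1L, ref = rb[j], alt = ab[j])
  } else {
    list(pos = cds$end - coding_pos + 1L,
         ref = unname(COMPLEMENT[rb[j]]), alt = unname(COMPLEMENT[ab[j]]))
  }
}

#' Generate a toy annotated genome with planted variants and ground truth
#'
#' Builds a random genome of `config$genome_length` bp carrying the
#' configured CDS intervals, plants reference codons so that a defined set
#' of variants of every class exists (nonsense — including the A-line-style
#' BEM3 Q61* stop — missense, synonymous, promoter, and far-intergenic,
#' on both strands), and emits per-strain variant tables: an `ancestor`
#' strain with background variants, and evolved lines `A1`, `A2`, `A3`
#' that carry the ancestor background plus their own planted mutations.
#'
#' @param config A [synth_config()].
#' @return A list with elements `genome` (a named
#'   [Biostrings::DNAStringSet]), `annotation` (tibble: `chrom`, `start`,
#'   `end`, `strand`, `feature`, `gene`), `variants` (tibble: `chrom`,
#'   `pos`, `ref`, `alt`, `strain`), and `truth` (tibble of planted evolved
#'   variants with expected `gene`, `effect`, `aa_change`).
#' @export
#' @examples
#' toy <- gen_toy_genome_and_variants(synth_config(seed = 1))
#' dplyr::count(toy$truth, effect)
gen_toy_genome_and_variants <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cds <- config$cds_intervals
  if (any(cds$end - cds$start + 1 < 3)) abort("each CDS must be at least 3 bp")
  chrom <- "toy_chr"
  genome <- with_seed(
    substream_seed(config$seed, "genome"),
    sample(c("A", "C", "G", "T"), config$genome_length, replace = TRUE)
  )

  cds_row <- function(gene) as.list(cds[cds$gene == gene, ])
  bem3 <- cds_row("BEM3"); nrp1 <- cds_row("NRP1")
  bem2 <- cds_row("BEM2"); syn1 <- cds_row("SYN1")

  plants <- list(
    # gene, codon, ref codon, alt codon, effect, aa_change, strains carrying it
    list(g = bem3, gene = "BEM3", codon = 61L, ref = "CAA", alt = "TAA",
         effect = "nonsense", aa = "Q61*", strains = c("A1", "A2", "A3")),
    list(g = nrp1, gene = "NRP1", codon = 25L, ref = "GGT", alt = "GTT",
         effect = "missense", aa = "G25V", strains = "A1"),
    list(g = nrp1, gene = "NRP1", codon = 30L, ref = "CAA", alt = "TAA",
         effect = "nonsense", aa = "Q30*", strains = "A2"),
    list(g = nrp1, gene = "NRP1", codon = 10L, ref = "CAG", alt = "TAG",
         effect = "nonsense", aa = "Q10*", strains = "A3"),
    list(g = bem2, gene = "BEM2", codon = 30L, ref = "CAA", alt = "TAA",
         effect = "nonsense", aa = "Q30*", strains = "A2"),
    list(g = syn1, gene = "SYN1", codon = 5L, ref = "GCT", alt = "GCC",
         effect = "rejected_synonymous", aa = "A5A", strains = "A1")
  )

  truth_rows <- list()
  for (p in plants) {
    genome <- plant_codon(genome, p$g, p$codon, p$ref)
    v <- codon_variant(p$g, p$codon, p$ref, p$alt)
    truth_rows <- c(truth_rows, list(tibble(
      chrom = chrom, pos = v$pos, ref = v$ref, alt = v$alt,
      strain = p$strains, gene = p$gene, effect = p$effect, aa_change = p$aa
    )))
  }

  # promoter variant for the minus-strand gene BEM2: 200 bp upstream of its
  # CDS start, i.e. downstream of `end` in genomic coordinates
  prom_pos <- bem2$end + 200L
  prom_ref <- genome[prom_pos]
  prom_alt <- setdiff(c("A", "C", "G", "T"), prom_ref)[1]
  truth_rows <- c(truth_rows, list(tibble(
    chrom = chrom, pos = prom_pos, ref = prom_ref, alt = prom_alt,
    strain = "A1", gene = "BEM2", effect = "promoter", aa_change = NA_character_
  )))

  # far-intergenic variant: 600 bp upstream of NRP1, outside the 500-bp window
  far_pos <- nrp1$start - 600L
  far_ref <- genome[far_pos]
  far_alt <- setdiff(c("A", "C", "G", "T"), far_ref)[1]
  truth_rows <- c(truth_rows, list(tibble(
    chrom = chrom, pos = far_pos, ref = far_ref, alt = far_alt,
    strain = "A1", gene = NA_character_, effect = "rejected_intergenic",
    aa_change = NA_character_
  )))

  truth <- list_rbind(truth_rows)

  # ancestor background variants at intergenic positions shared by all strains
  anc_pos <- c(3000L, 7000L, 16000L)
  anc_pos <- anc_pos[anc_pos <= config$genome_length]
  ancestor <- tibble(
    chrom = chrom, pos = anc_pos, ref = genome[anc_pos],
    alt = vapply(genome[anc_pos],
                 function(b) setdiff(c("A", "C", "G", "T"), b)[1], character(1),
                 USE.NAMES = FALSE)
  )

  strains <- unique(truth$strain)
  variants <- bind_rows(
    mutate(ancestor, strain = "ancestor"),
    list_rbind(map(strains, function(s) {
      bind_rows(
        mutate(ancestor, strain = s),
        truth |> filter(.data$strain == s) |>
          select("chrom", "pos", "ref", "alt", "strain")
      )
    }))
  ) |> arrange(.data$strain, .data$pos)

  seq <- Biostrings::DNAStringSet(paste(genome, collapse = ""))
  names(seq) <- chrom
  annotation <- tibble(
    chrom = chrom, start = cds$start, end = cds$end, strand = cds$strand,
    feature = "CDS", gene = cds$gene
  )
  list(genome = seq, annotation = annotation, variants = variants,
       truth = truth)
}
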