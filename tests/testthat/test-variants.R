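toy <- gen_toy_genome_and_variants(test_config())

test_that("ancestor_delta: identity, annihilation, and set-difference oracle", {
  v <- tibble::tibble(chrom = "c", pos = c(5L, 9L, 22L),
                      ref = c("A", "C", "G"), alt = c("T", "G", "A"))
  empty <- v[0, ]
  expect_equal(ancestor_delta(v, empty), v)
  expect_equal(nrow(ancestor_delta(v, v)), 0)
  expect_equal(ancestor_delta(rbind(v, tibble::tibble(
    chrom = "c", pos = 30L, ref = "T", alt = "C")), v)$pos, 30L)

  # random planted sets against a brute-force set difference
  set.seed(7)
  for (rep in 1:20) {
    pos_all <- sample(1:200, 40)
    ev <- tibble::tibble(chrom = "c", pos = sort(sample(pos_all, 25)),
                         ref = "A", alt = sample(c("C", "G", "T"), 25, TRUE))
    an <- ev[sample(nrow(ev), 10), ]
    got <- ancestor_delta(ev, an)
    brute <- ev[vapply(seq_len(nrow(ev)), function(i) {
      !any(an$chrom == ev$chrom[i] & an$pos == ev$pos[i] &
             an$alt == ev$alt[i])
    }, logical(1)), ]
    expect_equal(dplyr::arrange(got, pos), dplyr::arrange(brute, pos))
  }

  dup <- rbind(v, v[1, ])
  expect_error(ancestor_delta(dup, empty), "duplicate")
})

test_that("classification matches an independent full-CDS translation oracle", {
  # oracle: splice the whole CDS out of the genome with Biostrings, apply
  # the variant at the genomic level, translate both, and compare proteins
  oracle_effect <- function(variant, genome, ann_row) {
    seq <- as.character(genome[[variant$chrom]])
    mut <- seq
    substr(mut, variant$pos, variant$pos) <- variant$alt
    get_prot <- function(s) {
      cds <- Biostrings::DNAString(substr(s, ann_row$start, ann_row$end))
      if (ann_row$strand == "-") cds <- Biostrings::reverseComplement(cds)
      as.character(Biostrings::translate(cds, if.fuzzy.codon = "X",
                                         no.init.codon = TRUE))
    }
    p_ref <- get_prot(seq)
    p_alt <- get_prot(mut)
    d <- which(strsplit(p_ref, "")[[1]] != strsplit(p_alt, "")[[1]])
    if (length(d) == 0) return(list(effect = "rejected_synonymous"))
    aa_alt <- substr(p_alt, d, d)
    list(
      effect = if (aa_alt == "*") "nonsense" else "missense",
      aa_change = paste0(substr(p_ref, d, d), d, aa_alt)
    )
  }
  coding_truth <- dplyr::filter(
    toy$truth, effect %in% c("nonsense", "missense", "rejected_synonymous")
  ) |> dplyr::distinct(chrom, pos, ref, alt, gene, effect, aa_change)
  for (i in seq_len(nrow(coding_truth))) {
    v <- coding_truth[i, ]
    ann_row <- toy$annotation[toy$annotation$gene == v$gene, ]
    got <- classify_variants(v[, 1:4], toy$genome, toy$annotation)
    orc <- oracle_effect(v, toy$genome, ann_row)
    expect_equal(got$effect, orc$effect)
    if (orc$effect != "rejected_synonymous") {
      expect_equal(got$aa_change, orc$aa_change)
    }
    expect_equal(got$gene, v$gene)
  }
})

test_that("classify reproduces all planted ground-truth labels exactly", {
  truth <- dplyr::distinct(toy$truth, chrom, pos, ref, alt, gene, effect,
                           aa_change)
  calls <- classify_variants(truth[, c("chrom", "pos", "ref", "alt")],
                             toy$genome, toy$annotation)
  expect_equal(nrow(calls), nrow(truth))
  expect_equal(calls$effect, truth$effect)
  expect_equal(calls$gene, truth$gene)
  expect_equal(calls$aa_change[truth$effect == "nonsense"],
               truth$aa_change[truth$effect == "nonsense"])
})

test_that("promoter window boundaries are strand-aware and half-open", {
  # isolated plus-strand CDS on a controlled genome
  genome <- Biostrings::DNAStringSet(paste(rep("A", 3000), collapse = ""))
  names(genome) <- "c"
  ann <- tibble::tibble(chrom = "c", start = 1501L, end = 1620L,
                        strand = "+", feature = "CDS", gene = "G")
  cls <- function(pos) {
    classify_variants(tibble::tibble(chrom = "c", pos = pos, ref = "A",
                                     alt = "G"), genome, ann)$effect
  }
  expect_equal(cls(1501L - 200L), "promoter")
  expect_equal(cls(1501L - 500L), "promoter") # window edge, inside
  expect_equal(cls(1501L - 501L), "rejected_intergenic")
  expect_equal(cls(1501L - 600L), "rejected_intergenic")
  # minus strand: promoter lies downstream in genomic coordinates
  ann_m <- dplyr::mutate(ann, strand = "-")
  cls_m <- function(pos) {
    classify_variants(tibble::tibble(chrom = "c", pos = pos, ref = "A",
                                     alt = "G"), genome, ann_m)$effect
  }
  expect_equal(cls_m(1620L + 200L), "promoter")
  expect_equal(cls_m(1620L + 500L), "promoter")
  expect_equal(cls_m(1620L + 501L), "rejected_intergenic")
  expect_equal(cls_m(1501L - 200L), "rejected_intergenic")
})

test_that("classification is invariant under reverse-complementing the genome", {
  L <- test_config()$genome_length
  seq <- as.character(toy$genome[[1]])
  rc <- as.character(Biostrings::reverseComplement(toy$genome[[1]]))
  genome_rc <- Biostrings::DNAStringSet(rc)
  names(genome_rc) <- "toy_chr"
  ann_rc <- dplyr::mutate(toy$annotation,
                          new_start = L - end + 1L, new_end = L - start + 1L,
                          strand = ifelse(strand == "+", "-", "+")) |>
    dplyr::mutate(start = new_start, end = new_end) |>
    dplyr::select(-new_start, -new_end)
  truth <- dplyr::distinct(toy$truth, chrom, pos, ref, alt, effect)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  flipped <- dplyr::mutate(truth, pos = L - pos + 1L,
                           ref = unname(comp[ref]), alt = unname(comp[alt]))
  orig <- classify_variants(truth[, 1:4], toy$genome, toy$annotation)
  mirr <- classify_variants(flipped[, 1:4], genome_rc, ann_rc)
  expect_equal(mirr$effect, orig$effect)
  expect_equal(mirr$aa_change, orig$aa_change)
})

test_that("ref-base mismatches are reported with their position", {
  v <- toy$truth[1, ]
  bad <- dplyr::mutate(v[, 1:4], ref = setdiff(c("A", "C", "G", "T"), ref)[1])
  expect_error(classify_variants(bad, toy$genome, toy$annotation),
               as.character(v$pos))
})

test_that("recurrence counts lines, not calls, and ranks genes", {
  # the in-study pattern: BEM3 in 10/10 lines, NRP1 in 5, BEM2 in 3,
  # plus scattered one-off genes
  lines <- paste0("L", 1:10)
  calls <- dplyr::bind_rows(
    tibble::tibble(strain = lines, gene = "BEM3", effect = "nonsense"),
    tibble::tibble(strain = lines[1:5], gene = "NRP1", effect = "nonsense"),
    tibble::tibble(strain = lines[c(1, 2, 10)], gene = "BEM2",
                   effect = c("missense", "missense", "promoter")),
    tibble::tibble(strain = c("L3", "L7"), gene = c("YFG1", "YFG2"),
                   effect = "missense"),
    # second BEM3 call in line 1 must not double-count
    tibble::tibble(strain = "L1", gene = "BEM3", effect = "missense"),
    # rejected calls never count
    tibble::tibble(strain = lines, gene = "SYN1",
                   effect = "rejected_synonymous")
  )
  rec <- recurrence(calls, min_lines = 3)
  expect_equal(rec$gene[1:3], c("BEM3", "NRP1", "BEM2"))
  expect_equal(rec$n_lines[1:3], c(10, 5, 3))
  expect_equal(recurrent_genes(calls), c("BEM3", "NRP1", "BEM2"))
  expect_false("SYN1" %in% rec$gene)
  # single line: every mutated gene counted once, none recurrent at 3
  one <- tibble::tibble(strain = "L1", gene = c("A", "B"), effect = "missense")
  expect_equal(recurrence(one)$n_lines, c(1, 1))
  expect_length(recurrent_genes(one), 0)
})

test_that("end-to-end: ancestor comparison plus classification per line", {
  anc <- dplyr::filter(toy$variants, strain == "ancestor") |>
    dplyr::select(-strain)
  calls <- dplyr::bind_rows(lapply(c("A1", "A2", "A3"), function(s) {
    ev <- dplyr::filter(toy$variants, strain == s)
    classify_variants(ancestor_delta(ev, anc), toy$genome, toy$annotation)
  }))
  # ancestor background variants never survive the delta
  expect_false(any(calls$pos %in% anc$pos))
  rec <- recurrence(calls, min_lines = 2)
  expect_true("BEM3" %in% rec$gene[rec$recurrent]) # Q61* in all three lines
  expect_equal(rec$n_lines[rec$gene == "BEM3"], 3)
  q61 <- dplyr::filter(calls, gene == "BEM3", effect == "nonsense")
  expect_true(all(q61$aa_change == "Q61*"))
})
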