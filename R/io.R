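# Readers and writers for the plain-text interchange formats the pipeline
# uses: FASTA genomes (via Biostrings), GFF-like annotation TSV, VCF-like
# variant tables, landscape CSV, and JSON ground-truth sidecars.

#' Write and read the toy genome as FASTA
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param path Output FASTA path.
#' @return `write_genome_fasta` returns `path` invisibly;
#'   `read_genome_fasta` returns a `DNAStringSet`.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(genome, path)
  invisible(path)
}

#' @rdname write_genome_fasta
#' @export
read_genome_fasta <- function(path) {
  Biostrings::readDNAStringSet(path)
}

#' Read a variant table (minimal VCF or TSV dialect)
#'
#' Accepts either a minimal VCF (`#CHROM POS ID REF ALT ...` header; only
#' CHROM/POS/REF/ALT are used) or the package's TSV dialect with columns
#' `chrom`, `pos`, `ref`, `alt` and optionally `strain`.
#'
#' @param path Input path.
#' @param strain Optional strain name to attach to every record.
#' @return A tibble with columns `chrom`, `pos`, `ref`, `alt` (+ `strain`).
#' @export
read_variants <- function(path, strain = NULL) {
  first <- readLines(path, n = 50L)
  is_vcf <- any(grepl("^#CHROM", first)) || any(grepl("^##fileformat=VCF", first))
  d <- if (is_vcf) {
    raw <- utils::read.table(path, sep = "\t", comment.char = "#",
                             col.names = c("CHROM", "POS", "ID", "REF", "ALT",
                                           "QUAL", "FILTER", "INFO")[1:8],
                             fill = TRUE, stringsAsFactors = FALSE)
    tibble(chrom = as.character(raw$CHROM), pos = as.integer(raw$POS),
           ref = raw$REF, alt = raw$ALT)
  } else {
    as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  }
  if (!is.null(strain)) d$strain <- strain
  d
}

#' Write a variant table as TSV
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`
#'   (+ optional `strain`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(variants, path) {
  utils::write.table(variants, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write the 6-column annotation TSV
#'
#' Columns: `chrom`, `start`, `end`, `strand`, `feature`, `gene`, with
#' 1-based inclusive coordinates.
#'
#' @param annotation Annotation tibble.
#' @param path File path.
#' @return The annotation tibble / the path, respectively.
#' @export
read_annotation_tsv <- function(path) {
  as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @rdname read_annotation_tsv
#' @export
write_annotation_tsv <- function(annotation, path) {
  utils::write.table(annotation, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read/write a fitness landscape as CSV
#'
#' One row per genotype with columns `genotype` (bit-string), `rate`, `se`,
#' `n_reps`; locus names are stored in a `# loci:` comment line.
#'
#' @param landscape A [fitness_landscape()].
#' @param path File path.
#' @return The landscape / the path, respectively.
#' @export
write_landscape_csv <- function(landscape, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# loci: ", paste(landscape_loci(landscape), collapse = ",")),
             con)
  utils::write.csv(as.data.frame(landscape), con, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname write_landscape_csv
#' @export
read_landscape_csv <- function(path) {
  header <- readLines(path, n = 1L)
  loci <- strsplit(sub("^# loci: ", "", header), ",")[[1]]
  d <- utils::read.csv(path, comment.char = "#",
                       colClasses = c(genotype = "character"))
  fitness_landscape(d, loci = loci)
}
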