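# Deterministic readers/writers for the standard formats the pipeline
# consumes and emits. Sequence formats go through Biostrings; tables are
# plain TSV.

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read a FASTA file
#'
#' @param path input file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write reads to FASTQ (Phred+33)
#'
#' Qualities are constant (`quality_char`), matching the simulator's
#' error-free read model; output is byte-deterministic.
#'
#' @param reads named character vector of read sequences.
#' @param path output file.
#' @param quality_char single quality character applied to every base.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  stopifnot(is.character(reads), !is.null(names(reads)))
  dna <- Biostrings::DNAStringSet(reads)
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads)))
  Biostrings::writeXStringSet(dna, path, format = "fastq", qualities = qual)
  invisible(path)
}

#' Read a FASTQ file
#'
#' @param path input file.
#' @return Named character vector of read sequences.
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  stats::setNames(as.character(x), names(x))
}

#' Write a reference set to FASTA files
#'
#' One file per category (`<category>.fa`) under `dir`.
#'
#' @param ref_set a [build_reference_set()] object.
#' @param dir output directory (created if missing).
#' @return Named character vector of written paths, invisibly.
#' @export
write_reference_fasta <- function(ref_set, dir) {
  stopifnot(inherits(ref_set, "reference_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cats <- unique(ref_set$entries$category)
  paths <- vapply(cats, function(cc) {
    e <- ref_set$entries[ref_set$entries$category == cc, ]
    p <- file.path(dir, paste0(cc, ".fa"))
    write_fasta(stats::setNames(e$sequence, e$seq_id), p)
    p
  }, character(1))
  invisible(paths)
}

#' Write a TSV table
#'
#' @param x a data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a TSV table
#'
#' @param path input file.
#' @return A data frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write the terminator annotation table
#'
#' TSV with `gene_id`, 0-based `offset`, `length` and `t_class` of each
#' gene's T1 terminator.
#'
#' @param genes a `trna_gene_set` (or anything accepted by
#'   [annotate_terminators()]).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_terminator_table <- function(genes, path) {
  write_tsv(annotate_terminators(genes), path)
}

#' Export a count matrix to TSV
#'
#' Writes `<prefix>_raw.tsv` and `<prefix>_cpm.tsv` with rows
#' `gene_id:class` and one column per sample — the layout expected by
#' external differential-expression tools.
#'
#' @param x a `trf_counts` object.
#' @param prefix output path prefix.
#' @return The two paths, invisibly.
#' @export
write_count_matrix <- function(x, prefix) {
  stopifnot(inherits(x, "trf_counts"))
  out <- c(paste0(prefix, "_raw.tsv"), paste0(prefix, "_cpm.tsv"))
  for (i in 1:2) {
    m <- if (i == 1L) x$raw else x$cpm
    df <- data.frame(locus = rownames(m), x$loci, m,
                     check.names = FALSE, stringsAsFactors = FALSE)
    write_tsv(df, out[i])
  }
  invisible(out)
}
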