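# Small fixtures built in code.

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(n_genes = 12L, reads_per_sample = 3000,
                   n_mirnas = 30L, seed = 11L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

tiny_genes <- function(...) simulate_trna_genes(tiny_config(...))

# A trf_counts object with exactly the given CPM matrix (for filter /
# MA / biomarker semantics tests where precise CPM values matter).
make_counts <- function(cpm, groups) {
  if (is.null(colnames(cpm))) colnames(cpm) <- names(groups)
  raw <- round(cpm)  # raw values are irrelevant for these tests
  ids <- rownames(cpm) %||% character()
  parts <- strsplit(ids, ":", fixed = TRUE)
  obj <- list(
    raw = raw,
    cpm = cpm,
    loci = data.frame(gene_id = vapply(parts, `[`, "", 1L),
                      trf_class = vapply(parts, `[`, "", 2L),
                      row.names = ids, stringsAsFactors = FALSE),
    samples = data.frame(sample = colnames(cpm),
                         group = unname(groups[colnames(cpm)]),
                         stringsAsFactors = FALSE)
  )
  class(obj) <- "trf_counts"
  obj
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Synthetic exon-14..17 transcript pair around the given primers, with a
# spliced-out middle exon of length `exon_len`; total amplicon with the
# exon present is `amplicon_with` bp.
make_splice_transcripts <- function(fwd, rev, exon_len = 163L,
                                    amplicon_with = 485L, seed = 99L) {
  withr_seed <- function(code) {
    old <- if (exists(".Random.seed", .GlobalEnv)) .GlobalEnv$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed); code
  }
  withr_seed({
    rand <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                     replace = TRUE), collapse = "")
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(rev)))
    filler <- amplicon_with - nchar(fwd) - nchar(rev) - exon_len
    x1 <- rand(floor(filler / 2))
    x2 <- rand(ceiling(filler / 2))
    exon15 <- rand(exon_len)
    list(
      with_exon = paste0(rand(30), fwd, x1, exon15, x2, rc, rand(30)),
      skipped = paste0(rand(30), fwd, x1, x2, rc, rand(30)),
      exon_len = exon_len
    )
  })
}
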