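test_that("terminator scanner handles the canonical cases", {
  t1 <- find_t1_terminator("AATTTTGA")
  expect_equal(t1$offset, 2L)
  expect_equal(t1$length, 4L)
  expect_equal(t1$t_class, "fourT")
  t2 <- find_t1_terminator("GTTTTTC")
  expect_equal(t2$offset, 1L)
  expect_equal(t2$length, 5L)
  expect_equal(t2$t_class, "fivePlusT")
  # a 3-T run is skipped: the first run of >= 4 starts at offset 4
  t3 <- find_t1_terminator("TTTATTTT")
  expect_equal(t3$offset, 4L)
  expect_equal(t3$length, 4L)
  # empty input is found = FALSE, not an error
  expect_false(find_t1_terminator("")$found)
  expect_false(find_t1_terminator("ACGTTTACG")$found)
})

test_that("terminator scanner agrees with the brute-force oracle on random sequences", {
  set.seed(404)
  for (i in 1:1000) {
    s <- paste(sample(c("A", "C", "G", "T"), 150, replace = TRUE,
                      prob = c(0.2, 0.2, 0.2, 0.4)), collapse = "")
    got <- find_t1_terminator(s)
    want <- oracle_t1(s)
    expect_equal(got$found, want$found)
    expect_equal(got$offset, want$offset)
    expect_equal(got$length, want$length)
  }
})

test_that("mature tRNA construction removes introns and appends CCA", {
  genes <- tiny_genes(n_genes = 30, frac_intron = 0.5, seed = 17)
  mature <- build_mature_trna(genes)
  ilen <- ifelse(is.na(genes$intron_start), 0L,
                 genes$intron_end - genes$intron_start)
  expect_equal(unname(nchar(mature)), nchar(genes$genomic_seq) - ilen + 3L)
  expect_true(all(substring(mature, nchar(mature) - 2L) == "CCA"))
  # excised sequence equals the concatenation of the two exon slices
  for (i in which(!is.na(genes$intron_start))) {
    s <- genes$genomic_seq[i]
    want <- paste0(substr(s, 1, genes$intron_start[i]),
                   substr(s, genes$intron_end[i] + 1, nchar(s)), "CCA")
    expect_identical(unname(mature[i]), want)
  }
  # round trip: re-inserting the intron reproduces the genomic body
  for (i in which(!is.na(genes$intron_start))) {
    m <- sub("CCA$", "", mature[i])
    intron <- substr(genes$genomic_seq[i], genes$intron_start[i] + 1,
                     genes$intron_end[i])
    rebuilt <- paste0(substr(m, 1, genes$intron_start[i]), intron,
                      substr(m, genes$intron_start[i] + 1, nchar(m)))
    expect_identical(rebuilt, genes$genomic_seq[i])
  }
})

test_that("pre-tRNA records are body plus downstream with consistent coordinates", {
  genes <- tiny_genes(n_genes = 10, seed = 23)
  pre <- build_pre_trna_ref(genes)
  expect_equal(unname(nchar(pre)), nchar(genes$genomic_seq) + 150L)
  expect_identical(substr(pre, 1, nchar(genes$genomic_seq)),
                   stats::setNames(genes$genomic_seq, genes$gene_id))
  # terminator offset within the full record = body length + window offset
  ann <- annotate_terminators(genes)
  for (i in seq_len(nrow(genes))) {
    full <- find_t1_terminator(substr(pre[i], nchar(genes$genomic_seq[i]) + 1,
                                      nchar(pre[i])))
    expect_equal(full$offset, ann$offset[i])
  }
})

test_that("tRF window records have the defining sizes and are substrings", {
  genes <- tiny_genes(n_genes = 25, frac_intron = 0.3, seed = 29)
  w <- build_trf_refs(genes)
  mature <- build_mature_trna(genes)
  expect_equal(unique(nchar(w$trf5)), 35L)
  expect_equal(unique(nchar(w$trf3)), 30L)
  expect_equal(unique(nchar(w$trf1)), 150L)
  expect_true(all(substring(w$trf3, 28) == "CCA"))
  expect_identical(unname(w$trf5), unname(substr(mature, 1, 35)))
  expect_identical(unname(w$trf3),
                   unname(substring(mature, nchar(mature) - 29L)))
  expect_identical(unname(w$trf1), genes$downstream)
  # windows overlap iff the mature tRNA is shorter than 65 nt
  expect_true(all((nchar(mature) < 65L) == (35L + 30L > nchar(mature))))
})

test_that("half references split at the rounded-up midpoint and conserve sequence", {
  seqs <- c(a = strrep("ACGT", 25), b = paste0(strrep("AC", 50), "G"))
  halves <- build_half_refs(seqs)
  expect_equal(nchar(halves[["a|5half"]]), 50L)
  expect_equal(nchar(halves[["a|3half"]]), 50L)
  expect_equal(nchar(halves[["b|5half"]]), 51L)
  expect_equal(nchar(halves[["b|3half"]]), 50L)
  expect_identical(paste0(halves[["a|5half"]], halves[["a|3half"]]),
                   unname(seqs["a"]))
  expect_identical(paste0(halves[["b|5half"]], halves[["b|3half"]]),
                   unname(seqs["b"]))
})

test_that("reference sets are ordered, unique and carry gene metadata", {
  genes <- tiny_genes(n_genes = 6, seed = 37)
  mir <- simulate_mirnas(5, seed = 1)
  nc <- simulate_ncrnas(4, seed = 2)
  ref1 <- build_reference_set(genes, mir, nc, set = 1)
  expect_equal(ref1$set_kind, "set1_cascade")
  expect_equal(sort(unique(ref1$entries$stage)), 1:3)
  expect_equal(anyDuplicated(ref1$entries$seq_id), 0L)
  expect_true(all(nchar(ref1$entries$sequence) > 0))
  ref2 <- build_reference_set(genes, mir, set = 2,
                              half_ncrnas = simulate_ncrnas(3,
                                downstream = TRUE, seed = 9))
  expect_equal(ref2$set_kind, "set2_concatenated")
  expect_equal(unique(ref2$entries$stage), 1L)
  expect_true(all(c("tRF5", "tRF3", "tRF1", "ncRNA_half") %in%
                    ref2$entries$category))
})

test_that("in-silico RT-PCR sizes amplicons and flags bad primer geometry", {
  fwd <- "TATCCGCACTGGGCATGATG"
  rev <- "TGTGACTGCTGGCTTCTGTT"
  tx <- make_splice_transcripts(fwd, rev)
  expect_equal(insilico_rt_pcr(tx$with_exon, fwd, rev), 485L)
  expect_equal(insilico_rt_pcr(tx$skipped, fwd, rev), 322L)
  # missing reverse site -> none
  no_rev <- paste0("AAAA", fwd, strrep("AC", 40))
  expect_true(is.na(insilico_rt_pcr(no_rev, fwd, rev)))
  # wrong orientation -> none
  rc_rev <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(rev)))
  flipped <- paste0("GG", rc_rev, strrep("A", 30), fwd, "GG")
  expect_true(is.na(insilico_rt_pcr(flipped, fwd, rev)))
  # multiple forward sites -> error naming the primer
  doubled <- paste0(fwd, "AAAA", tx$with_exon)
  expect_error(insilico_rt_pcr(doubled, fwd, rev), "forward primer")
  expect_error(insilico_rt_pcr(tx$with_exon, "ACGTACGTAC", rev), "15 nt")
})

test_that("amplicon difference equals the skipped exon length for any transcript pair", {
  fwd <- "TATCCGCACTGGGCATGATG"
  rev <- "TGTGACTGCTGGCTTCTGTT"
  for (seed in 1:5) {
    exon_len <- sample(50:400, 1)
    tx <- make_splice_transcripts(fwd, rev, exon_len = exon_len,
                                  amplicon_with = 480 + exon_len,
                                  seed = seed)
    a <- insilico_rt_pcr(tx$with_exon, fwd, rev)
    b <- insilico_rt_pcr(tx$skipped, fwd, rev)
    expect_equal(a - b, exon_len)
  }
})
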