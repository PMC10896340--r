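test_that("length filter keeps reads at and above the cutoff", {
  reads <- stats::setNames(strrep("A", 15:22), paste0("r", 15:22))
  kept <- length_filter(reads)  # default 18
  expect_equal(unname(nchar(kept)), 18:22)
  expect_identical(length_filter(reads, 1L), reads)
  # oracle: brute-force count
  set.seed(1)
  rnd <- stats::setNames(strrep("C", sample(15:50, 200, TRUE)),
                         paste0("x", 1:200))
  for (ml in c(1L, 18L, 30L)) {
    expect_equal(length(length_filter(rnd, ml)),
                 sum(nchar(rnd) >= ml))
  }
})

test_that("exact, mismatched and antisense reads map per the contract", {
  genes <- tiny_genes(n_genes = 6, seed = 41)
  ref <- build_reference_set(genes, simulate_mirnas(5, seed = 1), set = 1)
  body <- genes$genomic_seq[3]
  read <- substr(body, 11, 30)  # exact 20-mer
  res <- map_stage(c(q = read), ref, stage = 2, max_mismatch = 2)
  expect_equal(nrow(res$records), 1L)
  expect_equal(res$records$mismatches, 0L)
  expect_equal(res$records$ref_start, 10L)
  expect_equal(res$records$strand, "+")
  # two substitutions still map, with the count reported
  mut <- read
  for (p in c(4L, 15L)) {
    substr(mut, p, p) <- setdiff(c("A", "C", "G", "T"),
                                 substr(mut, p, p))[1]
  }
  res2 <- map_stage(c(q = mut), ref, stage = 2, max_mismatch = 2)
  expect_equal(res2$records$mismatches, 2L)
  expect_equal(res2$records$ref_start, 10L)
  # three substitutions exceed the tolerance
  mut3 <- mut
  substr(mut3, 9L, 9L) <- setdiff(c("A", "C", "G", "T"),
                                  substr(mut3, 9L, 9L))[1]
  res3 <- map_stage(c(q = mut3), ref, stage = 2, max_mismatch = 2)
  expect_equal(nrow(res3$records), 0L)
  expect_equal(length(res3$unmapped), 1L)
  # antisense occurrence is found and recorded on the minus strand
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  resa <- map_stage(c(q = rc), ref, stage = 2, max_mismatch = 2)
  expect_equal(resa$records$strand, "-")
  expect_equal(resa$records$ref_start, 10L)
})

test_that("multi-mapping ties break to the lexicographically first record", {
  shared <- "AAGGCTTACGGATCCATGGCAATC"  # 24 nt, not self-reverse-complementary
  genes <- tiny_genes(n_genes = 3, seed = 43, frac_intron = 0)
  # plant the shared 24-mer into two mature bodies
  genes$genomic_seq[1] <- paste0(shared, substr(genes$genomic_seq[1], 25, 80))
  genes$genomic_seq[2] <- paste0(substr(genes$genomic_seq[2], 1, 30),
                                 shared,
                                 substr(genes$genomic_seq[2], 55, 85))
  ref <- build_reference_set(genes, set = 1)
  res <- map_stage(c(q = shared), ref, stage = 2, max_mismatch = 0)
  oracle <- oracle_scan_read(shared, ref, stage = 2, max_mismatch = 0)
  expect_equal(res$records$ref_id, oracle$best$ref_id)
  expect_equal(res$records$ref_start, oracle$best$pos)
  expect_gte(res$records$n_alt, 1L)  # flagged multi-hit
  expect_equal(res$records$n_alt, oracle$n_hits - 1L)
})

test_that("mapper agrees with the exhaustive scan oracle on random reads", {
  genes <- tiny_genes(n_genes = 4, seed = 47)
  ref <- build_reference_set(genes, simulate_mirnas(4, seed = 3), set = 1)
  set.seed(48)
  for (i in 1:40) {
    src <- sample(nrow(genes), 1)
    st <- sample(0:40, 1)
    w <- sample(18:30, 1)
    read <- substr(build_pre_trna_ref(genes)[src], st + 1, st + w)
    nmut <- sample(0:2, 1)
    for (p in sample(w, nmut)) {
      substr(read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(read, p, p))[1]
    }
    res <- map_stage(stats::setNames(read, "q"), ref, stage = 3,
                     max_mismatch = 2)
    oracle <- oracle_scan_read(read, ref, stage = 3, max_mismatch = 2)
    if (is.null(oracle)) {
      expect_equal(nrow(res$records), 0L)
    } else {
      expect_equal(res$records$ref_id, oracle$best$ref_id)
      expect_equal(res$records$ref_start, oracle$best$pos)
      expect_equal(res$records$mismatches, oracle$best$mism)
      expect_equal(res$records$strand, oracle$best$strand)
    }
  }
})

test_that("cascade counts each read once, at its first explaining stage", {
  genes <- tiny_genes(n_genes = 8, seed = 51)
  mir <- simulate_mirnas(10, seed = 4)
  # a read matching both stage 1 (miRNA) and stage 3 (planted into a
  # downstream window) must be counted at stage 1 only
  genes$downstream[2] <- paste0(mir$sequence[1],
                                substr(genes$downstream[2],
                                       nchar(mir$sequence[1]) + 1, 150))
  ref <- build_reference_set(genes, mir, set = 1)
  cas <- run_cascade(stats::setNames(mir$sequence[1], "amb"), ref,
                     min_len = 1L)
  expect_equal(nrow(cas$records), 1L)
  expect_equal(cas$records$stage, 1L)
  expect_equal(cas$records$category, "miRNA")
  # permuting stage order changes the assignment of the ambiguous read
  ref_perm <- ref
  ref_perm$entries$stage <- c(3L, 1L, 2L)[ref$entries$stage]
  ref_perm$entries <- ref_perm$entries[order(ref_perm$entries$stage), ]
  ref_perm$cache <- new.env(parent = emptyenv())
  cas_p <- run_cascade(stats::setNames(mir$sequence[1], "amb"), ref_perm,
                       min_len = 1L)
  expect_equal(cas_p$records$category, "pre_tRNA")
})

test_that("cascade conserves reads and degenerates to map_stage for one stage", {
  genes <- tiny_genes(n_genes = 10, seed = 53)
  mir <- simulate_mirnas(15, seed = 5)
  cfg <- tiny_config(n_genes = 10, seed = 53, reads_per_sample = 2000)
  rs <- simulate_reads(genes, mir, cfg)
  ref <- build_reference_set(genes, mir, set = 1)
  cas <- run_cascade(rs$reads$S1, ref)
  expect_equal(sum(cas$report$n_mapped) + length(cas$unmapped),
               cas$n_filtered)
  expect_equal(cas$report$n_in[-1], cas$report$n_out[-nrow(cas$report)])
  expect_equal(anyDuplicated(cas$records$read_id), 0L)
  # single-stage cascade == map_stage on the filtered reads
  ref2 <- build_reference_set(genes, mir, set = 2)
  kept <- length_filter(rs$reads$S1)
  cas2 <- run_cascade(rs$reads$S1, ref2)
  ms <- map_stage(kept, ref2, stage = 1)
  expect_equal(cas2$records[names(cas2$records) != "stage"],
               ms$records[names(ms$records) != "stage"])
  # empty read set gives an all-zero report
  cas0 <- run_cascade(character(), ref)
  expect_equal(sum(cas0$report$n_in), 0L)
  expect_equal(nrow(cas0$records), 0L)
})

test_that("reads with simulated sequencing errors still map within tolerance", {
  genes <- tiny_genes(n_genes = 6, seed = 57)
  mir <- simulate_mirnas(8, seed = 6)
  cfg <- tiny_config(n_genes = 6, seed = 57, reads_per_sample = 800,
                     error_rate = 0.01)
  rs <- simulate_reads(genes, mir, cfg)
  ref <- build_reference_set(genes, mir, set = 1)
  cas <- run_cascade(rs$reads$S1, ref)
  # at 1% per-base error nearly all reads carry <= 2 substitutions
  expect_gt(sum(cas$report$n_mapped) / cas$n_filtered, 0.99)
  expect_gt(sum(cas$records$mismatches > 0), 0)
})
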