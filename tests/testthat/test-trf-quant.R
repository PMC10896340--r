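# Shared small experiment for classification tests.
quant_fixture <- function() {
  genes <- tiny_genes(n_genes = 8, seed = 61, frac_intron = 0.25)
  mir <- simulate_mirnas(10, seed = 7)
  cfg <- tiny_config(n_genes = 8, seed = 61, reads_per_sample = 2500)
  rs <- simulate_reads(genes, mir, cfg)
  ref <- build_reference_set(genes, mir, set = 1)
  cas <- run_cascade(rs$reads$S1, ref)
  list(genes = genes, mir = mir, rs = rs, ref = ref, cas = cas,
       term = annotate_terminators(genes))
}

test_that("position on set-1 references defines the tRF class", {
  fx <- quant_fixture()
  asn <- assign_classes(fx$cas, fx$ref, terminators = fx$term)
  tr <- fx$rs$truth
  m <- merge(asn, tr, by = "read_id")
  expect_true(all(m$trf_class == m$class))
  # a read inside the downstream window is a tRF-1 by definition
  pre_id <- paste0(fx$genes$gene_id[1], "|pre")
  body <- nchar(fx$genes$genomic_seq[1])
  rec <- data.frame(read_id = "w", stage = 3L, category = "pre_tRNA",
                    ref_id = pre_id, ref_start = body, ref_end = body + 22L,
                    strand = "+", mismatches = 0L, n_alt = 0L,
                    primary = TRUE, stringsAsFactors = FALSE)
  expect_equal(assign_classes(rec, fx$ref)$trf_class, "tRF1")
  # a read straddling the body/downstream junction is pre_other
  rec$ref_start <- body - 5L
  rec$ref_end <- body + 17L
  expect_equal(assign_classes(rec, fx$ref)$trf_class, "pre_other")
  # mature-reference positions: start 0 -> tRF5; 3'-end -> tRF3; else other
  mat_id <- paste0(fx$genes$gene_id[1], "|mature")
  mlen <- nchar(build_mature_trna(fx$genes))[1]
  mk <- function(s, e) data.frame(read_id = "m", stage = 2L,
                                  category = "mature_tRNA", ref_id = mat_id,
                                  ref_start = s, ref_end = e, strand = "+",
                                  mismatches = 0L, n_alt = 0L, primary = TRUE,
                                  stringsAsFactors = FALSE)
  expect_equal(assign_classes(mk(0L, 25L), fx$ref)$trf_class, "tRF5")
  expect_equal(assign_classes(mk(2L, 27L), fx$ref)$trf_class, "tRF5")
  expect_equal(assign_classes(mk(mlen - 20L, mlen), fx$ref)$trf_class, "tRF3")
  expect_equal(assign_classes(mk(10L, 40L), fx$ref)$trf_class,
               "mature_other")
  # unknown reference id is an error
  rec$ref_id <- "nonsense|pre"
  expect_error(assign_classes(rec, fx$ref), "unknown ref_id")
})

test_that("readthrough requires the 3' end strictly beyond the terminator", {
  t1 <- list(offset = 20L, length = 4L, found = TRUE)
  expect_false(call_readthrough(23L, t1))
  expect_false(call_readthrough(24L, t1))  # boundary: ends at the last T
  expect_true(call_readthrough(25L, t1))
  expect_true(call_readthrough(30L, t1))
  expect_true(is.na(call_readthrough(30L, list(found = FALSE))))
})

test_that("CPM normalization matches the brute-force definition", {
  asn <- data.frame(
    read_id = sprintf("r%d", 1:4),
    gene_id = c("g1", "g2", "g3", "g4"),
    trf_class = c("tRF1", "tRF3", "tRF5", "miRNA"),
    readthrough = NA, read_length = 20L,
    sample = "S1", stringsAsFactors = FALSE
  )
  cm <- count_and_normalize(asn)
  expect_equal(unname(cm$cpm[, "S1"]), rep(250000, 4))
  expect_equal(sum(cm$cpm[, "S1"]), 1e6)
  # doubling all counts leaves CPM unchanged
  cm2 <- count_and_normalize(rbind(asn,
    transform(asn, read_id = paste0(read_id, "b"))))
  expect_equal(cm2$raw, cm$raw * 2L)
  expect_equal(cm2$cpm, cm$cpm)
  # brute-force per-cell check on a random table
  set.seed(9)
  big <- data.frame(
    read_id = sprintf("r%04d", 1:600),
    gene_id = sample(paste0("g", 1:6), 600, TRUE),
    trf_class = sample(c("tRF1", "tRF3", "tRF5"), 600, TRUE),
    readthrough = NA, read_length = 20L,
    sample = sample(c("A", "B"), 600, TRUE), stringsAsFactors = FALSE
  )
  cmx <- count_and_normalize(big)
  for (s in c("A", "B")) {
    tot <- sum(big$sample == s)
    for (k in sample(rownames(cmx$raw), 5)) {
      parts <- strsplit(k, ":")[[1]]
      n <- sum(big$sample == s & big$gene_id == parts[1] &
                 big$trf_class == parts[2])
      expect_equal(cmx$raw[k, s], n)
      expect_equal(cmx$cpm[k, s], n / tot * 1e6)
    }
  }
  # a declared sample with zero reads is an error naming it
  expect_error(count_and_normalize(asn, groups = c(S1 = "WT", S9 = "WT")),
               "S9")
})

test_that("percentile filter retains rows by interpolated 75th percentile", {
  cpm <- rbind(
    "g1:tRF1" = c(25, 25, 25),
    "g2:tRF1" = c(19, 19, 19),
    "g3:tRF1" = c(0, 0, 100)
  )
  colnames(cpm) <- paste0("S", 1:3)
  x <- make_counts(cpm, c(S1 = "a", S2 = "a", S3 = "b"))
  kept <- percentile_filter(x)
  expect_setequal(rownames(kept$cpm), c("g1:tRF1", "g3:tRF1"))
  # the asymmetric-retention case: {0,0,0,100} has 75th percentile 25
  cpm4 <- rbind("g4:tRF1" = c(0, 0, 0, 100))
  colnames(cpm4) <- paste0("S", 1:4)
  expect_equal(unname(stats::quantile(cpm4[1, ], 0.75)), 25)
  x4 <- make_counts(cpm4, stats::setNames(rep("a", 4), paste0("S", 1:4)))
  expect_equal(nrow(percentile_filter(x4)$cpm), 1L)
  # idempotence and monotonicity
  expect_equal(percentile_filter(percentile_filter(x))$cpm,
               percentile_filter(x)$cpm)
  for (thr in c(5, 20, 26, 200)) {
    expect_lte(nrow(percentile_filter(x, thr)$cpm),
               nrow(percentile_filter(x, thr - 1)$cpm))
  }
  expect_error(percentile_filter(make_counts(cpm[, 1, drop = FALSE],
                                             c(S1 = "a"))),
               "2 samples")
})

test_that("MA statistics apply the mean-CPM cutoff and are antisymmetric", {
  cpm <- rbind(
    "g1:tRF1" = c(100, 100, 400, 400),
    "g2:tRF1" = c(49, 49, 49, 49),
    "g3:tRF1" = c(60, 60, 60, 60)
  )
  colnames(cpm) <- paste0("S", 1:4)
  x <- make_counts(cpm, c(S1 = "A", S2 = "A", S3 = "B", S4 = "B"))
  ma <- ma_statistics(x, "A", "B")
  expect_setequal(ma$locus, c("g1:tRF1", "g3:tRF1"))  # 49 CPM excluded
  expect_equal(ma$log2fc[ma$locus == "g3:tRF1"], 0)
  expect_equal(ma$log2fc[ma$locus == "g1:tRF1"],
               log2(400.5 / 100.5))
  expect_equal(ma$mean_log10_cpm[ma$locus == "g1:tRF1"], log10(250))
  flipped <- ma_statistics(x, "B", "A")
  expect_equal(flipped$log2fc, -ma$log2fc)
  expect_error(ma_statistics(x, "A", "nope"), "unknown group")
})

test_that("length distribution and coverage conserve read counts", {
  fx <- quant_fixture()
  asn <- assign_classes(fx$cas, fx$ref, terminators = fx$term)
  h <- length_distribution(asn)
  expect_equal(sum(h), nrow(asn))
  expect_equal(unname(colSums(h)),
               as.numeric(table(asn$trf_class)[colnames(h)]))
  expect_equal(unname(rowSums(h)[as.character(15:17)]), c(0L, 0L, 0L))
  one <- asn[1, ]
  h1 <- length_distribution(one)
  expect_equal(sum(h1 > 0), 1L)
  expect_equal(h1[as.character(one$read_length), one$trf_class], 1L)
  # coverage: single and stacked reads, and total conservation
  pre_id <- paste0(fx$genes$gene_id[2], "|pre")
  body <- nchar(fx$genes$genomic_seq[2])
  rec <- data.frame(read_id = c("a", "b", "b2"), stage = 3L,
                    category = "pre_tRNA", ref_id = pre_id,
                    ref_start = c(5L, 40L, 40L), ref_end = c(25L, 60L, 60L),
                    strand = "+", mismatches = 0L, n_alt = 0L,
                    primary = TRUE, stringsAsFactors = FALSE)
  cov <- coverage_map(rec, fx$ref, pre_id)
  expect_equal(cov$coverage[cov$pos %in% 5:24],
               rep(1L, 20))
  expect_equal(cov$coverage[cov$pos %in% 40:59], rep(2L, 20))
  expect_equal(sum(cov$coverage), sum(rec$ref_end - rec$ref_start))
  expect_equal(sum(cov$starts), 3L)
  expect_equal(unique(cov$region[cov$pos < body]), "body")
  expect_equal(unique(cov$region[cov$pos >= body]), "downstream")
})

test_that("per-class CPM fractions recover the configured class weights", {
  genes <- tiny_genes(n_genes = 15, seed = 67)
  mir <- simulate_mirnas(20, seed = 8)
  cfg <- tiny_config(n_genes = 15, seed = 67, reads_per_sample = 30000)
  rs <- simulate_reads(genes, mir, cfg)
  ref <- build_reference_set(genes, mir, set = 2)
  cm <- quantify_samples(rs$reads, ref,
                         terminators = annotate_terminators(genes))
  frac <- tapply(cm$cpm[, 1], cm$loci$trf_class, sum) / 1e6
  # the 18-nt filter trims more of the short tRF classes than of
  # miRNAs, so compare against the post-filter ground truth
  tr <- rs$truth[rs$truth$read_id %in%
                   names(length_filter(rs$reads$S1)), ]
  want <- table(tr$class) / nrow(tr)
  for (cls in names(want)) {
    expect_lt(abs(frac[[cls]] - want[[cls]]), 0.01)
  }
})
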