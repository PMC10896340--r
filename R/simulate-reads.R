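#' Simulate class-structured small-RNA reads with ground truth
#'
#' Draws reads per (locus, class) from negative-binomial locus
#' abundances scaled by the configured condition profile:
#' * tRF-5 reads start at mature-tRNA position 0 (lengths 15-35 nt,
#'   clipped to the configured read-length range);
#' * tRF-3 reads end at the CCA 3' end of the mature tRNA (15-30 nt);
#' * tRF-1 reads start at position 0 of the downstream window
#'   (immediately after the discriminator) and end within the T1
#'   terminator tract or, for a `readthrough_frac` fraction, beyond it;
#' * miRNA reads are the full mature miRNA.
#'
#' Under `condition = "deficient"` tRF-1 abundances are multiplied by
#' `trf1_enrichment` while tRF-5/tRF-3 are deflated; under
#' `condition = "la_kd"` tRF-1 is deflated. Reads are error-free unless
#' `error_rate > 0`, qualities are constant, and the output is
#' deterministic under a fixed seed.
#'
#' @param genes a `trna_gene_set` from [simulate_trna_genes()].
#' @param mirnas a `mirna_set` from [simulate_mirnas()].
#' @param config a [sim_config()]; `config$seed` seeds the read draws,
#'   so the same gene set can be re-sequenced under different seeds and
#'   conditions with shared locus abundances.
#' @param n_samples number of replicate samples (libraries) to draw.
#' @param sample_names optional sample names (default `S1`, `S2`, ...).
#' @return A list of class `sim_reads`:
#'   \describe{
#'     \item{reads}{named list, one named character vector of read
#'       sequences per sample.}
#'     \item{truth}{per-read ground truth: `read_id`, `sample`,
#'       `source_id`, `class`, `start`, `end` (0-based half-open on the
#'       source region), `readthrough`.}
#'     \item{locus_expected}{expected (mean) count per sample for every
#'       (locus, class) pair, with the condition factor applied.}
#'     \item{config}{the configuration used.}
#'   }
#' @export
simulate_reads <- function(genes, mirnas, config, n_samples = 1L,
                           sample_names = NULL) {
  stopifnot(inherits(genes, "trna_gene_set"), inherits(config, "sim_config"))
  if (is.null(sample_names)) sample_names <- sprintf("S%d", seq_len(n_samples))
  stopifnot(length(sample_names) == n_samples)

  rmin <- config$read_length_range[1]
  rmax <- config$read_length_range[2]
  mature <- build_mature_trna(genes)
  mlen <- nchar(mature)
  w <- config$class_weights

  fac <- c(tRF5 = 1, tRF3 = 1, tRF1 = 1, miRNA = 1)
  if (config$condition == "deficient") {
    fac <- c(tRF5 = config$trf5_factor, tRF3 = config$trf3_factor,
             tRF1 = config$trf1_enrichment, miRNA = config$mirna_factor)
  } else if (config$condition == "la_kd") {
    fac["tRF1"] <- config$la_kd_trf1_factor
  }

  # class-specific feasible length windows
  l5 <- c(max(15L, rmin), min(35L, rmax))
  l3 <- c(max(15L, rmin), min(30L, rmax))
  if (l5[1] > l5[2]) stopf("read_length_range leaves no feasible tRF-5 length within its 35-nt source window")
  if (l3[1] > l3[2]) stopf("read_length_range leaves no feasible tRF-3 length within its 30-nt source window")
  if (any(mlen < 35L)) stopf("mature tRNA shorter than the 35-nt tRF-5 source window")

  # expected counts per locus x class (same in every replicate sample)
  mu <- cbind(
    tRF5 = config$reads_per_sample * w["tRF5"] * genes$share_tRF5 * fac["tRF5"],
    tRF3 = config$reads_per_sample * w["tRF3"] * genes$share_tRF3 * fac["tRF3"],
    tRF1 = config$reads_per_sample * w["tRF1"] * genes$share_tRF1 * fac["tRF1"]
  )
  mu_mir <- config$reads_per_sample * w["miRNA"] * mirnas$share * fac["miRNA"]

  locus_expected <- rbind(
    data.frame(source_id = rep(genes$gene_id, 3L),
               class = rep(c("tRF5", "tRF3", "tRF1"), each = nrow(genes)),
               expected = c(mu[, "tRF5"], mu[, "tRF3"], mu[, "tRF1"]),
               stringsAsFactors = FALSE),
    data.frame(source_id = mirnas$mirna_id, class = "miRNA",
               expected = mu_mir, stringsAsFactors = FALSE)
  )

  draw <- function(m) {
    if (config$dispersion > 0) {
      stats::rnbinom(length(m), mu = m, size = 1 / config$dispersion)
    } else {
      stats::rpois(length(m), m)
    }
  }

  with_seed(config$seed, {
    reads_by_sample <- vector("list", n_samples)
    names(reads_by_sample) <- sample_names
    truth_list <- list()

    for (s in seq_len(n_samples)) {
      cnt5 <- draw(mu[, "tRF5"]); cnt3 <- draw(mu[, "tRF3"])
      cnt1 <- draw(mu[, "tRF1"]); cntm <- draw(mu_mir)

      truth_df <- function(source_id, class, start, end, readthrough) {
        n <- length(source_id)
        data.frame(source_id = source_id, class = rep_len(class, n),
                   start = rep_len(start, n), end = rep_len(end, n),
                   readthrough = rep_len(readthrough, n),
                   stringsAsFactors = FALSE)
      }
      g5 <- rep(seq_len(nrow(genes)), cnt5)
      len5 <- sample_lengths(length(g5), l5)
      seq5 <- substring(mature[g5], 1L, len5)
      t5 <- truth_df(genes$gene_id[g5], "tRF5", 0L, len5, NA)

      g3 <- rep(seq_len(nrow(genes)), cnt3)
      len3 <- sample_lengths(length(g3), l3)
      seq3 <- substring(mature[g3], mlen[g3] - len3 + 1L, mlen[g3])
      t3 <- truth_df(genes$gene_id[g3], "tRF3", mlen[g3] - len3,
                     mlen[g3], NA)

      g1 <- rep(seq_len(nrow(genes)), cnt1)
      e1 <- trf1_ends(genes$t1_offset[g1], genes$t1_length[g1],
                      config$readthrough_frac, rmax)
      seq1 <- substring(genes$downstream[g1], 1L, e1$end)
      t1 <- truth_df(genes$gene_id[g1], "tRF1", 0L, e1$end,
                     e1$readthrough)

      gm <- rep(seq_len(nrow(mirnas)), cntm)
      seqm <- mirnas$sequence[gm]
      tm <- truth_df(mirnas$mirna_id[gm], "miRNA", 0L, nchar(seqm), NA)

      seqs <- c(seq5, seq3, seq1, seqm)
      truth <- rbind(t5, t3, t1, tm)
      if (config$error_rate > 0 && length(seqs) > 0L) {
        seqs <- mutate_reads(seqs, config$error_rate)
      }
      ids <- sprintf("%s_r%07d", sample_names[s], seq_along(seqs))
      names(seqs) <- ids
      truth <- cbind(read_id = ids, sample = sample_names[s], truth,
                     stringsAsFactors = FALSE)
      reads_by_sample[[s]] <- seqs
      truth_list[[s]] <- truth
    }

    out <- list(reads = reads_by_sample,
                truth = do.call(rbind, truth_list),
                locus_expected = locus_expected,
                config = config)
    rownames(out$truth) <- NULL
    class(out) <- "sim_reads"
    out
  })
}

# Uniform read lengths within a feasible [lo, hi] window.
sample_lengths <- function(n, window) {
  if (n == 0L) return(integer())
  if (window[1] == window[2]) return(rep(window[1], n))
  sample(seq(window[1], window[2]), n, replace = TRUE)
}

# tRF-1 read end positions (1-based end == read length, start fixed at 0).
# Termination within the T tract needs at least 2 terminal Us; a
# readthrough read ends strictly beyond the last T of the terminator.
trf1_ends <- function(t_off, t_len, readthrough_frac, rmax) {
  n <- length(t_off)
  if (n == 0L) return(list(end = integer(), readthrough = logical()))
  term_end <- t_off + t_len
  can_rt <- term_end + 1L <= pmin(150L, rmax)
  rt <- stats::runif(n) < readthrough_frac & can_rt
  lo <- ifelse(rt, term_end + 1L, t_off + 2L)
  hi <- ifelse(rt, pmin(150L, rmax), term_end)
  if (any(hi > rmax)) {
    stopf("a tRF-1 read of %d nt exceeds the maximum read length %d; shorten trailer_length_range",
          max(hi), rmax)
  }
  span <- hi - lo
  end <- lo + ifelse(span > 0L,
                     floor(stats::runif(n) * (span + 1L)),
                     0L)
  list(end = as.integer(pmin(end, hi)), readthrough = rt)
}

# Uniform per-base substitutions at rate p (to a different base).
mutate_reads <- function(seqs, p) {
  lens <- nchar(seqs)
  nmut <- stats::rbinom(length(seqs), lens, p)
  idx <- which(nmut > 0L)
  for (i in idx) {
    pos <- sample.int(lens[i], nmut[i])
    for (p1 in pos) {
      cur <- substr(seqs[i], p1, p1)
      substr(seqs[i], p1, p1) <- sample(setdiff(BASES, cur), 1L)
    }
  }
  seqs
}

#' @export
print.sim_reads <- function(x, ...) {
  n <- vapply(x$reads, length, integer(1))
  cat(sprintf("Simulated small-RNA read set (%s condition)\n",
              x$config$condition))
  cat(sprintf("  %d sample(s): %s reads\n", length(n),
              paste(format(n, big.mark = ","), collapse = ", ")))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$truth$class)),
                            table(x$truth$class)), collapse = " ")))
  invisible(x)
}
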