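#' Simulate tRNA gene models
#'
#' Generates a set of tRNA gene models in the style of a genomic tRNA
#' database record: a genomic body sequence (70-90 nt) with an optional
#' intron (10-25 nt) at the canonical insertion point after body
#' position 37, and a 150-nt downstream window that contains exactly one
#' deliberately placed oligo(T) tract (the T1 terminator) at a known
#' offset, with no other run of 4 or more Ts upstream of it. The planted
#' terminator offset and length are stored per gene as ground truth, and
#' per-gene, per-class baseline abundance shares (log-normal) are drawn
#' so that repeated read simulations over the same gene set share locus
#' abundances.
#'
#' @param config a [sim_config()] object.
#' @return A data frame of class `trna_gene_set` with one row per gene:
#'   `gene_id`, `genomic_seq` (body incl. intron, sense strand),
#'   `intron_start`/`intron_end` (0-based half-open on `genomic_seq`,
#'   `NA` if intronless), `downstream` (exactly 150 nt), `confidence`,
#'   planted `t1_offset` (0-based) and `t1_length`, and baseline
#'   abundance shares `share_tRF5`, `share_tRF3`, `share_tRF1`.
#' @export
#' @examples
#' genes <- simulate_trna_genes(sim_config(n_genes = 5, seed = 7))
#' genes$gene_id
#' nchar(genes$downstream)
simulate_trna_genes <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_genes
  tlr <- config$trailer_length_range
  max_run <- 7L
  if (tlr[2] + max_run > 150L) {
    stopf("trailer offset range [%d, %d] would truncate a T run of up to %d nt beyond position 150",
          tlr[1], tlr[2], max_run)
  }
  with_seed(config$seed, {
    aas <- c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly",
             "His", "Ile", "Leu", "Lys", "Met", "Phe", "Pro", "Ser",
             "Thr", "Trp", "Tyr", "Val")
    aa <- sample(aas, n, replace = TRUE)
    anticodon <- random_dna(n, 3L)
    gene_id <- sprintf("%s%s%d-1", aa, anticodon, seq_len(n))

    body_len <- sample(70:90, n, replace = TRUE)
    has_intron <- stats::runif(n) < config$frac_intron
    intron_len <- ifelse(has_intron, sample(10:25, n, replace = TRUE), 0L)
    is4T <- stats::runif(n) < config$frac_4T
    t1_length <- ifelse(is4T, 4L, sample(5:7, n, replace = TRUE))
    t1_offset <- sample(seq(tlr[1], tlr[2]), n, replace = TRUE)

    genomic <- character(n)
    intron_start <- rep(NA_integer_, n)
    intron_end <- rep(NA_integer_, n)
    downstream <- character(n)
    for (i in seq_len(n)) {
      body <- random_dna(1L, body_len[i])
      if (has_intron[i]) {
        intron <- random_dna(1L, intron_len[i])
        genomic[i] <- paste0(substr(body, 1L, 37L), intron,
                             substr(body, 38L, body_len[i]))
        intron_start[i] <- 37L
        intron_end[i] <- 37L + intron_len[i]
      } else {
        genomic[i] <- body
      }
      downstream[i] <- plant_terminator(t1_offset[i], t1_length[i])
    }

    share <- function() {
      s <- stats::rlnorm(n, meanlog = 0, sdlog = 1)
      s / sum(s)
    }
    genes <- data.frame(
      gene_id = gene_id,
      genomic_seq = genomic,
      intron_start = intron_start,
      intron_end = intron_end,
      downstream = downstream,
      confidence = ifelse(stats::runif(n) < 0.7, "high_confidence", "other"),
      t1_offset = as.integer(t1_offset),
      t1_length = as.integer(t1_length),
      share_tRF5 = share(),
      share_tRF3 = share(),
      share_tRF1 = share(),
      stringsAsFactors = FALSE
    )
    class(genes) <- c("trna_gene_set", "data.frame")
    attr(genes, "config") <- config
    genes
  })
}

# A 150-nt downstream window with a single T run of `len` at 0-based
# `offset`, no >=4T run upstream of it, and non-T flanks so the planted
# run is exactly maximal.
plant_terminator <- function(offset, len) {
  if (offset + len > 150L) {
    stopf("terminator at offset %d with %d Ts would extend beyond the 150-nt window",
          offset, len)
  }
  prefix <- if (offset > 0L) break_t_runs(random_dna(1L, offset)) else ""
  if (offset > 0L && substr(prefix, offset, offset) == "T") {
    substr(prefix, offset, offset) <- sample(c("A", "C", "G"), 1L)
  }
  tail_len <- 150L - offset - len
  suffix <- if (tail_len > 0L) random_dna(1L, tail_len) else ""
  if (tail_len > 0L && substr(suffix, 1L, 1L) == "T") {
    substr(suffix, 1L, 1L) <- sample(c("A", "C", "G"), 1L)
  }
  paste0(prefix, strrep("T", len), suffix)
}

#' Simulate decoy mature miRNAs
#'
#' Random 21-23 nt mature miRNA sequences with log-normal abundance
#' shares, used both as cascade stage-1 references and as background
#' reads.
#'
#' @param n number of miRNAs.
#' @param seed integer RNG seed.
#' @return A data frame of class `mirna_set`: `mirna_id`, `sequence`,
#'   `share`.
#' @export
simulate_mirnas <- function(n = 100L, seed = 1L) {
  with_seed(seed, {
    s <- stats::rlnorm(n, 0, 1)
    out <- data.frame(
      mirna_id = sprintf("mir-%03d", seq_len(n)),
      sequence = random_dna(n, sample(21:23, n, replace = TRUE)),
      share = s / sum(s),
      stringsAsFactors = FALSE
    )
    class(out) <- c("mirna_set", "data.frame")
    out
  })
}

#' Simulate decoy non-coding RNAs
#'
#' Random ncRNA sequences (default 80-120 nt) used as additional
#' stage-1 references; no reads are generated from them by default.
#' A 50-nt downstream extension is appended when `downstream = TRUE`
#' so the sequences can feed [build_half_refs()].
#'
#' @param n number of ncRNAs.
#' @param len_range length range of the ncRNA body.
#' @param downstream append 50 nt of downstream genomic sequence.
#' @param seed integer RNG seed.
#' @return A named character vector of sequences.
#' @export
simulate_ncrnas <- function(n = 20L, len_range = c(80L, 120L),
                            downstream = FALSE, seed = 2L) {
  with_seed(seed, {
    len <- sample(seq(len_range[1], len_range[2]), n, replace = TRUE)
    if (downstream) len <- len + 50L
    out <- random_dna(n, len)
    names(out) <- sprintf("ncRNA-%03d", seq_len(n))
    out
  })
}

#' @export
print.trna_gene_set <- function(x, ...) {
  n4 <- sum(x$t1_length == 4L)
  cat(sprintf("tRNA gene set: %d genes (%d with intron, %d/%d with 4T terminator)\n",
              nrow(x), sum(!is.na(x$intron_start)), n4, nrow(x)))
  cat(sprintf("  body %d-%d nt, downstream windows %d nt\n",
              min(nchar(x$genomic_seq)), max(nchar(x$genomic_seq)),
              unique(nchar(x$downstream))[1]))
  invisible(x)
}
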