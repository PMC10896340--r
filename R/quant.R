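#' Classify mapped reads into tRF classes
#'
#' For a set-2 (concatenated window) reference, the owning reference
#' category defines the class directly. For set-1, position defines it:
#' a read on a pre-tRNA record starting at or after the end of the
#' genomic body (i.e. inside the downstream window) is a tRF-1; a read
#' straddling the body/downstream junction is an unprocessed pre-tRNA
#' fragment (`pre_other`), not a tRF-1. On the mature reference a read
#' starting within `tolerance` nt of position 0 is a tRF-5 and a read
#' ending within `tolerance` nt of the 3' end is a tRF-3 (the tolerance
#' absorbs exonucleolytic raggedness); anything else is `mature_other`.
#'
#' tRF-1 assignments additionally carry a terminator-readthrough flag:
#' `TRUE` when the read's 3' end extends strictly beyond the last T of
#' the gene's T1 terminator (see [call_readthrough()]), `NA` when the
#' gene has no annotated terminator.
#'
#' @param records primary mapping records from [run_cascade()] /
#'   [map_stage()] (or a `cascade_result`).
#' @param ref_set the reference set the records were mapped against.
#' @param terminators optional terminator table from
#'   [annotate_terminators()]; required for readthrough calls.
#' @param tolerance positional tolerance (nt) for set-1 tRF-5/tRF-3
#'   calls (default 2).
#' @param include_antisense keep antisense records (default FALSE: tRFs
#'   are sense fragments).
#' @return A data frame of assignments: `read_id`, `gene_id` (source
#'   locus id), `trf_class` (one of `tRF5`, `tRF3`, `tRF1`,
#'   `mature_other`, `pre_other`, `miRNA`, `ncRNA`), `readthrough`,
#'   `read_length`, plus `sample` if present in the records.
#' @export
assign_classes <- function(records, ref_set, terminators = NULL,
                           tolerance = 2L, include_antisense = FALSE) {
  if (inherits(records, "cascade_result")) records <- records$records
  stopifnot(inherits(ref_set, "reference_set"))
  meta <- ref_set$meta
  mi <- match(records$ref_id, meta$seq_id)
  if (anyNA(mi)) {
    stopf("mapping record references unknown ref_id '%s'",
          records$ref_id[which(is.na(mi))[1]])
  }
  if (!include_antisense) {
    keep <- records$strand == "+"
    records <- records[keep, , drop = FALSE]
    mi <- mi[keep]
  }
  category <- meta$category[mi]
  gene_id <- meta$gene_id[mi]
  gene_id[is.na(gene_id)] <- sub("\\|.*$", "", records$ref_id[is.na(gene_id)])
  reflen <- meta$length[mi]
  body <- meta$body_len[mi]

  cls <- character(nrow(records))
  cls[category == "miRNA"] <- "miRNA"
  cls[category %in% c("ncRNA", "ncRNA_half")] <- "ncRNA"
  cls[category == "tRF5"] <- "tRF5"
  cls[category == "tRF3"] <- "tRF3"
  cls[category == "tRF1"] <- "tRF1"

  m <- category == "mature_tRNA"
  cls[m & records$ref_start <= tolerance] <- "tRF5"
  cls[m & cls == "" & records$ref_end >= reflen - tolerance] <- "tRF3"
  cls[m & cls == ""] <- "mature_other"

  p <- category == "pre_tRNA"
  cls[p & records$ref_start >= body] <- "tRF1"
  cls[p & cls == ""] <- "pre_other"

  # read end within the downstream window, for readthrough calls
  end_in_window <- rep(NA_integer_, nrow(records))
  t1 <- cls == "tRF1"
  end_in_window[t1 & p] <- records$ref_end[t1 & p] - body[t1 & p]
  end_in_window[t1 & category == "tRF1"] <-
    records$ref_end[t1 & category == "tRF1"]

  readthrough <- rep(NA, nrow(records))
  if (!is.null(terminators) && any(t1)) {
    ti <- match(gene_id[t1], terminators$gene_id)
    off <- terminators$offset[ti]
    len <- terminators$length[ti]
    found <- terminators$found[ti] & !is.na(ti)
    rt <- rep(NA, sum(t1))
    rt[found] <- end_in_window[t1][found] > (off[found] + len[found])
    readthrough[t1] <- rt
  }

  out <- data.frame(
    read_id = records$read_id,
    gene_id = gene_id,
    trf_class = cls,
    readthrough = readthrough,
    read_length = records$ref_end - records$ref_start,
    stringsAsFactors = FALSE
  )
  if (!is.null(records$sample)) out$sample <- records$sample
  out
}

#' Call terminator readthrough for a tRF-1 read
#'
#' A tRF-1 is a readthrough product when its 3' end extends strictly
#' beyond the last T of the T1 terminator; a read ending exactly at the
#' last T is not readthrough.
#'
#' @param read_end 0-based half-open end of the read within the
#'   downstream window (i.e. one past its last base).
#' @param terminator a [find_t1_terminator()] annotation (or any list
#'   with `offset`, `length`, `found`).
#' @return `TRUE`/`FALSE`, or `NA` when no terminator was found.
#' @export
#' @examples
#' t1 <- find_t1_terminator(paste0(strrep("A", 20), "TTTT", strrep("G", 30)))
#' call_readthrough(23, t1)  # ends inside the tract
#' call_readthrough(30, t1)  # extends beyond it
call_readthrough <- function(read_end, terminator) {
  if (!isTRUE(terminator$found)) return(NA)
  read_end > terminator$offset + terminator$length
}

#' Count assignments per locus and normalize to CPM
#'
#' Raw counts are tallied per (gene, class, sample); CPM divides by the
#' per-sample total of primary mapped reads across all categories
#' (including miRNA/ncRNA background), times 1e6.
#'
#' @param assignments an assignment table from [assign_classes()] with a
#'   `sample` column, or a named list of assignment tables (names become
#'   sample names).
#' @param groups optional named character vector mapping sample name to
#'   group label.
#' @return An object of class `trf_counts`: integer matrix `raw` and
#'   numeric matrix `cpm` (rows `gene:class`, columns samples), `loci`
#'   (`gene_id`, `trf_class`) and `samples` (`sample`, `group`) tables.
#' @export
count_and_normalize <- function(assignments, groups = NULL) {
  if (is.list(assignments) && !is.data.frame(assignments)) {
    nm <- names(assignments) %||% sprintf("S%d", seq_along(assignments))
    assignments <- do.call(rbind, Map(function(a, s) {
      a$sample <- s
      a
    }, assignments, nm))
  }
  if (is.null(assignments$sample)) assignments$sample <- "S1"
  samples <- if (!is.null(groups)) names(groups) else
    unique(assignments$sample)
  if (length(samples) < 1L) stopf("at least one sample is required")
  n_per_sample <- table(factor(assignments$sample, levels = samples))
  if (any(n_per_sample == 0L)) {
    stopf("sample '%s' has zero mapped reads",
          names(n_per_sample)[n_per_sample == 0L][1])
  }
  locus <- paste0(assignments$gene_id, ":", assignments$trf_class)
  raw <- table(factor(locus), factor(assignments$sample, levels = samples))
  raw <- matrix(as.integer(raw), nrow = nrow(raw),
                dimnames = dimnames(raw))
  libsize <- colSums(raw)
  cpm <- sweep(raw, 2L, libsize, "/") * 1e6
  parts <- strsplit(rownames(raw), ":", fixed = TRUE)
  loci <- data.frame(
    gene_id = vapply(parts, `[`, "", 1L),
    trf_class = vapply(parts, `[`, "", 2L),
    stringsAsFactors = FALSE
  )
  rownames(loci) <- rownames(raw)
  smp <- data.frame(sample = samples,
                    group = if (!is.null(groups)) unname(groups[samples])
                            else samples,
                    stringsAsFactors = FALSE)
  out <- list(raw = raw, cpm = cpm, loci = loci, samples = smp)
  class(out) <- "trf_counts"
  out
}

subset_counts <- function(x, keep) {
  x$raw <- x$raw[keep, , drop = FALSE]
  x$cpm <- x$cpm[keep, , drop = FALSE]
  x$loci <- x$loci[keep, , drop = FALSE]
  x
}

#' Percentile-based expression filter
#'
#' A row (locus) is retained when the 75th percentile of its per-sample
#' CPM values is at least `threshold_cpm` (default 20). The percentile
#' is computed with linear interpolation between order statistics, so a
#' locus high in only a subset of samples — e.g. low in an experimental
#' group but high in controls — is retained, which is the point of
#' filtering on a high percentile rather than the mean.
#'
#' @param x a `trf_counts` object with at least 2 samples.
#' @param threshold_cpm CPM threshold (default 20).
#' @param probs percentile used (default 0.75).
#' @return The filtered `trf_counts` (CPM values are not recomputed;
#'   library sizes stay those of the full object). The operation is
#'   idempotent.
#' @export
percentile_filter <- function(x, threshold_cpm = 20, probs = 0.75) {
  stopifnot(inherits(x, "trf_counts"))
  if (ncol(x$cpm) < 2L) stopf("percentile_filter needs at least 2 samples")
  p75 <- apply(x$cpm, 1L, stats::quantile, probs = probs, names = FALSE)
  subset_counts(x, p75 >= threshold_cpm)
}

#' MA statistics between two sample groups
#'
#' For each locus passing a low-expression cutoff (mean CPM across the
#' two groups' samples >= `low_cutoff_cpm`, default 50), computes the
#' average expression in log10 CPM and the log2 fold change
#' `log2((mean_B + eps) / (mean_A + eps))` with a 0.5-CPM pseudocount.
#'
#' @param x a `trf_counts` object.
#' @param group_a,group_b group labels in `x$samples$group`.
#' @param low_cutoff_cpm exclusion threshold on cross-group mean CPM.
#' @param pseudocount CPM pseudocount for the fold change.
#' @return A data frame: locus id, `gene_id`, `trf_class`, `mean_cpm`,
#'   `mean_log10_cpm`, `log2fc`.
#' @export
ma_statistics <- function(x, group_a, group_b, low_cutoff_cpm = 50,
                          pseudocount = 0.5) {
  stopifnot(inherits(x, "trf_counts"))
  for (g in c(group_a, group_b)) {
    if (!g %in% x$samples$group) stopf("unknown group label '%s'", g)
  }
  a_cols <- x$samples$sample[x$samples$group == group_a]
  b_cols <- x$samples$sample[x$samples$group == group_b]
  mean_a <- rowMeans(x$cpm[, a_cols, drop = FALSE])
  mean_b <- rowMeans(x$cpm[, b_cols, drop = FALSE])
  mean_all <- rowMeans(x$cpm[, c(a_cols, b_cols), drop = FALSE])
  keep <- mean_all >= low_cutoff_cpm
  data.frame(
    locus = rownames(x$cpm)[keep],
    gene_id = x$loci$gene_id[keep],
    trf_class = x$loci$trf_class[keep],
    mean_cpm = mean_all[keep],
    mean_log10_cpm = log10(mean_all[keep]),
    log2fc = log2((mean_b[keep] + pseudocount) /
                  (mean_a[keep] + pseudocount)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Per-class read-length distribution
#'
#' @param assignments an assignment table from [assign_classes()].
#' @param range length range of the histogram (default 15-50 nt, the
#'   library size selection window).
#' @return A matrix of counts, rows = lengths, columns = classes;
#'   column sums equal per-class read counts.
#' @export
length_distribution <- function(assignments, range = c(15L, 50L)) {
  bins <- seq(range[1], range[2])
  tab <- table(factor(assignments$read_length, levels = bins),
               assignments$trf_class)
  m <- matrix(as.integer(tab), nrow = length(bins),
              dimnames = list(length = bins, class = colnames(tab)))
  m
}

#' Positional coverage profile on one reference record
#'
#' Counts, at every reference position, the primary sense reads whose
#' alignment covers it, plus the number of reads starting there. For
#' pre-tRNA records positions are annotated as body vs downstream
#' (3'-trailer) region.
#'
#' @param records mapping records (or a `cascade_result`).
#' @param ref_set the reference set mapped against.
#' @param ref_id the record to profile.
#' @return A data frame with `pos` (0-based), `starts`, `coverage`, and
#'   `region` (`"body"`/`"downstream"` for pre-tRNA records, otherwise
#'   `"body"`).
#' @export
coverage_map <- function(records, ref_set, ref_id) {
  if (inherits(records, "cascade_result")) records <- records$records
  mi <- match(ref_id, ref_set$meta$seq_id)
  if (is.na(mi)) stopf("unknown ref_id '%s'", ref_id)
  len <- ref_set$meta$length[mi]
  sel <- records[records$ref_id == ref_id & records$strand == "+" &
                   records$primary, , drop = FALSE]
  starts <- tabulate(sel$ref_start + 1L, nbins = len)
  ends <- tabulate(sel$ref_end, nbins = len)  # last covered base (1-based)
  coverage <- cumsum(starts - c(0L, ends[-len]))
  body <- ref_set$meta$body_len[mi]
  region <- if (!is.na(body)) {
    ifelse(seq_len(len) - 1L < body, "body", "downstream")
  } else "body"
  data.frame(pos = seq_len(len) - 1L, starts = starts,
             coverage = coverage, region = region,
             stringsAsFactors = FALSE)
}

#' @export
print.trf_counts <- function(x, ...) {
  cat(sprintf("tRF count matrix: %d loci x %d samples\n",
              nrow(x$raw), ncol(x$raw)))
  cat(sprintf("  classes: %s\n",
              paste(sprintf("%s=%d", names(table(x$loci$trf_class)),
                            table(x$loci$trf_class)), collapse = " ")))
  cat(sprintf("  library sizes: %s\n",
              paste(format(colSums(x$raw), big.mark = ","),
                    collapse = ", ")))
  invisible(x)
}
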