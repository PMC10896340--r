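#' Quantify a set of small-RNA samples end to end
#'
#' Convenience wrapper chaining the per-sample steps: length filter,
#' alignment cascade, class assignment, then a combined count matrix
#' with CPM normalization.
#'
#' @param read_sets named list of read vectors (one per sample), e.g.
#'   the `reads` element of [simulate_reads()] output or values from
#'   [read_fastq()].
#' @param ref_set a [build_reference_set()] object.
#' @param groups optional named character vector mapping sample name to
#'   group label.
#' @param terminators optional [annotate_terminators()] table for
#'   readthrough calls.
#' @param min_len,max_mismatch cascade parameters, see [run_cascade()].
#' @param include_antisense see [assign_classes()].
#' @return A `trf_counts` object; the per-sample `cascade_result`
#'   reports and combined assignment table are attached as attributes
#'   `"cascades"` and `"assignments"`.
#' @export
quantify_samples <- function(read_sets, ref_set, groups = NULL,
                             terminators = NULL, min_len = 18L,
                             max_mismatch = 2L,
                             include_antisense = FALSE) {
  stopifnot(is.list(read_sets), !is.null(names(read_sets)))
  cascades <- list()
  assignments <- list()
  for (s in names(read_sets)) {
    cas <- run_cascade(read_sets[[s]], ref_set,
                       max_mismatch = max_mismatch, min_len = min_len)
    asn <- assign_classes(cas, ref_set, terminators = terminators,
                          include_antisense = include_antisense)
    asn$sample <- s
    cascades[[s]] <- cas
    assignments[[s]] <- asn
  }
  asn_all <- do.call(rbind, assignments)
  rownames(asn_all) <- NULL
  counts <- count_and_normalize(asn_all, groups = groups)
  attr(counts, "cascades") <- cascades
  attr(counts, "assignments") <- asn_all
  counts
}
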