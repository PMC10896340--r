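#' Build mature tRNA sequences
#'
#' A mature tRNA reference sequence is the genomic body with the intron
#' (if any) excised and the post-transcriptional 3'-terminal CCA
#' appended. CCA is always appended, even if the genomic 3' end already
#' reads CCA, so record lengths are reproducible:
#' `length = nchar(genomic) - intron_length + 3`.
#'
#' @param genes a `trna_gene_set` (see [simulate_trna_genes()]) or any
#'   data frame with `gene_id`, `genomic_seq`, `intron_start`,
#'   `intron_end` columns (0-based half-open intron on `genomic_seq`).
#' @return A named character vector of mature tRNA sequences.
#' @export
#' @examples
#' genes <- simulate_trna_genes(sim_config(n_genes = 3, seed = 1))
#' mat <- build_mature_trna(genes)
#' substring(mat, nchar(mat) - 2)  # all end in CCA
build_mature_trna <- function(genes) {
  seqs <- genes$genomic_seq
  out <- character(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    s <- seqs[i]
    if (!is.na(genes$intron_start[i])) {
      is0 <- genes$intron_start[i]
      ie0 <- genes$intron_end[i]
      if (is0 <= 0L || ie0 >= nchar(s) || ie0 <= is0) {
        stopf("gene %s: intron [%d, %d) must lie strictly inside the %d-nt body",
              genes$gene_id[i], is0, ie0, nchar(s))
      }
      s <- paste0(substr(s, 1L, is0), substr(s, ie0 + 1L, nchar(s)))
    }
    out[i] <- paste0(s, "CCA")
  }
  names(out) <- genes$gene_id
  out
}

#' Build pre-tRNA reference sequences
#'
#' A pre-tRNA record is the genomic body (intron retained) followed by
#' the downstream window; 5'-leaders are excluded. The record therefore
#' spans the tRNA body plus up to 150 nt of 3'-trailer and terminator
#' context.
#'
#' @inheritParams build_mature_trna
#' @return A named character vector of pre-tRNA sequences.
#' @export
build_pre_trna_ref <- function(genes) {
  out <- paste0(genes$genomic_seq, genes$downstream)
  names(out) <- genes$gene_id
  out
}

#' Build tRF window references (set-2 style)
#'
#' Window records used to classify tRF reads by reference membership:
#' tRF-5 is the first 35 nt of the mature tRNA, tRF-3 the 3'-most 30 nt
#' including the appended CCA, and tRF-1 the 150-nt downstream window
#' (3'-trailer) starting immediately after the discriminator. Records
#' are shorter than their window only if the source sequence is shorter.
#'
#' @inheritParams build_mature_trna
#' @return A list with named character vectors `trf5`, `trf3`, `trf1`;
#'   names carry the gene id plus a window tag (`|trf5`, `|trf3`,
#'   `|trf1`).
#' @export
build_trf_refs <- function(genes) {
  mature <- build_mature_trna(genes)
  ml <- nchar(mature)
  trf5 <- substr(mature, 1L, pmin(35L, ml))
  trf3 <- substr(mature, pmax(1L, ml - 29L), ml)
  trf1 <- substr(genes$downstream, 1L, 150L)
  names(trf5) <- paste0(genes$gene_id, "|trf5")
  names(trf3) <- paste0(genes$gene_id, "|trf3")
  names(trf1) <- paste0(genes$gene_id, "|trf1")
  list(trf5 = trf5, trf3 = trf3, trf1 = trf1)
}

#' Split ncRNA records into 5' and 3' halves
#'
#' snaR-A/VtRNA-style records (including their 50-nt downstream
#' extension) are classified as 5' or 3' fragments by dividing each
#' sequence in half; for odd lengths the 5' half gets the extra base.
#'
#' @param seqs named character vector of ncRNA sequences.
#' @return A named character vector twice as long, names tagged
#'   `|5half` / `|3half`.
#' @export
build_half_refs <- function(seqs) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  n <- nchar(seqs)
  mid <- ceiling(n / 2)
  five <- substr(seqs, 1L, mid)
  three <- substr(seqs, mid + 1L, n)
  out <- c(five, three)
  names(out) <- c(paste0(names(seqs), "|5half"), paste0(names(seqs), "|3half"))
  out[order(rep(seq_along(seqs), 2L), rep(1:2, each = length(seqs)))]
}

#' Assemble a reference set for the alignment cascade
#'
#' Two custom reference-set layouts are supported. Set-1 is the ordered
#' cascade: stage 1 miRNAs + other ncRNAs, stage 2 mature tRNAs (introns
#' removed, CCA appended), stage 3 pre-tRNAs (intron retained, 150-nt
#' downstream window, no 5'-leader); only reads unmapped at one stage
#' proceed to the next. Set-2 concatenates miRNAs + ncRNAs, the tRF-5 /
#' tRF-3 / tRF-1 window references and optional ncRNA 5'/3' halves into
#' a single stage, so class is defined by reference membership.
#'
#' Within a stage, records are ordered by category then lexicographic
#' sequence id; this is the deterministic tie-break order used by the
#' mapper for multi-mapping reads.
#'
#' @param genes a `trna_gene_set`.
#' @param mirnas a `mirna_set` data frame (see [simulate_mirnas()]) or a
#'   named character vector of mature miRNA sequences.
#' @param ncrnas optional named character vector of other ncRNAs.
#' @param set `1` (cascade) or `2` (concatenated tRF windows).
#' @param half_ncrnas optional named character vector (e.g. snaR-A /
#'   VtRNA genes incl. 50 nt downstream) split into halves and added to
#'   set-2.
#' @return An object of class `reference_set`: ordered `entries` data
#'   frame (`stage`, `category`, `seq_id`, `sequence`), a `meta` table
#'   with per-record gene attribution and body lengths, `set_kind`, and
#'   an internal index cache.
#' @export
build_reference_set <- function(genes, mirnas = NULL, ncrnas = NULL,
                                set = 1L, half_ncrnas = NULL) {
  stopifnot(set %in% c(1L, 2L))
  mir <- NULL
  if (!is.null(mirnas)) {
    mir <- if (is.data.frame(mirnas)) {
      stats::setNames(mirnas$sequence, mirnas$mirna_id)
    } else mirnas
  }
  mature <- build_mature_trna(genes)
  body_len <- nchar(genes$genomic_seq)

  rows <- list()
  add <- function(stage, category, seqs, gene_id = NA_character_,
                  body = NA_integer_) {
    if (is.null(seqs) || length(seqs) == 0L) return()
    rows[[length(rows) + 1L]] <<- data.frame(
      stage = stage, category = category,
      seq_id = names(seqs), sequence = unname(seqs),
      gene_id = gene_id, body_len = body,
      stringsAsFactors = FALSE
    )
  }

  if (set == 1L) {
    add(1L, "miRNA", mir)
    add(1L, "ncRNA", ncrnas)
    mat <- stats::setNames(mature, paste0(genes$gene_id, "|mature"))
    add(2L, "mature_tRNA", mat, gene_id = genes$gene_id)
    pre <- build_pre_trna_ref(genes)
    names(pre) <- paste0(genes$gene_id, "|pre")
    add(3L, "pre_tRNA", pre, gene_id = genes$gene_id, body = body_len)
    kind <- "set1_cascade"
    name <- "set-1 (miRNA+ncRNA / mature tRNA / pre-tRNA cascade)"
  } else {
    add(1L, "miRNA", mir)
    add(1L, "ncRNA", ncrnas)
    w <- build_trf_refs(genes)
    add(1L, "tRF5", w$trf5, gene_id = genes$gene_id)
    add(1L, "tRF3", w$trf3, gene_id = genes$gene_id)
    add(1L, "tRF1", w$trf1, gene_id = genes$gene_id)
    if (!is.null(half_ncrnas)) {
      add(1L, "ncRNA_half", build_half_refs(half_ncrnas))
    }
    kind <- "set2_concatenated"
    name <- "set-2 (concatenated tRF window references)"
  }
  entries <- do.call(rbind, rows)
  if (is.null(entries) || nrow(entries) == 0L) {
    stopf("reference set has no records")
  }
  if (any(nchar(entries$sequence) == 0L)) {
    stopf("reference set contains an empty sequence")
  }
  cat_order <- match(entries$category, unique(entries$category))
  entries <- entries[order(entries$stage, cat_order, entries$seq_id), ,
                     drop = FALSE]
  rownames(entries) <- NULL
  if (anyDuplicated(entries$seq_id)) {
    stopf("duplicate seq_id in reference set: %s",
          entries$seq_id[duplicated(entries$seq_id)][1])
  }
  meta <- entries[, c("seq_id", "category", "gene_id", "body_len")]
  meta$length <- nchar(entries$sequence)
  obj <- list(
    name = name,
    set_kind = kind,
    entries = entries[, c("stage", "category", "seq_id", "sequence")],
    meta = meta,
    cache = new.env(parent = emptyenv())
  )
  class(obj) <- "reference_set"
  obj
}

#' @export
print.reference_set <- function(x, ...) {
  cat(sprintf("Reference set: %s\n", x$name))
  tab <- table(x$entries$stage, x$entries$category)
  for (s in rownames(tab)) {
    cats <- colnames(tab)[tab[s, ] > 0]
    cat(sprintf("  stage %s: %s (%d records)\n", s,
                paste(cats, collapse = " + "),
                sum(tab[s, ])))
  }
  invisible(x)
}
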