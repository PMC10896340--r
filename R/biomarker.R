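#' Intragenic tRF-1/tRF-3 biomarker metric
#'
#' The internally-controlled biomarker for Pol III deficiency: within a
#' single tRNA gene, the ratio of mean tRF-1 CPM to mean tRF-3 CPM
#' (means over a group's replicates), compared between a case and a
#' control group as a ratio of ratios. Because both fragment classes
#' come from the same gene and the ratio is taken within each sample
#' group, the metric is invariant to library-size rescaling.
#'
#' No pseudocount is applied: candidate genes are pre-screened for
#' abundance, and an undefined ratio (zero tRF-3 mean) is an error, not
#' a zero.
#'
#' @param x a `trf_counts` object (typically after
#'   [percentile_filter()]).
#' @param gene_id the tRNA gene to assess; must have both `tRF1` and
#'   `tRF3` rows in `x`.
#' @param case_group,control_group group labels in `x$samples$group`;
#'   each group needs at least 2 replicates.
#' @return An object of class `intragenic_metric`: per-group mean CPM
#'   for tRF-1 and tRF-3, the per-group `tRF1/tRF3` ratios, and
#'   `ratio_of_ratios` (case ratio / control ratio).
#' @export
intragenic_ratio <- function(x, gene_id, case_group, control_group) {
  stopifnot(inherits(x, "trf_counts"))
  tab <- intragenic_ratio_table(x, case_group, control_group,
                                .gene = gene_id)
  if (nrow(tab) == 0L) {
    stopf("gene '%s' lacks tRF1 and/or tRF3 rows in the count matrix",
          gene_id)
  }
  out <- as.list(tab[1L, ])
  out$case_group <- case_group
  out$control_group <- control_group
  class(out) <- "intragenic_metric"
  out
}

#' Intragenic ratio table over all genes
#'
#' Vectorized form of [intragenic_ratio()]: the metric for every gene
#' with both tRF-1 and tRF-3 rows and non-zero tRF-3 means in both
#' groups.
#'
#' @inheritParams intragenic_ratio
#' @param .gene optional single gene; errors on undefined ratios
#'   instead of dropping the gene.
#' @return A data frame: `gene_id`, case/control tRF-1 and tRF-3 mean
#'   CPMs, `case_ratio`, `control_ratio`, `ratio_of_ratios`.
#' @export
intragenic_ratio_table <- function(x, case_group, control_group,
                                   .gene = NULL) {
  stopifnot(inherits(x, "trf_counts"))
  for (g in c(case_group, control_group)) {
    if (!g %in% x$samples$group) stopf("unknown group label '%s'", g)
    if (sum(x$samples$group == g) < 2L) {
      stopf("group '%s' needs at least 2 replicates", g)
    }
  }
  grp_mean <- function(g) {
    cols <- x$samples$sample[x$samples$group == g]
    rowMeans(x$cpm[, cols, drop = FALSE])
  }
  mc <- grp_mean(case_group)
  mk <- grp_mean(control_group)
  genes <- if (is.null(.gene)) unique(x$loci$gene_id) else .gene
  rid <- function(g, cls) match(paste0(g, ":", cls), rownames(x$cpm))
  i1 <- rid(genes, "tRF1")
  i3 <- rid(genes, "tRF3")
  ok <- !is.na(i1) & !is.na(i3)
  genes <- genes[ok]; i1 <- i1[ok]; i3 <- i3[ok]
  tab <- data.frame(
    gene_id = genes,
    case_trf1 = mc[i1], case_trf3 = mc[i3],
    control_trf1 = mk[i1], control_trf3 = mk[i3],
    row.names = NULL, stringsAsFactors = FALSE
  )
  if (!is.null(.gene) && nrow(tab) > 0L &&
      (any(tab$case_trf3 == 0) || any(tab$control_trf3 == 0))) {
    stopf("intragenic metric undefined for '%s': zero tRF-3 mean CPM",
          .gene)
  }
  tab <- tab[tab$case_trf3 > 0 & tab$control_trf3 > 0, , drop = FALSE]
  tab$case_ratio <- tab$case_trf1 / tab$case_trf3
  tab$control_ratio <- tab$control_trf1 / tab$control_trf3
  tab$ratio_of_ratios <- tab$case_ratio / tab$control_ratio
  rownames(tab) <- NULL
  tab
}

#' Screen for intragenic biomarker candidate genes
#'
#' Genes whose tRF-1 and tRF-3 CPMs exceed `min_cpm` in every sample of
#' the case and control groups (abundance substantially above
#' background), ranked by the minimum over the control groups of the
#' case-vs-control ratio of ratios (descending; deterministic tie-break
#' by gene id).
#'
#' @param x a `trf_counts` object.
#' @param case_group case group label.
#' @param control_groups character vector of control group labels.
#' @param min_cpm abundance threshold (default 50 CPM).
#' @return A ranked data frame: `gene_id`, one `ror_<control>` column
#'   per control group, and `score` (the minimum). Empty input yields
#'   an empty frame.
#' @export
candidate_screen <- function(x, case_group, control_groups, min_cpm = 50) {
  stopifnot(inherits(x, "trf_counts"))
  empty <- data.frame(gene_id = character(), score = numeric(),
                      stringsAsFactors = FALSE)
  if (nrow(x$cpm) == 0L) return(empty)
  used <- x$samples$sample[x$samples$group %in% c(case_group,
                                                  control_groups)]
  genes <- unique(x$loci$gene_id)
  i1 <- match(paste0(genes, ":tRF1"), rownames(x$cpm))
  i3 <- match(paste0(genes, ":tRF3"), rownames(x$cpm))
  ok <- !is.na(i1) & !is.na(i3)
  genes <- genes[ok]; i1 <- i1[ok]; i3 <- i3[ok]
  if (length(genes) == 0L) return(empty)
  above <- function(i) {
    apply(x$cpm[i, used, drop = FALSE] > min_cpm, 1L, all)
  }
  keep <- above(i1) & above(i3)
  genes <- genes[keep]
  if (length(genes) == 0L) return(empty)
  rors <- sapply(control_groups, function(ctrl) {
    tab <- intragenic_ratio_table(x, case_group, ctrl)
    tab$ratio_of_ratios[match(genes, tab$gene_id)]
  })
  rors <- matrix(rors, nrow = length(genes),
                 dimnames = list(NULL, paste0("ror_", control_groups)))
  score <- apply(rors, 1L, min)
  out <- data.frame(gene_id = genes, rors, score = score,
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-gene tRF class-ratio summaries by group
#'
#' For every gene and sample group, computes ratios of replicate-mean
#' CPMs — `tRF1/(tRF3 + tRF5)`, `tRF1/tRF3`, `tRF1/tRF5` — and
#' summarizes each ratio's distribution over genes per group (median,
#' Q1-Q3 quartiles, 5th-95th percentiles). Pairwise group comparisons
#' use a pluggable test hook; the default is a Mann-Whitney (Wilcoxon
#' rank-sum) test per group pair and ratio type.
#'
#' @param x a `trf_counts` object.
#' @param groups group labels to include (default: all).
#' @param test_fun function(case_values, control_values) returning a
#'   p-value; `NULL` selects the default Mann-Whitney test, `FALSE`
#'   skips testing.
#' @return An object of class `class_ratio_summary`: `per_gene` (long
#'   table of per-gene ratios), `summary` (group x ratio-type box
#'   statistics with counts of undefined ratios), and `tests` (pairwise
#'   p-values), if requested.
#' @export
class_ratio_summary <- function(x, groups = NULL, test_fun = NULL) {
  stopifnot(inherits(x, "trf_counts"))
  if (is.null(groups)) groups <- unique(x$samples$group)
  if (is.null(test_fun)) {
    test_fun <- function(a, b) stats::wilcox.test(a, b, exact = FALSE)$p.value
  }
  genes <- unique(x$loci$gene_id)
  per <- list()
  for (g in groups) {
    cols <- x$samples$sample[x$samples$group == g]
    m <- rowMeans(x$cpm[, cols, drop = FALSE])
    val <- function(cls) {
      v <- m[match(paste0(genes, ":", cls), names(m))]
      ifelse(is.na(v), 0, v)
    }
    m1 <- val("tRF1"); m3 <- val("tRF3"); m5 <- val("tRF5")
    per[[g]] <- data.frame(
      gene_id = rep(genes, 3L),
      group = g,
      ratio_type = rep(c("tRF1/(tRF3+tRF5)", "tRF1/tRF3", "tRF1/tRF5"),
                       each = length(genes)),
      value = c(ifelse(m3 + m5 > 0, m1 / (m3 + m5), NA_real_),
                ifelse(m3 > 0, m1 / m3, NA_real_),
                ifelse(m5 > 0, m1 / m5, NA_real_)),
      stringsAsFactors = FALSE
    )
  }
  per_gene <- do.call(rbind, per)
  rownames(per_gene) <- NULL

  box <- function(v) {
    q <- stats::quantile(v, c(0.05, 0.25, 0.5, 0.75, 0.95), names = FALSE,
                         na.rm = TRUE)
    c(p5 = q[1], q1 = q[2], median = q[3], q3 = q[4], p95 = q[5])
  }
  combos <- unique(per_gene[, c("group", "ratio_type")])
  summ <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    v <- per_gene$value[per_gene$group == combos$group[i] &
                          per_gene$ratio_type == combos$ratio_type[i]]
    cbind(combos[i, ], as.data.frame(as.list(box(v))),
          n = sum(!is.na(v)), n_undefined = sum(is.na(v)))
  }))
  rownames(summ) <- NULL

  tests <- NULL
  if (is.function(test_fun) && length(groups) > 1L) {
    pairs <- utils::combn(groups, 2L, simplify = FALSE)
    tests <- do.call(rbind, lapply(pairs, function(pr) {
      do.call(rbind, lapply(unique(per_gene$ratio_type), function(rt) {
        a <- per_gene$value[per_gene$group == pr[1] &
                              per_gene$ratio_type == rt]
        b <- per_gene$value[per_gene$group == pr[2] &
                              per_gene$ratio_type == rt]
        data.frame(group_a = pr[1], group_b = pr[2], ratio_type = rt,
                   p_value = test_fun(a[!is.na(a)], b[!is.na(b)]),
                   stringsAsFactors = FALSE)
      }))
    }))
    rownames(tests) <- NULL
  }
  out <- list(per_gene = per_gene, summary = summ, tests = tests)
  class(out) <- "class_ratio_summary"
  out
}

#' @export
print.intragenic_metric <- function(x, ...) {
  cat(sprintf("Intragenic tRF-1/tRF-3 metric for %s\n", x$gene_id))
  cat(sprintf("  %s: tRF1 %.1f / tRF3 %.1f CPM -> ratio %.3f\n",
              x$case_group, x$case_trf1, x$case_trf3, x$case_ratio))
  cat(sprintf("  %s: tRF1 %.1f / tRF3 %.1f CPM -> ratio %.3f\n",
              x$control_group, x$control_trf1, x$control_trf3,
              x$control_ratio))
  cat(sprintf("  ratio of ratios (%s / %s): %.3f\n",
              x$case_group, x$control_group, x$ratio_of_ratios))
  invisible(x)
}

#' @export
print.class_ratio_summary <- function(x, ...) {
  cat("tRF class-ratio summary (per-gene ratios of replicate-mean CPM)\n")
  print(x$summary, digits = 3)
  if (!is.null(x$tests)) {
    cat("Pairwise group tests:\n")
    print(x$tests, digits = 3)
  }
  invisible(x)
}
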