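#' Locate the T1 terminator in a downstream window
#'
#' The T1 terminator is the first (leftmost) maximal run of four or more
#' consecutive Ts on the sense strand downstream of a tRNA gene — the
#' Pol III termination signal. Runs shorter than 4 Ts are skipped; runs
#' are not merged across non-T bases. A run of exactly 4 Ts is class
#' `fourT`, longer runs are `fivePlusT`.
#'
#' @param downstream sense-strand nucleotide string (the 3' downstream
#'   window of a tRNA gene).
#' @return A list of class `t1_terminator`: `offset` (0-based position
#'   of the first T; `NA` if absent), `length` (run length), `t_class`
#'   (`"fourT"` or `"fivePlusT"`), `found` (logical). Empty input yields
#'   `found = FALSE`, not an error.
#' @seealso [annotate_terminators()] for the vectorized table form.
#' @export
#' @examples
#' find_t1_terminator("AATTTTGA")   # offset 2, length 4
#' find_t1_terminator("TTTATTTT")   # first run of >= 4 is at offset 4
find_t1_terminator <- function(downstream) {
  stopifnot(is.character(downstream), length(downstream) == 1L)
  out <- list(offset = NA_integer_, length = NA_integer_,
              t_class = NA_character_, found = FALSE)
  class(out) <- "t1_terminator"
  if (is.na(downstream) || nchar(downstream) == 0L) return(out)
  m <- regexpr("T{4,}", downstream)
  if (m[1] == -1L) return(out)
  out$offset <- as.integer(m) - 1L
  out$length <- attr(m, "match.length")
  out$t_class <- if (out$length == 4L) "fourT" else "fivePlusT"
  out$found <- TRUE
  out
}

#' Terminator annotation table for a gene set
#'
#' Applies [find_t1_terminator()] to the downstream window of every
#' gene.
#'
#' @param genes a `trna_gene_set` (or any data frame with `gene_id` and
#'   `downstream` columns), or a named character vector of downstream
#'   windows.
#' @return A data frame: `gene_id`, `offset` (0-based), `length`,
#'   `t_class`, `found`.
#' @export
annotate_terminators <- function(genes) {
  if (is.character(genes)) {
    ds <- genes
    ids <- names(genes) %||% as.character(seq_along(genes))
  } else {
    ds <- genes$downstream
    ids <- genes$gene_id
  }
  m <- regexpr("T{4,}", ds)
  found <- m != -1L & !is.na(ds)
  len <- ifelse(found, attr(m, "match.length"), NA_integer_)
  data.frame(
    gene_id = ids,
    offset = ifelse(found, as.integer(m) - 1L, NA_integer_),
    length = as.integer(len),
    t_class = ifelse(found, ifelse(len == 4L, "fourT", "fivePlusT"),
                     NA_character_),
    found = found,
    stringsAsFactors = FALSE
  )
}

#' @export
print.t1_terminator <- function(x, ...) {
  if (x$found) {
    cat(sprintf("T1 terminator: offset %d, %d Ts (%s)\n",
                x$offset, x$length, x$t_class))
  } else {
    cat("T1 terminator: none found (no run of >= 4 Ts)\n")
  }
  invisible(x)
}
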