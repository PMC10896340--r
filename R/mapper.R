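# Internal short-read mapper: end-to-end, ungapped matching of each read
# (sense or antisense) against the records of one cascade stage, with at
# most `max_mismatch` substitutions and no indels. Exact occurrences are
# found by hashing every reference substring of the read's width;
# mismatched occurrences by a pigeonhole seed-and-verify search (a read
# with <= 2 substitutions has at least one of three disjoint segments
# exact). Ties are broken deterministically by (fewest mismatches, sense
# before antisense, category order, lexicographic seq_id, leftmost
# position). Indexes are cached on the reference_set.

stage_entries <- function(ref_set, stage) {
  ref_set$entries[ref_set$entries$stage == stage, , drop = FALSE]
}

# Exact index: every substring of width w across a stage's records, in
# priority order; match() therefore returns the primary hit directly.
exact_index <- function(ref_set, stage, width) {
  key <- sprintf("ex_s%d_w%d", stage, width)
  cached <- ref_set$cache[[key]]
  if (!is.null(cached)) return(cached)
  e <- stage_entries(ref_set, stage)
  lens <- nchar(e$sequence)
  keep <- which(lens >= width)
  if (length(keep) == 0L) {
    obj <- NULL
  } else {
    nk <- lens[keep] - width + 1L
    ref <- rep(keep, nk)
    pos0 <- unlist(lapply(nk, function(m) 0:(m - 1L)), use.names = FALSE)
    kmer <- substring(e$sequence[ref], pos0 + 1L, pos0 + width)
    u <- !duplicated(kmer)
    uid <- match(kmer, kmer[u])
    nhit <- tabulate(uid, nbins = sum(u))[uid]
    obj <- list(kmer = kmer, ref = ref, pos0 = pos0, nhit = as.integer(nhit))
  }
  assign(key, obj, envir = ref_set$cache)
  obj
}

# Segment index for the pigeonhole search: unique k-mers plus the list
# of (ref, pos) occurrences for each.
segment_index <- function(ref_set, stage, width) {
  key <- sprintf("seg_s%d_w%d", stage, width)
  cached <- ref_set$cache[[key]]
  if (!is.null(cached)) return(cached)
  base <- exact_index(ref_set, stage, width)
  if (is.null(base)) {
    obj <- NULL
  } else {
    u <- !duplicated(base$kmer)
    uid <- match(base$kmer, base$kmer[u])
    obj <- list(ukmer = base$kmer[u],
                occ = split(seq_along(uid), uid),
                ref = base$ref, pos0 = base$pos0)
  }
  assign(key, obj, envir = ref_set$cache)
  obj
}

#' Filter reads by minimum length
#'
#' First-pass length cutoff applied before alignment (default 18 nt).
#'
#' @param reads named character vector of read sequences.
#' @param min_len minimum retained read length in nt (>= 1).
#' @return The reads of length >= `min_len`.
#' @export
#' @examples
#' length_filter(c(a = strrep("A", 17), b = strrep("A", 18)))
length_filter <- function(reads, min_len = 18L) {
  stopifnot(min_len >= 1L)
  reads[nchar(reads) >= min_len]
}

#' Map reads against one reference stage
#'
#' A read maps if it has an end-to-end, ungapped occurrence on the sense
#' or antisense strand of some record with at most `max_mismatch`
#' substitutions (no indels). The best hit has the fewest mismatches;
#' ties are broken deterministically by sense strand first, then
#' category order, lexicographic `seq_id`, and leftmost position. One
#' primary record is reported per mapped read; additional hits are
#' counted in `n_alt` (capped at 10, mirroring the usual alternate-hit
#' reporting ceiling).
#'
#' @param reads named character vector of read sequences.
#' @param ref_set a [build_reference_set()] object.
#' @param stage which stage of the reference set to map against.
#' @param max_mismatch maximum substitutions (default 2).
#' @return A list with `records` (data frame: `read_id`, `stage`,
#'   `category`, `ref_id`, `ref_start`, `ref_end` 0-based half-open,
#'   `strand`, `mismatches`, `n_alt`, `primary`) and `unmapped` (the
#'   reads that did not map).
#' @export
map_stage <- function(reads, ref_set, stage = 1L, max_mismatch = 2L) {
  stopifnot(inherits(ref_set, "reference_set"))
  e <- stage_entries(ref_set, stage)
  if (nrow(e) == 0L) stopf("reference set has no stage %d", stage)
  if (length(reads) == 0L) {
    return(list(records = empty_records(), unmapped = reads))
  }
  if (is.null(names(reads))) {
    names(reads) <- sprintf("read%07d", seq_along(reads))
  }
  widths <- nchar(reads)
  recs <- vector("list", 0L)
  unmapped <- character()

  for (w in sort(unique(widths))) {
    sel <- which(widths == w)
    rs <- reads[sel]
    idx <- exact_index(ref_set, stage, w)
    hit <- data.frame(read = seq_along(rs), ref = NA_integer_,
                      pos0 = NA_integer_, strand = NA_character_,
                      mism = NA_integer_, n_alt = NA_integer_)
    if (!is.null(idx)) {
      j <- match(rs, idx$kmer)
      ok <- !is.na(j)
      hit$ref[ok] <- idx$ref[j[ok]]
      hit$pos0[ok] <- idx$pos0[j[ok]]
      hit$strand[ok] <- "+"
      hit$mism[ok] <- 0L
      hit$n_alt[ok] <- pmin(idx$nhit[j[ok]] - 1L, 10L)
      todo <- which(!ok)
      if (length(todo) > 0L) {
        j2 <- match(revcomp(rs[todo]), idx$kmer)
        ok2 <- !is.na(j2)
        t2 <- todo[ok2]
        hit$ref[t2] <- idx$ref[j2[ok2]]
        hit$pos0[t2] <- idx$pos0[j2[ok2]]
        hit$strand[t2] <- "-"
        hit$mism[t2] <- 0L
        hit$n_alt[t2] <- pmin(idx$nhit[j2[ok2]] - 1L, 10L)
      }
    }
    if (max_mismatch > 0L) {
      todo <- which(is.na(hit$ref))
      if (length(todo) > 0L) {
        fb <- pigeonhole_search(rs[todo], ref_set, stage, w, max_mismatch)
        if (!is.null(fb)) {
          hit$ref[todo[fb$read]] <- fb$ref
          hit$pos0[todo[fb$read]] <- fb$pos0
          hit$strand[todo[fb$read]] <- fb$strand
          hit$mism[todo[fb$read]] <- fb$mism
          hit$n_alt[todo[fb$read]] <- fb$n_alt
        }
      }
    }
    mapped <- which(!is.na(hit$ref))
    if (length(mapped) > 0L) {
      recs[[length(recs) + 1L]] <- data.frame(
        read_id = names(rs)[mapped],
        stage = stage,
        category = e$category[hit$ref[mapped]],
        ref_id = e$seq_id[hit$ref[mapped]],
        ref_start = hit$pos0[mapped],
        ref_end = hit$pos0[mapped] + w,
        strand = hit$strand[mapped],
        mismatches = hit$mism[mapped],
        n_alt = hit$n_alt[mapped],
        primary = TRUE,
        stringsAsFactors = FALSE
      )
    }
    unmapped <- c(unmapped, names(rs)[is.na(hit$ref)])
  }
  records <- if (length(recs)) do.call(rbind, recs) else empty_records()
  # restore input read order
  records <- records[order(match(records$read_id, names(reads))), ,
                     drop = FALSE]
  rownames(records) <- NULL
  list(records = records,
       unmapped = reads[names(reads) %in% unmapped])
}

empty_records <- function() {
  data.frame(read_id = character(), stage = integer(),
             category = character(), ref_id = character(),
             ref_start = integer(), ref_end = integer(),
             strand = character(), mismatches = integer(),
             n_alt = integer(), primary = logical(),
             stringsAsFactors = FALSE)
}

# Seed-and-verify search for occurrences with 1..max_mismatch
# substitutions. Reads are split into three disjoint segments; any
# occurrence with <= 2 substitutions leaves at least one segment exact,
# so candidate alignments are read off the segment index and verified.
pigeonhole_search <- function(rs, ref_set, stage, w, max_mismatch) {
  e <- stage_entries(ref_set, stage)
  s1 <- w %/% 3L
  if (s1 < 1L) return(NULL)
  offs <- c(0L, s1, 2L * s1)
  lens <- c(s1, s1, w - 2L * s1)
  seqs <- e$sequence
  seq_len_v <- nchar(seqs)

  gather <- function(strings, strand) {
    out <- list()
    for (k in 1:3) {
      sl <- lens[k]
      sidx <- segment_index(ref_set, stage, sl)
      if (is.null(sidx)) next
      seg <- substr(strings, offs[k] + 1L, offs[k] + sl)
      id <- match(seg, sidx$ukmer)
      okr <- which(!is.na(id))
      if (length(okr) == 0L) next
      occ <- sidx$occ[id[okr]]
      nocc <- lengths(occ)
      rows <- unlist(occ, use.names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        read = rep(okr, nocc),
        ref = sidx$ref[rows],
        p = sidx$pos0[rows] - offs[k],
        strand = strand,
        stringsAsFactors = FALSE
      )
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  cand <- rbind(gather(rs, "+"), gather(revcomp(rs), "-"))
  if (is.null(cand) || nrow(cand) == 0L) return(NULL)
  cand <- cand[cand$p >= 0L & cand$p + w <= seq_len_v[cand$ref], ,
               drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  key <- paste(cand$read, cand$strand, cand$ref, cand$p)
  cand <- cand[!duplicated(key), , drop = FALSE]

  qry <- ifelse(cand$strand == "+", rs[cand$read], revcomp(rs)[cand$read])
  win <- substring(seqs[cand$ref], cand$p + 1L, cand$p + w)
  cand$mism <- count_mismatches(qry, win)
  cand <- cand[cand$mism <= max_mismatch, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)

  o <- order(cand$read, cand$mism, cand$strand != "+", cand$ref, cand$p)
  cand <- cand[o, , drop = FALSE]
  nhits <- tabulate(cand$read, nbins = length(rs))
  first <- cand[!duplicated(cand$read), , drop = FALSE]
  list(read = first$read, ref = first$ref, pos0 = first$p,
       strand = first$strand, mism = first$mism,
       n_alt = pmin(nhits[first$read] - 1L, 10L))
}

#' Run the sequential alignment cascade
#'
#' Reads are length-filtered, then aligned to each stage of the
#' reference set in order; only reads unmapped at stage k are used for
#' stage k + 1, so every read is counted at most once, at the first
#' stage able to explain it. For a set-2 (concatenated) reference the
#' cascade degenerates to a single alignment.
#'
#' @param reads named character vector of read sequences.
#' @param ref_set a [build_reference_set()] object.
#' @param max_mismatch maximum substitutions per read (default 2).
#' @param min_len length-filter cutoff applied before stage 1
#'   (default 18 nt); use 1 to disable.
#' @return An object of class `cascade_result`: `records` (primary
#'   mapping records across stages), `unmapped` (reads left after the
#'   last stage), `report` (per-stage in/mapped/out counts),
#'   `total_reads` (input), `n_filtered` (reads surviving the length
#'   filter), and per-category assignment counts.
#' @export
run_cascade <- function(reads, ref_set, max_mismatch = 2L, min_len = 18L) {
  stopifnot(inherits(ref_set, "reference_set"))
  if (length(reads) > 0L && is.null(names(reads))) {
    names(reads) <- sprintf("read%07d", seq_along(reads))
  }
  total <- length(reads)
  kept <- length_filter(reads, min_len)
  stages <- sort(unique(ref_set$entries$stage))
  current <- kept
  rep_rows <- list()
  all_rec <- list()
  for (st in stages) {
    res <- map_stage(current, ref_set, stage = st,
                     max_mismatch = max_mismatch)
    rep_rows[[length(rep_rows) + 1L]] <- data.frame(
      stage = st,
      categories = paste(unique(stage_entries(ref_set, st)$category),
                         collapse = "+"),
      n_in = length(current),
      n_mapped = nrow(res$records),
      n_out = length(res$unmapped)
    )
    all_rec[[length(all_rec) + 1L]] <- res$records
    current <- res$unmapped
  }
  records <- do.call(rbind, all_rec)
  rownames(records) <- NULL
  out <- list(
    records = records,
    unmapped = current,
    report = do.call(rbind, rep_rows),
    total_reads = total,
    n_filtered = length(kept),
    category_counts = table(records$category)
  )
  class(out) <- "cascade_result"
  out
}

#' @export
print.cascade_result <- function(x, ...) {
  cat(sprintf("Alignment cascade: %s reads in, %s after length filter\n",
              format(x$total_reads, big.mark = ","),
              format(x$n_filtered, big.mark = ",")))
  for (i in seq_len(nrow(x$report))) {
    r <- x$report[i, ]
    cat(sprintf("  stage %d (%s): %s mapped, %s passed on\n",
                r$stage, r$categories,
                format(r$n_mapped, big.mark = ","),
                format(r$n_out, big.mark = ",")))
  }
  cat(sprintf("  final unmapped: %s\n",
              format(length(x$unmapped), big.mark = ",")))
  invisible(x)
}
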