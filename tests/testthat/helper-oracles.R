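# Independent oracles used to freeze expected values. Each is written
# as plainly as possible (position-by-position scans, dense grids) and
# shares no code with the implementation it checks.

# Leftmost maximal run of >= 4 Ts, by scanning every position.
oracle_t1 <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L
  while (i <= n) {
    if (chars[i] == "T") {
      j <- i
      while (j < n && chars[j + 1L] == "T") j <- j + 1L
      if (j - i + 1L >= 4L) {
        return(list(offset = i - 1L, length = j - i + 1L, found = TRUE))
      }
      i <- j + 1L
    } else {
      i <- i + 1L
    }
  }
  list(offset = NA_integer_, length = NA_integer_, found = FALSE)
}

# Dense-grid read-off of the 50% crossing of a piecewise log-linear
# decay curve, refined in two zoom stages (final resolution << 1e-6).
oracle_halflife_grid <- function(time, value) {
  v_at <- function(tt) {
    exp(stats::approx(time, log(value), xout = tt)$y)
  }
  lo <- min(time); hi <- max(time)
  for (pass in 1:3) {
    grid <- seq(lo, hi, length.out = 100001L)
    vg <- v_at(grid)
    k <- which(vg <= 50)[1L]
    if (is.na(k)) return(NA_real_)
    lo <- grid[max(1L, k - 1L)]
    hi <- grid[k]
  }
  (lo + hi) / 2
}

# Exhaustive end-to-end scan of one read against one stage of a
# reference set: every record, every offset, both strands; best hit by
# (mismatches, sense first, record order, leftmost).
oracle_scan_read <- function(read, ref_set, stage, max_mismatch) {
  e <- ref_set$entries[ref_set$entries$stage == stage, , drop = FALSE]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(read)))
  w <- nchar(read)
  hits <- list()
  for (i in seq_len(nrow(e))) {
    ref <- e$sequence[i]
    L <- nchar(ref)
    if (L < w) next
    for (p in 0:(L - w)) {
      win <- substr(ref, p + 1L, p + w)
      for (strand in c("+", "-")) {
        q <- if (strand == "+") read else rc
        mm <- sum(strsplit(q, "")[[1]] != strsplit(win, "")[[1]])
        if (mm <= max_mismatch) {
          hits[[length(hits) + 1L]] <- data.frame(
            ref_id = e$seq_id[i], rec = i, pos = p, strand = strand,
            mism = mm, stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(hits) == 0L) return(NULL)
  h <- do.call(rbind, hits)
  h <- h[order(h$mism, h$strand != "+", h$rec, h$pos), , drop = FALSE]
  list(best = h[1L, ], n_hits = nrow(h))
}
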