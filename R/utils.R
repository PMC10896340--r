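# Internal helpers shared across modules.

BASES <- c("A", "C", "G", "T")

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  code
}

# Random DNA strings; `len` is recycled to length n.
random_dna <- function(n, len) {
  if (n == 0L) return(character())
  len <- rep_len(len, n)
  vapply(len, function(l) {
    paste(sample(BASES, l, replace = TRUE), collapse = "")
  }, character(1))
}

# Reverse-complement a character vector of DNA sequences.
revcomp <- function(x) {
  if (length(x) == 0L) return(character())
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Disrupt every run of >= 4 consecutive Ts by substituting the 4th T.
break_t_runs <- function(s) {
  if (is.na(s) || nchar(s) < 4L) return(s)
  repeat {
    m <- regexpr("TTTT", s, fixed = TRUE)
    if (m[1] == -1L) return(s)
    pos <- as.integer(m) + 3L
    substr(s, pos, pos) <- sample(c("A", "C", "G"), 1L)
  }
}

# Count per-pair character mismatches between equal-width string vectors.
count_mismatches <- function(a, b) {
  n <- length(a)
  if (n == 0L) return(integer())
  w <- nchar(a[1L])
  if (w == 0L) return(integer(n))
  am <- matrix(unlist(strsplit(a, "", fixed = TRUE), use.names = FALSE),
               nrow = w)
  bm <- matrix(unlist(strsplit(b, "", fixed = TRUE), use.names = FALSE),
               nrow = w)
  as.integer(colSums(am != bm))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
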