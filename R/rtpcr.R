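#' In-silico RT-PCR amplicon sizing
#'
#' Predicts the amplicon length produced by a primer pair on a sense
#' transcript sequence: the distance from the 5' end of the forward
#' primer site to the 3' end of the reverse-complemented reverse primer
#' site, inclusive. Used to size splice-variant products (e.g. an
#' exon-skipping event shortens the amplicon by exactly the exon
#' length).
#'
#' @param transcript sense-strand transcript sequence.
#' @param fwd_primer forward primer (sense), at least 15 nt.
#' @param rev_primer reverse primer (reverse-complement of the sense
#'   strand), at least 15 nt.
#' @return The amplicon length in bp, or `NA_integer_` if either primer
#'   site is absent or the orientation is wrong. A primer with multiple
#'   sites on the transcript is an error naming the primer.
#' @export
#' @examples
#' tx <- paste0("AAAA", "TATCCGCACTGGGCATGATG", strrep("G", 10),
#'              "AACAGAAGCCAGCAGTCACA", "CCCC")
#' insilico_rt_pcr(tx, "TATCCGCACTGGGCATGATG", "TGTGACTGCTGGCTTCTGTT")
insilico_rt_pcr <- function(transcript, fwd_primer, rev_primer) {
  stopifnot(is.character(transcript), length(transcript) == 1L)
  if (nchar(fwd_primer) < 15L || nchar(rev_primer) < 15L) {
    stopf("primers must be at least 15 nt")
  }
  find_sites <- function(site, label) {
    m <- gregexpr(site, transcript, fixed = TRUE)[[1]]
    if (m[1] == -1L) return(integer())
    if (length(m) > 1L) {
      stopf("%s primer has %d sites on the transcript", label, length(m))
    }
    as.integer(m)
  }
  f_start <- find_sites(fwd_primer, "forward")
  r_start <- find_sites(revcomp(rev_primer), "reverse")
  if (length(f_start) == 0L || length(r_start) == 0L) return(NA_integer_)
  r_end <- r_start + nchar(rev_primer) - 1L
  if (r_start <= f_start) return(NA_integer_)  # wrong orientation
  as.integer(r_end - f_start + 1L)
}
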