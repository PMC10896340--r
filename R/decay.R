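#' Normalize a decay series to percent of t = 0
#'
#' Each signal is divided by the loading control at the same timepoint,
#' then expressed as a percentage of the t = 0 value:
#' `value(t) = (signal(t)/control(t)) / (signal(0)/control(0)) * 100`.
#' With replicates, normalization is per replicate (averaging, when
#' wanted, happens after normalization).
#'
#' @param series a `decay_series` data frame (see [simulate_decay()]) or
#'   any data frame with `transcript_id`, `time`, `signal` and optional
#'   `replicate` columns, containing a loading-control transcript.
#' @param control_id transcript id of the loading control.
#' @return A data frame `transcript_id`, `replicate`, `time`,
#'   `percent_remaining`; t = 0 rows are exactly 100.
#' @export
normalize_series <- function(series, control_id = "loading_control") {
  control_id <- attr(series, "control_id") %||% control_id
  if (is.null(series$replicate)) series$replicate <- 1L
  ctrl <- series[series$transcript_id == control_id, , drop = FALSE]
  if (nrow(ctrl) == 0L) stopf("no loading-control rows ('%s')", control_id)
  if (any(!is.finite(ctrl$signal)) || any(ctrl$signal <= 0)) {
    stopf("loading-control signal must be positive at every timepoint")
  }
  dat <- series[series$transcript_id != control_id, , drop = FALSE]
  ckey <- paste(ctrl$replicate, ctrl$time)
  ci <- match(paste(dat$replicate, dat$time), ckey)
  if (anyNA(ci)) stopf("loading control missing for some (replicate, time)")
  ratio <- dat$signal / ctrl$signal[ci]
  key0 <- paste(dat$transcript_id, dat$replicate)
  at0 <- dat$time == 0
  if (!all(key0 %in% key0[at0])) {
    stopf("every (transcript, replicate) needs a t = 0 measurement")
  }
  r0 <- ratio[at0][match(key0, key0[at0])]
  data.frame(
    transcript_id = dat$transcript_id,
    replicate = dat$replicate,
    time = dat$time,
    percent_remaining = ratio / r0 * 100,
    stringsAsFactors = FALSE
  )
}

#' Estimate an RNA half-life from a normalized decay series
#'
#' The half-life is the time at which 50% of the t = 0 RNA remains.
#' The default method reproduces the graphical read-off from a decay
#' plot: log-linear interpolation between the two timepoints bracketing
#' the 50% crossing,
#' `t_half = t_a + (t_b - t_a) * ln(v_a/50) / ln(v_a/v_b)`.
#' On a non-monotone series the first downward crossing is used. The
#' alternative `exp_fit` method fits a single exponential by least
#' squares on the log scale. If the series never drops below 50% within
#' the observed window, `not_reached` is flagged and `t_half` is `NA`.
#'
#' @param time timepoints in minutes (increasing, including 0).
#' @param value normalized percent-remaining values (100 at t = 0).
#' @param method `"interpolation"` (default) or `"exp_fit"`.
#' @return An object of class `halflife_estimate` with elements
#'   `t_half` (minutes), `method`, `not_reached`, `steady_state` (the
#'   t = 0 value) and the input series.
#' @export
#' @examples
#' estimate_half_life(c(0, 10, 20), c(100, 50, 25))     # exactly 10
#' estimate_half_life(c(0, 10, 20), c(100, 60, 30))     # ~12.63
estimate_half_life <- function(time, value,
                               method = c("interpolation", "exp_fit")) {
  method <- match.arg(method)
  stopifnot(length(time) == length(value))
  if (length(time) < 3L) stopf("at least 3 timepoints are required")
  o <- order(time)
  time <- time[o]; value <- value[o]
  out <- list(t_half = NA_real_, method = method, not_reached = FALSE,
              steady_state = value[1L], time = time, value = value)
  class(out) <- "halflife_estimate"

  if (method == "interpolation") {
    below <- value < 50
    if (!any(below)) {
      out$not_reached <- TRUE
      return(out)
    }
    # first downward crossing: first i with v[i] >= 50 and v[i+1] < 50
    i <- which(value[-length(value)] >= 50 & value[-1L] < 50)[1L]
    if (is.na(i)) {  # series starts below 50
      out$t_half <- time[which(below)[1L]]
      return(out)
    }
    va <- value[i]; vb <- value[i + 1L]
    out$t_half <- time[i] + (time[i + 1L] - time[i]) *
      log(va / 50) / log(va / vb)
  } else {
    pos <- value > 0
    if (sum(pos) < 2L) stopf("exp_fit needs at least 2 positive values")
    fit <- stats::lm(log(value[pos]) ~ time[pos])
    slope <- unname(stats::coef(fit)[2L])
    if (!is.finite(slope) || slope >= 0) {
      out$not_reached <- TRUE
      return(out)
    }
    out$t_half <- -log(2) / slope
    if (out$t_half > max(time)) out$not_reached <- TRUE
  }
  out
}

#' @export
print.halflife_estimate <- function(x, ...) {
  if (x$not_reached || is.na(x$t_half)) {
    cat(sprintf("Half-life not reached within the observed window (%s, max t = %g min)\n",
                x$method, max(x$time)))
  } else {
    cat(sprintf("Estimated half-life: %.3f min (%s over %d timepoints)\n",
                x$t_half, x$method, length(x$time)))
  }
  invisible(x)
}

#' @export
coef.halflife_estimate <- function(object, ...) {
  c(t_half = object$t_half)
}

#' Attribute a steady-state difference to transcription vs stability
#'
#' If two cell states transcribe a gene equally and only stability
#' differs, the ratio of half-lives should match the ratio of steady-
#' state levels; if transcription differs, the steady-state ratio will
#' exceed what the half-life ratio can account for. Both ratios are
#' computed case/control; the discrepancy is
#' `steady_state_ratio / half_life_ratio` — the fold-difference left
#' over after stability is accounted for.
#'
#' Classification works on fold magnitudes (`m(x) = max(x, 1/x)`): the
#' difference is `transcription_dominant` when the residual discrepancy
#' is at least `threshold`-fold while the half-life ratio is below it;
#' `stability_dominant` in the opposite case; `mixed` when both or
#' neither component reaches the threshold. The call is symmetric under
#' case/control swap (all ratios invert).
#'
#' @param case,control decay series for one transcript each: data
#'   frames with `time`, `signal` and either a `control` column (the
#'   loading-control signal per timepoint) or already-normalized
#'   `percent_remaining`; replicates (column `replicate`) are
#'   normalized individually then averaged.
#' @param threshold fold-change threshold (default 2).
#' @param method half-life method, see [estimate_half_life()].
#' @return An object of class `attribution_result`:
#'   `steady_state_ratio` (case/control at t = 0, loading-control
#'   corrected), `half_life_ratio`, `discrepancy`, `attribution`
#'   (`transcription_dominant`, `stability_dominant`, `mixed`, or
#'   `indeterminate` when a half-life was not reached).
#' @export
attribute_difference <- function(case, control, threshold = 2,
                                 method = "interpolation") {
  prep <- function(d) {
    if (is.null(d$replicate)) d$replicate <- 1L
    if (!is.null(d$percent_remaining)) {
      s0 <- NA_real_
      pr <- d[, c("replicate", "time", "percent_remaining")]
    } else {
      if (is.null(d$control)) {
        stopf("series needs either 'percent_remaining' or a 'control' column")
      }
      ratio <- d$signal / d$control
      r0 <- ratio[d$time == 0][match(d$replicate, d$replicate[d$time == 0])]
      s0 <- mean(ratio[d$time == 0])
      pr <- data.frame(replicate = d$replicate, time = d$time,
                       percent_remaining = ratio / r0 * 100)
    }
    avg <- stats::aggregate(percent_remaining ~ time, data = pr, FUN = mean)
    list(s0 = s0, time = avg$time, value = avg$percent_remaining)
  }
  pc <- prep(case)
  pk <- prep(control)
  if (is.na(pc$s0) || is.na(pk$s0)) {
    stopf("steady-state attribution needs un-normalized signal and control columns")
  }
  hc <- estimate_half_life(pc$time, pc$value, method = method)
  hk <- estimate_half_life(pk$time, pk$value, method = method)
  ss_ratio <- pc$s0 / pk$s0
  out <- list(steady_state_ratio = ss_ratio,
              half_life_ratio = NA_real_, discrepancy = NA_real_,
              attribution = "indeterminate", threshold = threshold,
              case_half_life = hc$t_half, control_half_life = hk$t_half)
  class(out) <- "attribution_result"
  if (hc$not_reached || hk$not_reached) return(out)
  hl_ratio <- hc$t_half / hk$t_half
  disc <- ss_ratio / hl_ratio
  mag <- function(x) max(x, 1 / x)
  out$half_life_ratio <- hl_ratio
  out$discrepancy <- disc
  out$attribution <- if (mag(disc) >= threshold && mag(hl_ratio) < threshold) {
    "transcription_dominant"
  } else if (mag(hl_ratio) >= threshold && mag(disc) < threshold) {
    "stability_dominant"
  } else {
    "mixed"
  }
  out
}

#' @export
print.attribution_result <- function(x, ...) {
  cat("Transcription-vs-stability attribution\n")
  cat(sprintf("  steady-state ratio (case/control): %.3f\n",
              x$steady_state_ratio))
  cat(sprintf("  half-life ratio:                   %.3f\n",
              x$half_life_ratio))
  cat(sprintf("  residual discrepancy:              %.3f\n", x$discrepancy))
  cat(sprintf("  attribution (threshold %g-fold): %s\n",
              x$threshold, x$attribution))
  invisible(x)
}

#' Processed fraction L/(L+U)
#'
#' Fraction of trailer-probed pre-tRNA signal in the intron-spliced
#' (lower, L) band over total (L plus the intron-containing upper band
#' U): the fraction of transcript output already processed through
#' splicing.
#'
#' @param L,U non-negative band signals (vectorized); a pair with both
#'   zero is an error.
#' @return `L / (L + U)`.
#' @export
#' @examples
#' processed_fraction(1, 1)  # 0.5
#' processed_fraction(1, 0)  # 1
processed_fraction <- function(L, U) {
  if (any(L < 0) || any(U < 0)) stopf("band signals must be non-negative")
  if (any(L + U == 0)) stopf("L and U cannot both be zero")
  L / (L + U)
}

#' Oligo probe melting and incubation temperature
#'
#' Melting temperature of a DNA oligo probe by the salt/GC/length
#' formula `Tm = 16.6 log10(M) + 0.41 Pgc + 81.5 - 675/L - 0.65`
#' (M molar monovalent salt, Pgc percent G+C, L length in nt; the
#' trailing -0.65 constant is applied verbatim). The hybridization /
#' standardized-wash incubation temperature Ti is 15 degrees C below
#' Tm.
#'
#' @param sequence unambiguous DNA oligo sequence (A/C/G/T), length
#'   >= 10.
#' @param M molar salt concentration (default 0.5).
#' @return An object of class `probe_spec`: `sequence`, `L`, `Pgc`,
#'   `M`, `Tm`, `Ti` (degrees C).
#' @export
#' @examples
#' probe_tm_ti(paste(rep(c("G", "C", "A", "T"), 5), collapse = ""))
probe_tm_ti <- function(sequence, M = 0.5) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  L <- nchar(sequence)
  if (L < 10L) stopf("probe must be at least 10 nt")
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  if (!all(chars %in% BASES)) {
    stopf("ambiguous or non-DNA base in probe: %s",
          paste(unique(chars[!chars %in% BASES]), collapse = ", "))
  }
  if (!is.numeric(M) || M <= 0) stopf("M must be positive")
  Pgc <- 100 * sum(chars %in% c("G", "C")) / L
  Tm <- 16.6 * log10(M) + 0.41 * Pgc + 81.5 - 675 / L - 0.65
  out <- list(sequence = sequence, L = L, Pgc = Pgc, M = M,
              Tm = Tm, Ti = Tm - 15)
  class(out) <- "probe_spec"
  out
}

#' @export
print.probe_spec <- function(x, ...) {
  cat(sprintf("Probe %s (%d nt, %.1f%% GC, M = %g)\n",
              x$sequence, x$L, x$Pgc, x$M))
  cat(sprintf("  Tm = %.2f C, Ti = %.2f C\n", x$Tm, x$Ti))
  invisible(x)
}

#' Correct probe signal for isotope decay
#'
#' Radioactive probe signal acquired `elapsed_days` after labelling is
#' scaled back up by `2^(elapsed / half_life)`. The default isotope
#' half-life is 14.3 days (32P).
#'
#' @param signal measured signal (e.g. intensity/pixel/minute).
#' @param elapsed_days days since probe labelling (>= 0).
#' @param isotope_half_life_days isotope half-life in days.
#' @return The decay-corrected signal.
#' @export
decay_correct_signal <- function(signal, elapsed_days,
                                 isotope_half_life_days = 14.3) {
  if (any(elapsed_days < 0)) stopf("elapsed_days must be >= 0")
  if (any(isotope_half_life_days <= 0)) {
    stopf("isotope half-life must be positive")
  }
  signal * 2^(elapsed_days / isotope_half_life_days)
}
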