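#' Simulate an actinomycin-D decay time course
#'
#' Signal follows first-order decay,
#' `signal(t) = S0 * exp(-log(2) * t / t_half)`, multiplied by
#' log-normal noise with coefficient of variation `noise_cv` (mean 1).
#' A stable loading-control transcript (effectively infinite half-life,
#' like U5 snRNA on a northern blot) is included for normalization.
#'
#' @param true_half_lives named numeric vector of half-lives in minutes
#'   (all positive).
#' @param timepoints harvest times in minutes; must include 0 (the
#'   untreated steady-state sample).
#' @param noise_cv coefficient of variation of the multiplicative
#'   log-normal noise.
#' @param n_replicates replicate time courses per transcript.
#' @param s0 signal at t = 0 before noise (arbitrary units).
#' @param control_id transcript id of the loading-control row.
#' @param seed integer RNG seed.
#' @return A data frame of class `decay_series`: `transcript_id`,
#'   `replicate`, `time`, `signal`. True half-lives are kept in the
#'   `"half_lives"` attribute.
#' @export
#' @examples
#' d <- simulate_decay(c(tyr = 10), timepoints = c(0, 10, 20),
#'                     noise_cv = 0, seed = 1)
#' subset(d, transcript_id == "tyr")$signal  # 100, 50, 25
simulate_decay <- function(true_half_lives, timepoints = c(0, 10, 20, 40, 80),
                           noise_cv = 0.1, n_replicates = 1L, s0 = 100,
                           control_id = "loading_control", seed = 1L) {
  if (is.null(names(true_half_lives)) || any(names(true_half_lives) == "")) {
    stopf("true_half_lives must be a named vector")
  }
  if (any(!is.finite(true_half_lives)) || any(true_half_lives <= 0)) {
    stopf("half-lives must be positive and finite")
  }
  if (!any(timepoints == 0)) stopf("timepoints must include 0")
  if (control_id %in% names(true_half_lives)) {
    stopf("'%s' is reserved for the loading control", control_id)
  }
  hl <- c(true_half_lives, stats::setNames(Inf, control_id))
  sdlog <- sqrt(log1p(noise_cv^2))
  with_seed(seed, {
    grid <- expand.grid(transcript_id = names(hl),
                        replicate = seq_len(n_replicates),
                        time = sort(timepoints),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- s0 * 2^(-grid$time / hl[grid$transcript_id])
    noise <- if (noise_cv > 0) {
      stats::rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
    } else 1
    grid$signal <- mu * noise
    grid <- grid[order(grid$transcript_id, grid$replicate, grid$time), ]
    rownames(grid) <- NULL
    class(grid) <- c("decay_series", "data.frame")
    attr(grid, "half_lives") <- hl
    attr(grid, "control_id") <- control_id
    grid
  })
}
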