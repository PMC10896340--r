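#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator into a validated
#' configuration object. Defaults describe a small but realistic Pol III
#' deficiency experiment: tRNA gene models with a 4T terminator in ~70%
#' of genes (the fraction reported for the high-confidence human set),
#' introns in ~6.5% of genes (28/429), 15-50 nt size-selected reads, and
#' negative-binomial locus abundances.
#'
#' `condition` selects the per-class abundance profile applied by
#' [simulate_reads()]:
#' \describe{
#'   \item{WT}{all classes at baseline.}
#'   \item{deficient}{tRF-1 multiplied by `trf1_enrichment`, tRF-5 by
#'     `trf5_factor`, tRF-3 by `trf3_factor` (tRF-5 more depleted than
#'     tRF-3), miRNAs by `mirna_factor`.}
#'   \item{la_kd}{tRF-1 multiplied by `la_kd_trf1_factor` (La knockdown
#'     selectively destabilizes 3'-trailer fragments).}
#' }
#'
#' @param n_genes number of tRNA genes to simulate.
#' @param frac_intron fraction of genes carrying a single intron.
#' @param frac_4T fraction of genes whose planted T1 terminator is
#'   exactly 4 Ts (the remainder get 5-7 Ts).
#' @param trailer_length_range integer range (nt) for the 3'-trailer,
#'   i.e. the offset of the planted T run within the 150-nt downstream
#'   window; must lie within `[1, 150]`.
#' @param n_mirnas number of decoy mature miRNAs.
#' @param condition one of `"WT"`, `"deficient"`, `"la_kd"`.
#' @param class_weights named expected read fractions per class; must
#'   sum to 1. Names: `tRF5`, `tRF3`, `tRF1`, `miRNA`.
#' @param reads_per_sample expected library size per sample.
#' @param read_length_range allowed insert length range (nt), within
#'   `[15, 50]`.
#' @param dispersion negative-binomial dispersion of locus counts
#'   (0 gives Poisson counts).
#' @param trf1_enrichment,trf5_factor,trf3_factor,mirna_factor
#'   multipliers applied under `condition = "deficient"`.
#' @param la_kd_trf1_factor tRF-1 multiplier under `condition = "la_kd"`.
#' @param readthrough_frac fraction of tRF-1 reads extending beyond the
#'   T1 terminator.
#' @param error_rate per-base substitution rate applied to reads
#'   (default 0: error-free reads with exact ground truth).
#' @param seed integer RNG seed.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @seealso [simulate_trna_genes()], [simulate_reads()],
#'   [sim_config_from_yaml()]
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 10, reads_per_sample = 1000, seed = 1)
#' cfg$frac_4T
sim_config <- function(n_genes = 60L,
                       frac_intron = 0.065,
                       frac_4T = 0.7,
                       trailer_length_range = c(17L, 36L),
                       n_mirnas = 100L,
                       condition = c("WT", "deficient", "la_kd"),
                       class_weights = c(tRF5 = 0.25, tRF3 = 0.25,
                                         tRF1 = 0.20, miRNA = 0.30),
                       reads_per_sample = 200000L,
                       read_length_range = c(15L, 50L),
                       dispersion = 0.1,
                       trf1_enrichment = 3,
                       trf5_factor = 0.5,
                       trf3_factor = 0.7,
                       mirna_factor = 1.25,
                       la_kd_trf1_factor = 0.5,
                       readthrough_frac = 0.1,
                       error_rate = 0,
                       seed = 1L) {
  condition <- match.arg(condition)
  frac_ok <- function(x) is.numeric(x) && length(x) == 1L &&
    !is.na(x) && x >= 0 && x <= 1
  if (!frac_ok(frac_intron)) stopf("frac_intron must be in [0, 1]")
  if (!frac_ok(frac_4T)) stopf("frac_4T must be in [0, 1]")
  if (!frac_ok(readthrough_frac)) stopf("readthrough_frac must be in [0, 1]")
  if (!frac_ok(error_rate)) stopf("error_rate must be in [0, 1]")
  if (abs(sum(class_weights) - 1) > 1e-9) {
    stopf("class_weights must sum to 1 (got %.12f)", sum(class_weights))
  }
  if (any(class_weights < 0)) stopf("class_weights must be non-negative")
  needed <- c("tRF5", "tRF3", "tRF1", "miRNA")
  if (!all(needed %in% names(class_weights))) {
    stopf("class_weights needs names: %s", paste(needed, collapse = ", "))
  }
  rlr <- as.integer(read_length_range)
  if (length(rlr) != 2L || rlr[1] > rlr[2] || rlr[1] < 15L || rlr[2] > 50L) {
    stopf("read_length_range must be an interval within [15, 50]")
  }
  tlr <- as.integer(trailer_length_range)
  if (length(tlr) != 2L || tlr[1] > tlr[2] || tlr[1] < 1L || tlr[2] > 150L) {
    stopf("trailer_length_range must be an interval within [1, 150]")
  }
  if (!is.numeric(dispersion) || dispersion < 0) {
    stopf("dispersion must be >= 0")
  }
  for (nm in c("trf1_enrichment", "trf5_factor", "trf3_factor",
               "mirna_factor", "la_kd_trf1_factor")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || v <= 0) {
      stopf("%s must be a positive scalar", nm)
    }
  }
  cfg <- list(
    n_genes = as.integer(n_genes),
    frac_intron = frac_intron,
    frac_4T = frac_4T,
    trailer_length_range = tlr,
    n_mirnas = as.integer(n_mirnas),
    condition = condition,
    class_weights = class_weights[needed],
    reads_per_sample = as.numeric(reads_per_sample),
    read_length_range = rlr,
    dispersion = dispersion,
    trf1_enrichment = trf1_enrichment,
    trf5_factor = trf5_factor,
    trf3_factor = trf3_factor,
    mirna_factor = mirna_factor,
    la_kd_trf1_factor = la_kd_trf1_factor,
    readthrough_frac = readthrough_frac,
    error_rate = error_rate,
    seed = as.integer(seed)
  )
  class(cfg) <- "sim_config"
  cfg
}

#' Read a simulation configuration from a YAML file
#'
#' Fields in the YAML map onto [sim_config()] arguments; unset fields
#' keep their defaults.
#'
#' @param path path to a YAML file.
#' @return A `sim_config` object.
#' @export
sim_config_from_yaml <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("the 'yaml' package is required to read YAML configurations")
  }
  vals <- yaml::read_yaml(path)
  if (!is.null(vals$class_weights)) {
    vals$class_weights <- unlist(vals$class_weights)
  }
  do.call(sim_config, vals)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Small-RNA simulation configuration\n")
  cat(sprintf("  %d tRNA genes (%.0f%% 4T terminators, %.1f%% with intron)\n",
              x$n_genes, 100 * x$frac_4T, 100 * x$frac_intron))
  cat(sprintf("  condition: %s; %s reads/sample, lengths %d-%d nt\n",
              x$condition, format(x$reads_per_sample, big.mark = ","),
              x$read_length_range[1], x$read_length_range[2]))
  cat(sprintf("  class weights: %s\n",
              paste(sprintf("%s=%.2f", names(x$class_weights),
                            x$class_weights), collapse = " ")))
  invisible(x)
}
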