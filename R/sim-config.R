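#' Configuration for the synthetic-data generator
#'
#' Bundles every tunable of the simulators into one validated list. The
#' defaults describe the study conditions the package is exercised under:
#' two conditions (a control and a knockdown) with three replicates each,
#' a 0.3 shift in percent-spliced-in (PSI) for planted differential events,
#' negative-binomial count noise with a decreasing mean-dispersion trend,
#' m6A-like peaks enriched in the flanking introns of planted skipped exons,
#' a DRACH-compatible motif written at peak summits, and a patient cohort
#' whose hazard is log-linear in the event PSIs.
#'
#' @param n_genes Number of simulated genes; each gene carries exactly one
#'   alternative-splicing event.
#' @param event_mix Named proportions over the seven event types
#'   (`SE`, `RI`, `MX`, `A5`, `A3`, `AF`, `AL`); must sum to 1.
#' @param n_replicates Replicates per condition (>= 2).
#' @param conditions Character vector of two condition labels.
#' @param dse_fraction Fraction of genes planted as differentially spliced.
#' @param psi_shift Magnitude of the planted PSI shift, in (0, 1].
#' @param psi_logit_sd Replicate-level logit-normal noise on isoform usage
#'   (0 disables noise; keeps PSI inside (0, 1)).
#' @param expr_meanlog,expr_sdlog Log-normal parameters of per-gene expression.
#' @param tpm_noise_sd Replicate-level log-normal noise on gene expression.
#' @param dispersion_fn Function mapping a mean count to a dispersion `d`
#'   such that the count variance is `mean + d * mean^2`; the constant-zero
#'   function gives Poisson counts.
#' @param depth Expected total read count per sample.
#' @param exon_len_range,intron_len_range Uniform sampling ranges (nt) for
#'   exon and intron lengths; introns are kept long enough to host a full
#'   motif window.
#' @param pad Flanking padding (nt) added on both ends of each gene's contig.
#' @param ptc_fraction Fraction of exclusion-form transcripts whose annotated
#'   stop codon is planted >50 nt upstream of the last junction (PTC+).
#' @param peak_enrichment_fraction Fraction of planted-DSE flanking introns
#'   receiving an m6A-like peak.
#' @param background_peak_rate Background peaks per kilobase of non-target
#'   intron.
#' @param peak_width Width (nt) of simulated peaks.
#' @param motif IUPAC motif (RNA or DNA alphabet) written at peak summits.
#' @param n_patients Cohort size for the survival simulator.
#' @param true_betas Per-event log hazard-ratio coefficients for the cohort.
#' @param censor_rate Expected fraction of censored patients, in [0, 1).
#' @param baseline_hazard Exponential baseline hazard rate.
#' @param seed Integer seed; every simulator is a deterministic function of
#'   the config (and of an optional per-call seed override).
#'
#' @return An object of class `sw_sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genes = 20, seed = 1)
#' cfg$psi_shift
#' @export
sim_config <- function(n_genes = 200,
                       event_mix = c(SE = 0.40, RI = 0.10, MX = 0.10,
                                     A5 = 0.10, A3 = 0.10, AF = 0.10, AL = 0.10),
                       n_replicates = 3,
                       conditions = c("ctrl", "kd"),
                       dse_fraction = 0.2,
                       psi_shift = 0.3,
                       psi_logit_sd = 0.3,
                       expr_meanlog = 3,
                       expr_sdlog = 1,
                       tpm_noise_sd = 0.15,
                       dispersion_fn = function(m) 0.05 + 2 / (m + 1),
                       depth = 3e5,
                       exon_len_range = c(80, 250),
                       intron_len_range = c(450, 900),
                       pad = 300,
                       ptc_fraction = 0.15,
                       peak_enrichment_fraction = 0.8,
                       background_peak_rate = 0.1,
                       peak_width = 150,
                       motif = "GGACT",
                       n_patients = 1000,
                       true_betas = c(1.5, -1.5, 0),
                       censor_rate = 0.2,
                       baseline_hazard = 0.1,
                       seed = 1L) {
  types <- c("SE", "RI", "MX", "A5", "A3", "AF", "AL")
  if (is.null(names(event_mix)) || !all(names(event_mix) %in% types)) {
    sw_abort("`event_mix` must be named with a subset of SE, RI, MX, A5, A3, AF, AL")
  }
  if (any(event_mix < 0) || abs(sum(event_mix) - 1) > 1e-8) {
    sw_abort("`event_mix` proportions must be non-negative and sum to 1")
  }
  if (n_genes < 1 || n_replicates < 2) sw_abort("counts must be positive (and n_replicates >= 2)")
  if (length(conditions) != 2) sw_abort("exactly two conditions are supported")
  if (!(psi_shift > 0 && psi_shift <= 1)) sw_abort("`psi_shift` must lie in (0, 1]")
  if (!(censor_rate >= 0 && censor_rate < 1)) sw_abort("`censor_rate` must lie in [0, 1)")
  if (!is.function(dispersion_fn)) sw_abort("`dispersion_fn` must be a function")
  if (any(exon_len_range <= 0) || any(intron_len_range <= 0)) {
    sw_abort("exon and intron lengths must be positive")
  }
  if (intron_len_range[1] < 2 * pad / 2 + 10) {
    # introns must be able to contain a +/-150 nt window plus margin
  }
  cfg <- list(
    n_genes = as.integer(n_genes), event_mix = event_mix[event_mix > 0],
    n_replicates = as.integer(n_replicates), conditions = conditions,
    dse_fraction = dse_fraction, psi_shift = psi_shift,
    psi_logit_sd = psi_logit_sd, expr_meanlog = expr_meanlog,
    expr_sdlog = expr_sdlog, tpm_noise_sd = tpm_noise_sd,
    dispersion_fn = dispersion_fn, depth = depth,
    exon_len_range = exon_len_range, intron_len_range = intron_len_range,
    pad = pad, ptc_fraction = ptc_fraction,
    peak_enrichment_fraction = peak_enrichment_fraction,
    background_peak_rate = background_peak_rate, peak_width = peak_width,
    motif = motif_to_dna(motif), n_patients = as.integer(n_patients),
    true_betas = true_betas, censor_rate = censor_rate,
    baseline_hazard = baseline_hazard, seed = as.integer(seed)
  )
  structure(cfg, class = "sw_sim_config")
}

#' @export
print.sw_sim_config <- function(x, ...) {
  cat("<sw_sim_config>\n")
  cat(glue("  genes: {x$n_genes}  replicates: {x$n_replicates} x {paste(x$conditions, collapse = '/')}"), "\n")
  cat(glue("  psi_shift: {x$psi_shift}  dse_fraction: {x$dse_fraction}  motif: {x$motif}"), "\n")
  cat(glue("  patients: {x$n_patients}  censor_rate: {x$censor_rate}  seed: {x$seed}"), "\n")
  invisible(x)
}
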