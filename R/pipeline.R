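#' Run the full analysis pipeline on files
#'
#' Ties the stages together in the order the analysis flows: event
#' derivation from the annotation, per-knockdown PSI and differential
#' splicing, combination of knockdown runs, negative-binomial differential
#' expression, intronic-m6A (and PTC) enrichment among differentially
#' skipped exons, motif density around peak summits versus matched random
#' intronic regions, and the PSI-based survival signature. Every stage
#' writes a TSV under `out_dir`; a JSON manifest records inputs, seeds,
#' thresholds and per-stage record counts. Input paths are validated before
#' any computation starts.
#'
#' @param out_dir Output directory (created if needed).
#' @param annotation_gtf Path to the GTF annotation.
#' @param quant Named list of quantification sets (one per knockdown
#'   experiment); each element is `list(paths = c(sample = path, ...),
#'   conditions = c(sample = condition, ...))`.
#' @param control,treatment Condition labels compared by [delta_psi()] /
#'   [nb_test()].
#' @param peaks_bed Optional BED6+summit peak file (enables the m6A stage).
#' @param genome_fasta Optional genome FASTA (enables the motif stage;
#'   required when `peaks_bed` is given and `motif` is non-`NULL`).
#' @param clinical_tsv Optional clinical table (enables the survival stage).
#' @param motif IUPAC motif profiled around summits (default `"DRACH"`;
#'   `NULL` disables the motif stage).
#' @param dse_fdr FDR threshold for a bona fide differential splicing event.
#' @param half_width Summit window half-width (nt).
#' @param profile_range Reported profile half-range (nt).
#' @param q Risk-score percentile for patient stratification.
#' @param seed Integer seed used by every stochastic stage.
#' @return Invisibly, a named list of in-memory stage results plus
#'   `manifest`.
#' @export
run_pipeline <- function(out_dir, annotation_gtf, quant,
                         control, treatment,
                         peaks_bed = NULL, genome_fasta = NULL,
                         clinical_tsv = NULL, motif = "DRACH",
                         dse_fdr = 0.05, half_width = 150, profile_range = 80,
                         q = 0.75, seed = 1L) {
  # fail fast on configuration before computing anything
  inputs <- c(annotation_gtf,
              unlist(lapply(quant, function(x) x$paths)),
              peaks_bed, genome_fasta, clinical_tsv)
  missing <- inputs[!file.exists(inputs)]
  if (length(missing) > 0) {
    sw_abort(glue("run_pipeline: missing input file(s): {paste(missing, collapse = ', ')}"))
  }
  if (!is.null(peaks_bed) && !is.null(motif) && is.null(genome_fasta)) {
    sw_abort("run_pipeline: the motif stage needs `genome_fasta`")
  }
  if (!(dse_fdr > 0 && dse_fdr < 1) || q <= 0 || q >= 1 || half_width <= 0) {
    sw_abort("run_pipeline: thresholds must lie in (0, 1) and window sizes be positive")
  }
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  results <- list()
  manifest <- list(seed = seed, thresholds = list(dse_fdr = dse_fdr, q = q),
                   windows = list(half_width = half_width, profile_range = profile_range),
                   inputs = list(annotation = annotation_gtf, peaks = peaks_bed,
                                 genome = genome_fasta, clinical = clinical_tsv),
                   stages = list())

  annotation <- read_gtf(annotation_gtf)
  events <- build_events(annotation)
  write_event_table(events, file.path(out_dir, "events.tsv"))
  results$events <- events
  manifest$stages$events <- list(n_events = nrow(events),
                                 n_by_type = as.list(table(events$type)))

  dse_runs <- list()
  for (nm in names(quant)) {
    qt <- read_quant_tables(quant[[nm]]$paths, quant[[nm]]$conditions)
    psi <- compute_psi(events, qt)
    readr::write_tsv(psi, file.path(out_dir, glue("psi_{nm}.tsv")))
    dse <- delta_psi(psi, control, treatment)
    readr::write_tsv(dse, file.path(out_dir, glue("dse_{nm}.tsv")))
    dse_runs[[nm]] <- dse
    manifest$stages[[glue("dse_{nm}")]] <-
      list(n_tested = nrow(dse), n_significant = sum(dse$fdr < dse_fdr),
           n_dropped = attr(dse, "dropped"))
    if (nm == names(quant)[1]) results$quant <- qt
  }
  results$dse_runs <- dse_runs

  dse_final <- if (length(dse_runs) >= 2) {
    comb <- combine_knockdowns(dse_runs[[1]], dse_runs[[2]], fdr_threshold = dse_fdr)
    readr::write_tsv(comb, file.path(out_dir, "dse_combined.tsv"))
    manifest$stages$dse_combined <- list(n_retained = nrow(comb))
    results$dse_combined <- comb
    tibble(event_id = dse_runs[[1]]$event_id,
           significant = dse_runs[[1]]$event_id %in% comb$event_id)
  } else {
    d <- dse_runs[[1]]
    tibble(event_id = d$event_id, significant = d$fdr < dse_fdr)
  }

  deg <- nb_test(results$quant |>
                   transmute(feature_id = .data$transcript_id, .data$sample,
                             .data$condition, count = round(.data$count)) |>
                   filter_detected(),
                 control, treatment)
  readr::write_tsv(deg, file.path(out_dir, "deg.tsv"))
  results$deg <- deg
  manifest$stages$diffexpr <- list(n_tested = nrow(deg),
                                   n_significant = sum(deg$fdr < 0.05))

  if (!is.null(peaks_bed)) {
    peaks <- read_bed(peaks_bed)
    m6a_flags <- assign_peaks(peaks, events)
    enr <- enrichment_test(dse_final |> semi_join(m6a_flags, by = "event_id"),
                           m6a_flags)
    readr::write_tsv(tidy(enr), file.path(out_dir, "m6a_enrichment.tsv"))
    results$m6a <- enr
    manifest$stages$m6a <- list(p_value = enr$p_value,
                                frac_m6a_significant = enr$frac_m6a_significant)

    nmd <- flag_nmd(annotation)
    if (nrow(nmd) > 0) {
      se_universe <- dse_final |>
        semi_join(events |> filter(.data$type == "SE"), by = "event_id")
      ptc <- ptc_association(events, nmd, se_universe)
      readr::write_tsv(tidy(ptc), file.path(out_dir, "ptc_association.tsv"))
      results$ptc <- ptc
      manifest$stages$ptc <- list(p_value = ptc$p_value)
    }

    if (!is.null(motif)) {
      genome <- Biostrings::readDNAStringSet(genome_fasta)
      win_pk <- extract_windows(peaks, genome, half_width)
      win_rd <- match_random_regions(peaks, annotation, genome, half_width,
                                     seed = seed)
      rng <- -profile_range:profile_range
      prof <- bind_rows(
        density_profile(win_pk, motif, rng, label = "peaks"),
        density_profile(win_rd, motif, rng, label = "random"))
      readr::write_tsv(prof, file.path(out_dir, "motif_profile.tsv"))
      ce <- center_enrichment(win_pk, win_rd, motif, seed = seed)
      results$motif <- list(profile = prof, center = ce)
      manifest$stages$motif <- list(ratio = ce$ratio, p_value = ce$p_value,
                                    n_windows = nrow(win_pk))
    }
  }

  if (!is.null(clinical_tsv)) {
    cohort <- read_clinical(clinical_tsv)
    model <- cox_lasso(cohort, q = q, seed = seed)
    jsonlite::write_json(
      list(events = model$events, beta = as.list(model$beta),
           penalty = model$penalty, cutoff = model$cutoff, q = model$q),
      file.path(out_dir, "risk_model.json"), auto_unbox = TRUE, digits = NA)
    scored <- risk_score(model, cohort)
    scored$risk_group <- percentile_split(scored$risk_score, q = q)
    readr::write_tsv(scored |> select("patient_id", "risk_score", "risk_group"),
                     file.path(out_dir, "risk_scores.tsv"))
    km <- km_estimate(scored$time, scored$status, scored$risk_group)
    readr::write_tsv(km, file.path(out_dir, "km.tsv"))
    lr <- logrank_test(scored$time, scored$status, scored$risk_group)
    readr::write_tsv(tibble(test = "logrank_high_vs_low",
                            statistic = lr$statistic, p_value = lr$p_value),
                     file.path(out_dir, "survival_tests.tsv"))
    results$survival <- list(model = model, scores = scored, km = km, logrank = lr)
    manifest$stages$survival <- list(
      n_patients = nrow(scored),
      n_high = sum(scored$risk_group == "high"),
      n_low = sum(scored$risk_group == "low"),
      logrank_p = lr$p_value)
  }

  manifest$stages <- manifest$stages
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  results$manifest <- manifest
  invisible(results)
}
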