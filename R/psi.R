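#' Per-sample percent spliced-in (PSI) from transcript TPMs
#'
#' For each event and sample, PSI is the summed TPM of the inclusion
#' transcripts divided by the summed TPM of all transcripts participating in
#' the event. Events whose total abundance in a sample is (numerically) zero
#' get an undefined PSI (`NA`); condition-level expression filtering is
#' applied later by [delta_psi()]. The result is invariant to a uniform
#' rescaling of all TPMs within a sample.
#'
#' @param events Event tibble from [build_events()].
#' @param quant Long quantification tibble with columns `transcript_id`,
#'   `sample`, `condition`, `tpm` (e.g. `sim_quant(...)$quant` or
#'   [read_quant_tables()]).
#' @return A tibble `event_id`, `type`, `sample`, `condition`, `psi`,
#'   `total_tpm`.
#' @export
compute_psi <- function(events, quant) {
  assert_columns(quant, c("transcript_id", "sample", "condition", "tpm"), "quant")
  ev_tx <- events |>
    select("event_id", "type", "inclusion", "exclusion") |>
    pivot_longer(c("inclusion", "exclusion"), names_to = "role",
                 values_to = "transcript_id") |>
    unnest("transcript_id")
  unknown <- setdiff(ev_tx$transcript_id, unique(quant$transcript_id))
  if (length(unknown) > 0) {
    bad <- ev_tx |> filter(.data$transcript_id %in% unknown)
    sw_abort(glue(
      "transcript(s) {paste(head(unknown, 5), collapse = ', ')} referenced by ",
      "event(s) {paste(head(unique(bad$event_id), 3), collapse = ', ')} ",
      "are absent from the quantification"))
  }
  ev_tx |>
    inner_join(quant |> select("transcript_id", "sample", "condition", "tpm"),
               by = "transcript_id", relationship = "many-to-many") |>
    group_by(.data$event_id, .data$type, .data$sample, .data$condition) |>
    summarise(
      inc_tpm = sum(.data$tpm[.data$role == "inclusion"]),
      total_tpm = sum(.data$tpm), .groups = "drop") |>
    mutate(psi = ifelse(.data$total_tpm > 1e-12,
                        .data$inc_tpm / .data$total_tpm, NA_real_)) |>
    select("event_id", "type", "sample", "condition", "psi", "total_tpm")
}

#' Differential PSI between two conditions with an empirical significance
#'
#' The difference in mean PSI (condition B minus condition A) is assessed
#' against an empirical null built from between-replicate PSI fluctuations:
#' within each condition all replicate-pair PSI differences are collected,
#' rescaled by `sqrt((1/nA + 1/nB) / 2)` so their spread matches that of a
#' difference of condition means, and pooled within equal-occupancy bins of
#' log10 mean event abundance. The p-value of an event is the add-one tail
#' frequency of its |dPSI| in its abundance bin; FDR is Benjamini-Hochberg.
#'
#' Events are dropped (and counted in the `dropped` attribute) when their
#' PSI is undefined in more than half the samples of either condition or
#' when their mean total TPM falls below `min_total_tpm` in either condition.
#'
#' @param psi Output of [compute_psi()].
#' @param cond_a,cond_b Condition labels; dPSI is `mean(B) - mean(A)`.
#' @param min_total_tpm Expression floor on per-condition mean total TPM.
#' @param n_bins Target number of abundance bins for the null (reduced when
#'   few events are available so each bin keeps ~25 events).
#' @return A tibble `event_id`, `type`, `mean_psi_a`, `mean_psi_b`, `dpsi`,
#'   `p_value`, `fdr`, `sign`, sorted by p-value, with a `dropped` attribute.
#' @export
delta_psi <- function(psi, cond_a, cond_b, min_total_tpm = 1, n_bins = 10) {
  assert_columns(psi, c("event_id", "sample", "condition", "psi", "total_tpm"), "psi")
  if (!all(c(cond_a, cond_b) %in% psi$condition)) {
    sw_abort("`cond_a` and `cond_b` must both be present in `psi$condition`")
  }
  psi <- psi |> filter(.data$condition %in% c(cond_a, cond_b))
  n_samples <- psi |> distinct(.data$condition, .data$sample) |> count(.data$condition)
  if (any(n_samples$n < 2)) sw_abort("need at least 2 replicates per condition")
  n_a <- n_samples$n[n_samples$condition == cond_a]
  n_b <- n_samples$n[n_samples$condition == cond_b]

  per_event <- psi |>
    group_by(.data$event_id, .data$type, .data$condition) |>
    summarise(mean_psi = mean(.data$psi, na.rm = TRUE),
              n_def = sum(!is.na(.data$psi)), n = n(),
              mean_total = mean(.data$total_tpm), .groups = "drop")
  keep <- per_event |>
    group_by(.data$event_id) |>
    filter(all(.data$n_def > .data$n / 2), all(.data$mean_total >= min_total_tpm)) |>
    ungroup()
  dropped <- length(unique(per_event$event_id)) - length(unique(keep$event_id))
  if (dropped > 0) {
    inform(glue("delta_psi: dropped {dropped} event(s) below the expression/coverage floor"))
  }
  if (nrow(keep) == 0) {
    out <- tibble(event_id = character(), type = character(),
                  mean_psi_a = numeric(), mean_psi_b = numeric(), dpsi = numeric(),
                  p_value = numeric(), fdr = numeric(), sign = integer())
    attr(out, "dropped") <- dropped
    return(out)
  }

  obs <- keep |>
    select("event_id", "type", "condition", "mean_psi", "mean_total") |>
    pivot_wider(names_from = "condition", values_from = c("mean_psi", "mean_total")) |>
    mutate(dpsi = .data[[paste0("mean_psi_", cond_b)]] - .data[[paste0("mean_psi_", cond_a)]],
           abundance = log10(1 + (.data[[paste0("mean_total_", cond_a)]] +
                                    .data[[paste0("mean_total_", cond_b)]]) / 2))

  # between-replicate fluctuations, rescaled to the spread of a mean difference
  scale_fac <- sqrt((1 / n_a + 1 / n_b) / 2)
  null_tbl <- psi |>
    filter(.data$event_id %in% obs$event_id) |>
    group_by(.data$event_id, .data$condition) |>
    group_map(function(d, key) {
      v <- d$psi[!is.na(d$psi)]
      if (length(v) < 2) return(NULL)
      pairs <- utils::combn(v, 2)
      tibble(event_id = key$event_id, null_d = abs(pairs[1, ] - pairs[2, ]) * scale_fac)
    }) |>
    bind_rows() |>
    left_join(obs |> select("event_id", "abundance"), by = "event_id")

  eff_bins <- max(1, min(n_bins, floor(nrow(obs) / 25)))
  obs$bin <- ntile(obs$abundance, eff_bins)
  null_tbl$bin <- obs$bin[match(null_tbl$event_id, obs$event_id)]
  null_by_bin <- split(null_tbl$null_d, null_tbl$bin)

  obs$p_value <- vapply(seq_len(nrow(obs)), function(i) {
    nd <- null_by_bin[[as.character(obs$bin[i])]]
    (1 + sum(nd >= abs(obs$dpsi[i]))) / (1 + length(nd))
  }, numeric(1))

  out <- obs |>
    transmute(.data$event_id, .data$type,
              mean_psi_a = .data[[paste0("mean_psi_", cond_a)]],
              mean_psi_b = .data[[paste0("mean_psi_", cond_b)]],
              .data$dpsi, .data$p_value,
              fdr = adjust_fdr(.data$p_value),
              sign = as.integer(base::sign(.data$dpsi))) |>
    arrange(.data$p_value, .data$event_id)
  attr(out, "dropped") <- dropped
  out
}

#' Combine two knockdown differential-splicing runs
#'
#' Emulates the use of two independent hairpins against one target to weed
#' out off-target effects: an event is retained only when it passes the FDR
#' threshold in *both* runs with the *same* dPSI sign. The combined dPSI is
#' the mean of the two estimates; the reported p-value and FDR are the less
#' significant (maximum) of the pair.
#'
#' @param dse1,dse2 Two [delta_psi()] results computed against the same
#'   control condition.
#' @param fdr_threshold Per-run FDR cutoff (default 0.05).
#' @return A tibble of retained events: `event_id`, `type`, `dpsi`,
#'   `p_value`, `fdr`, `sign`.
#' @export
combine_knockdowns <- function(dse1, dse2, fdr_threshold = 0.05) {
  assert_columns(dse1, c("event_id", "dpsi", "p_value", "fdr", "sign"), "dse1")
  assert_columns(dse2, c("event_id", "dpsi", "p_value", "fdr", "sign"), "dse2")
  shared <- intersect(dse1$event_id, dse2$event_id)
  if (length(shared) == 0) {
    warn("combine_knockdowns: the two runs share no events; returning an empty result")
  }
  inner_join(dse1, dse2, by = c("event_id", "type"), suffix = c("_1", "_2")) |>
    filter(.data$fdr_1 < fdr_threshold, .data$fdr_2 < fdr_threshold,
           .data$sign_1 == .data$sign_2, .data$sign_1 != 0L) |>
    transmute(.data$event_id, .data$type,
              dpsi = (.data$dpsi_1 + .data$dpsi_2) / 2,
              p_value = pmax(.data$p_value_1, .data$p_value_2),
              fdr = pmax(.data$fdr_1, .data$fdr_2),
              sign = .data$sign_1) |>
    arrange(.data$p_value, .data$event_id)
}
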