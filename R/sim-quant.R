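#' Plant condition-specific isoform usage (true PSI) on a simulated annotation
#'
#' Draws a baseline inclusion fraction per gene and shifts it by
#' `config$psi_shift` in the second condition for a planted subset of genes
#' (the differential splicing events, DSE). The shift direction is chosen so
#' the shifted value stays inside (0.02, 0.98).
#'
#' @inheritParams sim_annotation
#' @param annotation A [sim_annotation()] tibble.
#' @return A tibble with one row per gene: `gene_id`, `type`, inclusion and
#'   exclusion transcript ids, `psi_1`/`psi_2` (true inclusion usage in each
#'   condition), `is_dse` and `shift_sign`.
#' @export
sim_splicing_truth <- function(annotation, config, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  truth <- sim_truth(annotation)
  seed <- seed %||% child_seed(config$seed, 1)
  withr::with_seed(seed, {
    n <- nrow(truth)
    psi1 <- runif(n, 0.2, 0.8)
    n_dse <- round(config$dse_fraction * n)
    is_dse <- seq_len(n) %in% sample(n, n_dse)
    sign <- ifelse(runif(n) < 0.5, 1, -1)
    # flip when the shift would leave (0.02, 0.98)
    sign <- ifelse(psi1 + sign * config$psi_shift > 0.98, -1,
            ifelse(psi1 + sign * config$psi_shift < 0.02, 1, sign))
    psi2 <- ifelse(is_dse, psi1 + sign * config$psi_shift, psi1)
    truth |>
      select("gene_id", "type", "inclusion_tx", "exclusion_tx") |>
      mutate(psi_1 = psi1, psi_2 = psi2, is_dse = is_dse,
             shift_sign = ifelse(is_dse, sign, 0L))
  })
}

#' Simulate replicate transcript quantifications
#'
#' Emulates the per-sample transcript tables a pseudoalignment quantifier
#' produces. Per-gene expression is log-normal; isoform usage equals the true
#' inclusion PSI with optional replicate-level logit-normal jitter; TPMs are
#' renormalized to sum to 1e6 per sample; expected read counts are
#' proportional to TPM times effective length scaled to the configured depth,
#' with negative-binomial noise whose dispersion follows
#' `config$dispersion_fn` (variance `mu + d(mu) * mu^2`).
#'
#' @inheritParams sim_splicing_truth
#' @param truth Optional output of [sim_splicing_truth()]; generated from the
#'   config when missing. Pass the same truth twice with different seeds to
#'   emulate two independent knockdown experiments sharing one biology.
#' @return A list with `quant` (a long tibble: `transcript_id`, `gene_id`,
#'   `length`, `effective_length`, `sample`, `condition`, `tpm`, `count`) and
#'   `truth` (the splicing ground truth used).
#' @examples
#' cfg <- sim_config(n_genes = 10, seed = 1)
#' ann <- sim_annotation(cfg)
#' sim <- sim_quant(ann, cfg)
#' head(sim$quant)
#' @export
sim_quant <- function(annotation, config, truth = NULL, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  if (is.null(truth)) truth <- sim_splicing_truth(annotation, config)
  seed <- seed %||% child_seed(config$seed, 2)

  tx_len <- annotation |>
    filter(.data$feature == "exon") |>
    group_by(.data$gene_id, .data$transcript_id) |>
    summarise(length = sum(.data$end - .data$start), .groups = "drop")

  base <- bind_rows(
    truth |> transmute(gene_id = .data$gene_id, transcript_id = .data$inclusion_tx,
                       role = "inclusion", psi_1 = .data$psi_1, psi_2 = .data$psi_2),
    truth |> transmute(gene_id = .data$gene_id, transcript_id = .data$exclusion_tx,
                       role = "exclusion", psi_1 = .data$psi_1, psi_2 = .data$psi_2)
  ) |>
    left_join(tx_len, by = c("gene_id", "transcript_id")) |>
    mutate(effective_length = pmax(.data$length - 150, 10))

  samples <- tibble(
    condition = rep(config$conditions, each = config$n_replicates),
    replicate = rep(seq_len(config$n_replicates), times = 2)
  ) |>
    mutate(sample = paste0(.data$condition, "_r", .data$replicate))

  withr::with_seed(seed, {
    expr <- truth |>
      transmute(gene_id = .data$gene_id,
                expr = rlnorm(n(), config$expr_meanlog, config$expr_sdlog))
    out <- vector("list", nrow(samples))
    for (s in seq_len(nrow(samples))) {
      cond_idx <- match(samples$condition[s], config$conditions)
      tab <- base |>
        left_join(expr, by = "gene_id") |>
        mutate(psi = if (cond_idx == 1) .data$psi_1 else .data$psi_2)
      # replicate-level jitter: logit-normal on usage, log-normal on expression
      g <- tab |> distinct(.data$gene_id)
      g$usage_noise <- if (config$psi_logit_sd > 0) rnorm(nrow(g), 0, config$psi_logit_sd) else 0
      g$expr_noise <- if (config$tpm_noise_sd > 0) rnorm(nrow(g), 0, config$tpm_noise_sd) else 0
      tab <- tab |>
        left_join(g, by = "gene_id") |>
        mutate(usage = plogis(qlogis(.data$psi) + .data$usage_noise),
               usage = ifelse(.data$role == "inclusion", .data$usage, 1 - .data$usage),
               tpm = .data$expr * exp(.data$expr_noise) * .data$usage,
               tpm = .data$tpm / sum(.data$tpm) * 1e6)
      mu <- with(tab, tpm * effective_length)
      mu <- mu / sum(mu) * config$depth
      d <- config$dispersion_fn(mu)
      count <- ifelse(d <= 0, rpois(length(mu), mu),
                      rnbinom(length(mu), mu = mu, size = 1 / pmax(d, 1e-12)))
      out[[s]] <- tab |>
        transmute(.data$transcript_id, .data$gene_id, .data$length,
                  .data$effective_length, sample = samples$sample[s],
                  condition = samples$condition[s], .data$tpm, count = count)
    }
    list(quant = bind_rows(out), truth = truth)
  })
}

#' Simulate negative-binomial count data for the expression test
#'
#' A plain feature-by-sample count simulator used to exercise and calibrate
#' the negative-binomial machinery: per-feature means are log-normal, counts
#' are NB with variance `mu + d(mu) * mu^2`, and an optional log2
#' fold-change is planted in the second condition for a leading subset of
#' features.
#'
#' @param n_features Number of features.
#' @param n_per_group Samples per condition.
#' @param meanlog,sdlog Log-normal parameters of the per-feature means.
#' @param dispersion_fn Mean-to-dispersion function (0 gives Poisson).
#' @param lfc Planted log2 fold-change (0 = pure null).
#' @param frac_de Fraction of features receiving the fold-change.
#' @param seed Integer seed.
#' @return A list: `counts` (long tibble `feature_id`, `sample`, `condition`,
#'   `count`), `means`, and `is_de` (logical per feature).
#' @export
sim_nb_counts <- function(n_features, n_per_group = 3, meanlog = 4, sdlog = 1,
                          dispersion_fn = function(m) 0.05 + 2 / (m + 1),
                          lfc = 0, frac_de = 0, seed = 1L) {
  withr::with_seed(seed, {
    mu <- rlnorm(n_features, meanlog, sdlog)
    is_de <- seq_len(n_features) <= round(frac_de * n_features)
    fid <- sprintf("f%05d", seq_len(n_features))
    samples <- c(paste0("A_r", seq_len(n_per_group)), paste0("B_r", seq_len(n_per_group)))
    condition <- rep(c("A", "B"), each = n_per_group)
    rows <- vector("list", length(samples))
    for (j in seq_along(samples)) {
      m <- if (condition[j] == "B") mu * ifelse(is_de, 2^lfc, 1) else mu
      d <- dispersion_fn(m)
      k <- ifelse(d <= 0, rpois(n_features, m),
                  rnbinom(n_features, mu = m, size = 1 / pmax(d, 1e-12)))
      rows[[j]] <- tibble(feature_id = fid, sample = samples[j],
                          condition = condition[j], count = k)
    }
    list(counts = bind_rows(rows), means = mu, is_de = is_de)
  })
}
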