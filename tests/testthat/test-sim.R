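test_that("config validation rejects impossible settings", {
  expect_error(sim_config(event_mix = c(SE = 0.5, RI = 0.4)), "sum to 1")
  expect_error(sim_config(psi_shift = 0), "psi_shift")
  expect_error(sim_config(psi_shift = 1.2), "psi_shift")
  expect_error(sim_config(censor_rate = 1), "censor_rate")
  expect_error(sim_config(n_replicates = 1), "positive")
  expect_error(sim_config(exon_len_range = c(-5, 10)), "positive")
  expect_error(sim_config(event_mix = c(XX = 1)), "SE, RI")
})

test_that("every generator is a deterministic function of the seed", {
  cfg <- sim_config(n_genes = 40, seed = 7)
  a1 <- sim_annotation(cfg); a2 <- sim_annotation(cfg)
  expect_identical(a1, a2)
  t1 <- sim_splicing_truth(a1, cfg)
  q1 <- sim_quant(a1, cfg, truth = t1); q2 <- sim_quant(a1, cfg, truth = t1)
  expect_identical(q1$quant, q2$quant)
  p1 <- sim_peaks(a1, t1, cfg); p2 <- sim_peaks(a1, t1, cfg)
  expect_identical(p1, p2)
  g1 <- sim_genome(a1, p1, cfg); g2 <- sim_genome(a1, p1, cfg)
  expect_identical(as.character(g1), as.character(g2))
  c1 <- sim_cohort(c("x", "y", "z"), cfg); c2 <- sim_cohort(c("x", "y", "z"), cfg)
  expect_identical(c1$cohort, c2$cohort)
  # a different seed produces different data
  expect_false(identical(a1, sim_annotation(cfg, seed = 8)))
})

test_that("simulated intervals and usages are well-formed", {
  cfg <- sim_config(n_genes = 60, seed = 19)
  ann <- sim_annotation(cfg)
  expect_true(all(ann$end > ann$start))
  expect_true(all(ann$start >= 0))
  truth <- sim_splicing_truth(ann, cfg)
  expect_true(all(truth$psi_1 >= 0 & truth$psi_1 <= 1))
  expect_true(all(truth$psi_2 >= 0 & truth$psi_2 <= 1))
  q <- sim_quant(ann, cfg, truth = truth)$quant
  expect_true(all(q$tpm >= 0))
  expect_true(all(q$count >= 0 & q$count == round(q$count)))
  # per-sample TPMs are normalized
  tot <- q |> group_by(.data$sample) |> summarise(s = sum(.data$tpm))
  expect_equal(tot$s, rep(1e6, nrow(tot)))
})

test_that("zero dispersion gives Poisson-like counts across 1000 genes", {
  cfg <- sim_config(n_genes = 500, seed = 23, psi_logit_sd = 0, tpm_noise_sd = 0,
                    dse_fraction = 0, dispersion_fn = function(m) rep(0, length(m)))
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  q <- sim_quant(ann, cfg, truth = truth)$quant
  mv <- q |>
    filter(.data$condition == "ctrl") |>
    group_by(.data$transcript_id) |>
    summarise(m = mean(.data$count), v = var(.data$count)) |>
    filter(.data$m >= 5)
  # 1000 transcripts: aggregate variance/mean ratio near 1
  expect_gt(nrow(mv), 500)
  expect_lt(abs(sum(mv$v) / sum(mv$m) - 1), 0.1)
})

test_that("peak planting follows the binomial enrichment fraction", {
  cfg <- sim_config(n_genes = 100, event_mix = c(SE = 1), dse_fraction = 1,
                    peak_enrichment_fraction = 0.5, background_peak_rate = 0,
                    seed = 29)
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  pk <- sim_peaks(ann, truth, cfg)
  expect_lt(abs(nrow(pk) - 50), 3 * sqrt(100 * 0.25))
  expect_true(all(pk$planted))
  # summits inside their flanking introns
  st <- sim_truth(ann)
  j <- pk |> left_join(st, by = c("gene_id", "contig"))
  in_flank <- (j$summit >= j$flank_up_start & j$summit < j$flank_up_end) |
    (j$summit >= j$flank_down_start & j$summit < j$flank_down_end)
  expect_true(all(in_flank))
  # both rates zero: empty peak set
  cfg0 <- sim_config(n_genes = 30, peak_enrichment_fraction = 0,
                     background_peak_rate = 0, seed = 1)
  ann0 <- sim_annotation(cfg0)
  expect_equal(nrow(sim_peaks(ann0, sim_splicing_truth(ann0, cfg0), cfg0)), 0)
})

test_that("the genome carries the motif at summits and random background elsewhere", {
  cfg <- sim_config(n_genes = 40, seed = 37, dse_fraction = 0.5,
                    peak_enrichment_fraction = 1, background_peak_rate = 0)
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  pk <- sim_peaks(ann, truth, cfg)
  g <- sim_genome(ann, pk, cfg)
  for (i in seq_len(nrow(pk))) {
    s <- pk$summit[i]
    if (pk$strand[i] == "+") {
      got <- as.character(Biostrings::subseq(g[[pk$contig[i]]], s + 1, s + 5))
      expect_equal(got, cfg$motif)
    } else {
      got <- as.character(Biostrings::reverseComplement(
        Biostrings::subseq(g[[pk$contig[i]]], s - 3, s + 1)))
      expect_equal(got, cfg$motif)
    }
  }
  # without peaks the background motif count matches the closed-form rate
  g0 <- sim_genome(ann, pk[0, ], cfg)
  n_match <- sum(Biostrings::vcountPattern(cfg$motif, g0))
  len <- sum(Biostrings::width(g0))
  expected <- len * 0.25^5
  expect_lt(abs(n_match - expected), 4 * sqrt(expected))
})

test_that("the cohort respects censoring and the null-beta independence", {
  cfg0 <- sim_config(n_patients = 500, true_betas = c(0.8), censor_rate = 0, seed = 41)
  co0 <- sim_cohort("e1", cfg0)$cohort
  expect_true(all(co0$status == 1))
  expect_true(all(co0$time > 0))
  cfg1 <- sim_config(n_patients = 2000, true_betas = c(0, 0), censor_rate = 0.3,
                     seed = 43)
  co1 <- sim_cohort(c("e1", "e2"), cfg1)$cohort
  expect_lt(abs(suppressWarnings(
    stats::cor(co1$time, co1$e1, method = "spearman"))), 0.06)
  expect_lt(abs(mean(co1$status == 0) - 0.3), 3 * sqrt(0.3 * 0.7 / 2000))
  expect_error(sim_cohort(c("only_one"), cfg1), "same length")
})

test_that("cohort hazard ratios recover exp(beta) within the CI at n = 2000", {
  cfg <- sim_config(n_patients = 2000, true_betas = c(1.2, -0.7), censor_rate = 0.2,
                    seed = 47)
  co <- sim_cohort(c("e1", "e2"), cfg)$cohort
  fit <- survival::coxph(survival::Surv(time, status) ~ e1 + e2, data = co)
  ci <- stats::confint(fit, level = 0.99)
  expect_true(ci["e1", 1] < 1.2 && 1.2 < ci["e1", 2])
  expect_true(ci["e2", 1] < -0.7 && -0.7 < ci["e2", 2])
})
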