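# splicewise

Alternative-splicing (AS) switches — local changes in how exons are joined —
reshape the transcriptome of tumor cells, and the m6A methyltransferase
METTL3 has been implicated in steering them. `splicewise` packages the
computational side of that kind of study for R users working from standard
files (GTF annotation, transcript quantification tables, peak BEDs, a genome
FASTA and a clinical table):

* **Event calculus** — derive the seven canonical event classes from a gene
  annotation: skipped exon (SE), retained intron (RI), mutually exclusive
  exons (MX), alternative 5′/3′ splice sites (A5/A3) and alternative
  first/last exons (AF/AL), each with its inclusion/exclusion transcript
  sets; flag transcripts whose stop codon lies >50 nt upstream of the last
  exon–exon junction (PTC/NMD targets).
* **PSI and differential splicing** — per-sample percent spliced-in
  `PSI = Σ TPM(inclusion) / Σ TPM(all isoforms)`, ΔPSI between conditions
  with an empirical significance built from between-replicate fluctuations
  pooled in abundance bins, Benjamini–Hochberg FDR, and the dual-knockdown
  combination rule (significant in both hairpins with concordant sign).
* **Differential expression** — an exact conditional test under a negative
  binomial whose variance is tied to the mean by a locally regressed smooth
  function, with a detection filter (reads in at least half the samples) and
  median-of-ratios normalization.
* **Intronic m6A × splicing** — assign peak summits to the flanking introns
  of skipped exons and test the 2×2 association between differential
  splicing and intronic m6A (or PTC status) with Fisher's exact test.
* **Motif density** — profile an IUPAC motif (e.g. `DRACH`) in the −80..+80
  nt region around peak summits against length-matched random intronic
  windows, with a permutation test of central enrichment.
* **Survival signature** — a Lasso-penalized Cox model on event PSIs, the
  risk score `Σ βᵢ × PSIᵢ`, stratification at the 75th percentile of the
  score (1207 patients split exactly 302 high / 905 low), Kaplan–Meier
  curves and log-rank tests, tumor/normal PSI comparisons and
  expression–PSI correlations.

A first-class **synthetic-data generator** (`sim_*` functions) produces every
input with known ground truth — planted event types, usage shifts,
peak-bearing introns, summit motifs and hazard coefficients — so the whole
pipeline is testable end to end without downloads.

All user-facing functions take and return tibbles and chain with the pipe;
fitted objects support `tidy()`/`glance()` and results `autoplot()`.

## A worked example

```r
library(splicewise)
library(dplyr)

cfg    <- sim_config(n_genes = 120, seed = 1)
ann    <- sim_annotation(cfg)
events <- build_events(ann)
count(events, type)
#>   type      n
#> 1 A3       12
#> 2 A5       12
#> ...
#> 7 SE       48

truth <- sim_splicing_truth(ann, cfg)           # planted usage per condition
sh1 <- sim_quant(ann, cfg, truth = truth, seed = 101)$quant
sh2 <- sim_quant(ann, cfg, truth = truth, seed = 202)$quant
dse1 <- compute_psi(events, sh1) |> delta_psi("ctrl", "kd")
dse2 <- compute_psi(events, sh2) |> delta_psi("ctrl", "kd")
dse <- combine_knockdowns(dse1, dse2)
head(dse, 3)
#>   event_id                                  type    dpsi p_value    fdr  sign
#> 1 g0027;AF:ctg_g0027:301:516-1690:620:...   AF    -0.315 0.00552 0.0288    -1
#> 2 g0034;SE:ctg_g0034:465-986:1183-2016:-    SE     0.233 0.00552 0.0288     1
#> 3 g0040;SE:ctg_g0040:459-1232:1312-1847:+   SE     0.259 0.00552 0.0288     1
```

23 of the 24 planted differential events are retained, every one with the
planted shift direction. The m6A association stage cross-tabulates the
significant skipped exons against intronic peak summits:

```r
peaks <- sim_peaks(ann, truth, cfg)
flags <- assign_peaks(peaks, events)
sig <- tibble(event_id = flags$event_id,
              significant = flags$event_id %in% dse$event_id)
enrichment_test(sig, flags)
#> <sw_enrichment> Fisher's exact association
#>                 m6a_pos m6a_neg
#> significant           9       0
#> not_significant       4      35
#>   p = 4.263e-07; m6A+ fraction among significant = 1
```

and the survival stage recovers planted hazard coefficients and stratifies
patients at the 75th risk-score percentile:

```r
co    <- sim_cohort(c("e1", "e2", "e3"),
                    sim_config(n_patients = 1000,
                               true_betas = c(1.5, -1.5, 0), seed = 1))
model <- cox_lasso(co$cohort, seed = 1)
tidy(model)
#>   term  estimate hazard_ratio
#> 1 e1        1.47        4.34
#> 2 e2       -1.52        0.219
#> 3 e3        0           1

scored <- risk_score(model, co$cohort)
grp    <- percentile_split(scored$risk_score)        # top 25% = "high"
logrank_test(scored$time, scored$status, grp)$p_value
#> [1] 1.34e-33
```

The per-event β̂ are within sampling error of the planted (1.5, −1.5) and the
null coefficient is shrunk exactly to zero by the cross-validated penalty.

`run_pipeline()` drives the same stages from files (GTF, quant TSVs, BED,
FASTA, clinical TSV) and writes per-stage TSVs plus a JSON run manifest.

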