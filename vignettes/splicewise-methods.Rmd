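---
title: "Models and methods behind splicewise"
author: "splicewise authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind splicewise}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(splicewise)
library(dplyr)
```

`splicewise` implements the statistical machinery of an alternative-splicing
(AS) study driven by transcript quantifications: event derivation and
percent spliced-in (PSI), differential splicing with an empirical null,
negative-binomial differential expression, enrichment of intronic m6A among
differentially skipped exons, motif density around peak summits, and a
PSI-based survival signature. This vignette explains each model, the
tunable parameters, the numerical choices, and what the bundled simulators
do and do not emulate.

## Event calculus

Events are derived per gene from local structural differences between
transcripts, using exon–exon junctions as the unit of evidence. Internally
all coordinates are 0-based half-open; GTF input/output converts once at
the boundary (`read_gtf()` / `write_gtf()`).

* **SE** — a cassette exon with junctions $(e_1,s_2)$ and $(e_2,s_3)$
  against the direct junction $(e_1,s_3)$. The two flanking introns are
  retained on the event record; they are the assignment target for m6A
  peaks.
* **RI** — a single exon spanning exactly the outer boundaries of an
  exon–intron–exon triplet in another transcript. Exact-boundary matching
  keeps inclusion/exclusion membership unambiguous.
* **A5/A3** — two introns sharing one boundary whose alternative-side exons
  overlap. The classification is strand-mirrored (the same genomic
  configuration is A5 on `+` and A3 on `-`); the *shorter-intron* (more
  exonic) form is the inclusion form.
* **MX** — two internal exons sharing both outer splice sites, mutually
  non-overlapping, each absent from the other form. The inclusion form
  carries the exon proximal to the transcript 5′ end, which makes the
  orientation strand-symmetric.
* **AF/AL** — distinct, non-overlapping terminal exons spliced to a shared
  acceptor (donor). Tandem starts inside one terminal exon are deliberately
  ignored; the *distal* terminal exon is the inclusion form.

Inclusion and exclusion sets contain every transcript of the gene carrying
the relevant junction signature, not just the defining pair; they are
disjoint by construction. Event identifiers follow the
`gene;TYPE:contig:coords:strand` convention with 1-based display
coordinates, so tables interoperate with ioe-style tooling.

**PTC flags.** A transcript with a CDS is flagged as a likely
nonsense-mediated-decay target when its stop codon ends strictly more than
50 nt upstream of the last exon–exon junction, measured in mRNA
coordinates. Stops in the last exon and single-exon transcripts are never
flagged; transcripts without a CDS yield no flag at all (absence, not
`FALSE`). Both an annotation-driven entry point (`flag_nmd()`) and direct
flag tables are supported, since studies differ in whether they trust
annotation NMD tags or recompute the rule.

## PSI and differential splicing

For an event with inclusion set $I$ and exclusion set $E$,

$$\mathrm{PSI} = \frac{\sum_{t \in I} \mathrm{TPM}_t}
                      {\sum_{t \in I \cup E} \mathrm{TPM}_t},$$

per sample. PSI is invariant to any uniform rescaling of a sample's TPMs.
An event/sample cell with zero total abundance is undefined (`NA`).

`delta_psi()` reports $\Delta\mathrm{PSI} = \overline{\mathrm{PSI}}_B -
\overline{\mathrm{PSI}}_A$ and attaches an empirical p-value. The null is
built from the data themselves: within each condition, all replicate-pair
PSI differences are collected and pooled within roughly ten
equal-occupancy bins of $\log_{10}$ mean event abundance (fewer bins when
fewer than ~25 events per bin are available), and the p-value is the
add-one tail frequency $(1 + \#\{|d_0| \ge |\Delta\mathrm{PSI}|\}) / (1 +
N)$ within the event's bin. Two numerical choices matter:

* **Rescaling the null.** A replicate-pair difference has variance
  $2\sigma^2$ while a difference of condition means has variance
  $\sigma^2(1/n_A + 1/n_B)$. Null values are therefore multiplied by
  $\sqrt{(1/n_A + 1/n_B)/2}$ before pooling. Without this the p-values are
  conservative by a factor $\approx\sqrt{n}$ in scale; with it, pure-null
  simulations give approximately uniform p-values (a property the test
  suite checks with a KS test at $n = 2000$ events).
* **Expression floor.** Events whose mean total TPM falls below 1 in either
  condition, or whose PSI is undefined in more than half the samples of a
  condition, are dropped and counted — ratios of near-zero abundances are
  noise, not biology.

FDR control is Benjamini–Hochberg (`adjust_fdr()`), chosen as the
parameter-free, monotone default; a q-value estimator would be a
reasonable alternative but is not silently substituted.

**Dual-knockdown combination.** Two independent hairpins against the same
target are combined by *intersection*: an event is kept only when it passes
the FDR threshold (default 0.05) in both runs with the same
$\Delta\mathrm{PSI}$ sign; the reported effect is the mean, the reported
p-value the maximum. Intersection (rather than sample pooling) matches the
purpose of dual knockdowns — excluding off-target effects — and
`combine_knockdowns(x, x)` reduces to the significant subset of `x`.
Pooling samples before testing is a legitimate alternative design; it is
not what this function does.

## Negative-binomial differential expression

Counts are normalized by median-of-ratios size factors (rows with no zero
count; factors rescaled to geometric mean 1). Features must show a nonzero
count in at least half the samples (`filter_detected()`).

The variance is tied to the mean by a locally regressed smooth function:
per feature, the mean normalized count and the within-condition pooled
variance are computed, and `log(variance)` is regressed on `log(mean)` with
a tricube-weighted locally linear fit (`stats::loess`, `degree = 1`,
`span = 0.4` by default). Two corrections keep the fit honest:

* Regressing *log* sample variances underestimates the log true variance
  (Jensen's inequality applied to few-df variance estimates). The fit is
  multiplied by the chi-square log-moment correction
  $\exp(\log(\nu/2) - \psi(\nu/2))$ at the design's residual df $\nu$;
  without it the downstream test is anticonservative (~0.08 type-I error at
  nominal 0.05 in our simulations, versus ~0.05 with it).
* Evaluation clamps queries to the fitted mean range and floors the result
  at the Poisson bound (variance ≥ mean).

`nb_test()` is an exact conditional two-sided test: the per-condition raw
count sums are modeled as negative binomials with means from the pooled
normalized estimate and variances from the fitted curve, and, conditioning
on the observed total $K$, the p-value sums the probabilities of all splits
$(a, K-a)$ at most as probable as the observed one. All-zero features
return $p = 1$ by convention. Because raw sums are integers, no rounding
convention is needed for the enumeration; size factors enter through the
means. A Wald or likelihood-ratio GLM would be the natural alternative; the
exact conditional form was chosen because the method being implemented is a
moment-based NB test, not a GLM fit.

## Intronic m6A and PTC association

`assign_peaks()` flags an SE event m6A-positive when at least one peak
*summit* lies inside either flanking intron. Summit containment (rather
than any-overlap) is the default because a summit is a single unambiguous
point even when a peak straddles an exon–intron boundary; any-overlap is
available behind `rule = "overlap"`. Non-SE events are outside the
procedure's definition and are excluded from the enrichment universe.

`fisher_exact()` computes the two-sided Fisher p-value by summing
hypergeometric probabilities of all tables with the observed margins that
are at most as probable as the observed table; zero-margin tables return
$p = 1$. The test suite checks exact agreement with full enumeration for
every 2×2 table with total ≤ 40 and with `stats::fisher.test`.

`enrichment_test()` cross-tabulates differential-splicing significance
against the m6A flag at the *event* level over all tested events (the finer
unit; a gene-level collapse would hide multiple events per gene), and also
reports the fraction of significant events that are m6A-positive.
`ptc_association()` is the same machinery with "any participating
transcript is PTC+" replacing the m6A flag.

## Motif density around summits

Windows of ±150 nt are cut around summits (clipped windows are dropped and
counted) and reverse-complemented on minus-strand peaks, so position 0
always reads 5′→3′ through the summit. Matched random windows are drawn
uniformly from the intronic space of peak-bearing genes, length-matched and
fully intron-contained — the operational reading of "random regions with
similar properties"; optional GC matching was considered and left off by
default because the simulator's background is compositionally uniform.

`density_profile()` counts motif-match *starts* per offset in −80..+80
(IUPAC degeneracy honored, e.g. `DRACH`; overlapping matches allowed, which
gives the clean conservation identity: summed density × window count =
total match count). Matching uses `fixed = "subject"` so degenerate motif
letters act as wildcards while an `N` in the sequence matches nothing.
`center_enrichment()` compares mean central-band (±20 nt) density between
peak and random windows and attaches a one-sided permutation p-value
(≥1000 seeded label permutations).

## Survival signature

`cox_lasso()` maximizes the L1-penalized Cox partial likelihood on event
PSI covariates (glmnet's cyclic coordinate descent; Breslow ties). The
penalty defaults to seeded 5-fold cross-validated partial likelihood;
`penalty = 0` and single-covariate models reduce to an unpenalized
`coxph()` fit. Patients with missing values are dropped (complete-case) —
imputation over sparse PSI tables would be an unstated modeling choice — and
an all-censored cohort is an explicit error.

The risk score is the linear predictor $\sum_i \beta_i \cdot
\mathrm{PSI}_i$. `percentile_split()` stratifies by *rank*: the top
$\lceil (1-q)\,n \rceil$ scores are "high". A rank rule rather than an
interpolated quantile is interpolation-convention-free and reproduces the
printed 302/905 split of 1207 patients exactly; boundary ties are broken by
stable input order with a warning. Kaplan–Meier curves come from the
product-limit estimator and group comparisons from the standard two-group
log-rank test. Tumor/normal PSI comparisons default to the two-sided
rank-sum test (the robust choice when only box plots with p-values are
given; Welch's t is available behind `method = "t"`), and expression–PSI
correlation is Pearson's r with the t-transform p-value, with an `NA`
sentinel for degenerate inputs.

## What the simulators emulate — and what they do not

The `sim_*` family generates every input with known ground truth:

* `sim_annotation()` — one gene per contig, each realizing exactly one
  event type from `event_mix` through two transcripts, with ≥300 nt contig
  padding and introns of 450–900 nt (long enough to host a full ±150 nt
  window). CDSs are planted so a configurable fraction of exclusion-form
  transcripts is PTC+ by a wide margin (~70–80 nt upstream of the last
  junction).
* `sim_quant()` — log-normal gene expression (meanlog 3, sdlog 1),
  logit-normal replicate jitter on isoform usage (sd 0.3, keeping PSI in
  (0,1)), log-normal expression jitter (sd 0.15), TPMs renormalized to 1e6,
  and NB counts with variance $\mu + d(\mu)\mu^2$ under a decreasing
  dispersion trend $d(\mu) = 0.05 + 2/(\mu+1)$, linked to TPM via effective
  length and a depth factor so the table shape matches pseudoalignment
  output. Defaults (3 replicates, ΔPSI 0.3 planted in 20% of genes) are the
  study conditions the acceptance checks run under.
* `sim_peaks()` / `sim_genome()` — peaks in a configurable fraction of
  planted-DSE flanking introns plus a uniform per-kb background elsewhere
  (flanks of all planted genes excluded from the background so ground truth
  stays crisp), and a uniform-base genome with the motif written at each
  summit, reverse-complement-aware.
* `sim_cohort()` — uniform PSIs, exponential baseline hazard scaled by
  $\exp(\sum\beta_i \mathrm{PSI}_i)$, independent censoring with the
  censoring hazard chosen so the expected censored fraction equals
  `censor_rate` exactly.

These simulators share the *statistical structure* of real inputs, not
their content: no splice-site sequence signal, no GC/mappability biases, no
overlapping genes or multi-event genes, uniform base composition, one
isoform pair per gene, proportional-hazards survival with uniform
covariates. A test passing on them demonstrates that the estimators are
correct and calibrated under their stated models — not that real data meet
those models.

## Problem sizes and determinism

The test suite and `scripts/acceptance.R` use desk-scale sizes chosen to
make Monte-Carlo bands tight enough to be meaningful while keeping a full
run in minutes on one CPU: 5,000 null features for NB calibration, 2,000
events for p-uniformity, 250 genes for DSE recovery, 500 SE genes × 100/200
replicates for m6A power/calibration, 1,000 null replicates for log-rank
calibration, cohorts of 1,000–2,000 patients for coefficient recovery.
Every stochastic stage takes a seed; each simulator derives per-stage child
seeds from the config so runs are byte-reproducible (the pipeline test
asserts identical output files across reruns).

## Known limitations

* Events are derived from annotation only; novel junctions from reads are
  out of scope, as is transcript-level differential-usage modeling.
* The empirical ΔPSI null assumes replicate fluctuations are exchangeable
  across events within an abundance bin; strong per-event variance
  heterogeneity would miscalibrate it.
* The NB exact test handles two-group designs without covariates and does
  not shrink fold changes.
* Peak quality is taken at face value: no peak calling, no
  single-nucleotide m6A resolution, no genome-build liftover.
* The survival module fits PSI-only signatures; clinical covariate
  adjustment is deliberately not included.
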