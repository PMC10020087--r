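make_genome <- function(seqs) Biostrings::DNAStringSet(seqs)

test_that("window extraction does the arithmetic, clipping and strand flip", {
  g <- withr::with_seed(1, make_genome(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""))))
  pk <- tibble(contig = "c1", summit = c(200, 100), strand = c("+", "+"))
  expect_message(w <- extract_windows(pk, g), "dropped 1")
  expect_equal(nrow(w), 1)
  expect_equal(nchar(w$seq), 301)
  expect_equal(w$seq, as.character(Biostrings::subseq(g[["c1"]], 51, 351)))
  # minus strand equals the reverse complement of the plus extraction
  pk2 <- tibble(contig = "c1", summit = 200, strand = "-")
  w2 <- extract_windows(pk2, g)
  expect_equal(w2$seq, as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(w$seq))))
})

test_that("motif density honours IUPAC degeneracy and planted summits", {
  cfg <- sim_config(n_genes = 60, seed = 7, dse_fraction = 0.4,
                    peak_enrichment_fraction = 1, background_peak_rate = 0,
                    motif = "GGACU")                      # RNA alphabet accepted
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  pk <- sim_peaks(ann, truth, cfg)
  g <- sim_genome(ann, pk, cfg)
  w <- extract_windows(pk, g)
  prof <- density_profile(w, "GGACT")
  expect_equal(prof$density[prof$position == 0], 1)        # exact match at summit
  drach <- density_profile(w, "DRACH")                     # planted GGACT matches DRACH
  expect_equal(drach$density[drach$position == 0], 1)
  expect_lt(mean(prof$density[abs(prof$position) > 10]), 0.01)
})

test_that("density is zero on unresolvable sequence and conserved in total", {
  w_n <- tibble(contig = "x", summit = 150, strand = "+",
                seq = paste(rep("N", 301), collapse = ""))
  prof_n <- density_profile(w_n, "ACGT")
  expect_true(all(prof_n$density == 0))

  g <- withr::with_seed(8, make_genome(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = ""))))
  pk <- tibble(contig = "c1", summit = seq(200, 4500, by = 180), strand = "+")
  w <- extract_windows(pk, g)
  prof <- density_profile(w, "ACGT", range = -80:80)
  # conservation: densities times window count equals the match total,
  # counted independently with gregexpr
  total <- sum(vapply(w$seq, function(s) {
    hits <- gregexpr("ACGT", s, fixed = TRUE)[[1]]
    hits <- hits[hits > 0]
    offs <- hits - 1 - 150
    sum(offs >= -80 & offs <= 80)
  }, numeric(1)))
  expect_equal(sum(prof$density) * nrow(w), total)
  # mean density approximates the closed-form 4^-4 background rate
  p0 <- 0.25^4
  n_obs <- length(prof$density) * nrow(w)
  expect_lt(abs(mean(prof$density) - p0), 4 * sqrt(p0 * (1 - p0) / n_obs))
})

test_that("density profiles are window-order invariant", {
  g <- withr::with_seed(9, make_genome(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 3000, replace = TRUE), collapse = ""))))
  pk <- tibble(contig = "c1", summit = seq(200, 2700, by = 250), strand = "+")
  w <- extract_windows(pk, g)
  p1 <- density_profile(w, "DRACH")
  p2 <- density_profile(w[rev(seq_len(nrow(w))), ], "DRACH")
  expect_equal(p1$density, p2$density)
})

test_that("matched random regions live inside introns of peak-bearing genes", {
  cfg <- sim_config(n_genes = 50, seed = 13, dse_fraction = 0.4)
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  pk <- sim_peaks(ann, truth, cfg)
  g <- sim_genome(ann, pk, cfg)
  w <- match_random_regions(pk, ann, g, seed = 3)
  expect_equal(nrow(w), nrow(pk))
  introns <- splicewise:::gene_introns(ann)
  inside <- vapply(seq_len(nrow(w)), function(i) {
    any(introns$contig == w$contig[i] &
          introns$start <= w$summit[i] - 150 &
          introns$end >= w$summit[i] + 151)
  }, logical(1))
  expect_true(all(inside))
  # determinism and the zero-peak degenerate case
  w2 <- match_random_regions(pk, ann, g, seed = 3)
  expect_equal(w, w2)
  expect_equal(nrow(match_random_regions(pk[0, ], ann, g, seed = 3)), 0)
  # GC of matched windows close to the intronic background
  gc <- function(s) mean(strsplit(paste(s, collapse = ""), "")[[1]] %in% c("G", "C"))
  expect_lt(abs(gc(w$seq) - 0.5), 0.05)
})

test_that("center enrichment is 1 on identical sets and detects planting", {
  g <- withr::with_seed(21, make_genome(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 8000, replace = TRUE), collapse = ""))))
  pk <- tibble(contig = "c1", summit = seq(200, 7500, by = 160), strand = "+")
  w <- extract_windows(pk, g)
  same <- center_enrichment(w, w, "DRACH", n_perm = 200, seed = 2)
  expect_equal(same$ratio, 1)
  expect_gt(same$p_value, 0.5)

  cfg <- sim_config(n_genes = 60, seed = 17, dse_fraction = 0.5,
                    peak_enrichment_fraction = 1, background_peak_rate = 0)
  ann <- sim_annotation(cfg)
  truth <- sim_splicing_truth(ann, cfg)
  pks <- sim_peaks(ann, truth, cfg)
  gen <- sim_genome(ann, pks, cfg)
  wp <- extract_windows(pks, gen)
  wr <- match_random_regions(pks, ann, gen, seed = 5)
  ce <- center_enrichment(wp, wr, cfg$motif, seed = 5)
  expect_gt(ce$ratio, 2)
  expect_lt(ce$p_value, 0.01)
})

test_that("permutation p-values are approximately uniform under the null", {
  g <- withr::with_seed(33, make_genome(c(
    c1 = paste(sample(c("A", "C", "G", "T"), 20000, replace = TRUE), collapse = ""))))
  pk <- tibble(contig = "c1", summit = seq(200, 19500, by = 320), strand = "+")
  w <- extract_windows(pk, g)
  half <- seq_len(nrow(w) %/% 2)
  ps <- vapply(1:150, function(b) {
    idx <- withr::with_seed(500 + b, sample(nrow(w)))
    center_enrichment(w[idx[half], ], w[idx[-half], ], "DRACH",
                      n_perm = 99, seed = b)$p_value
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
})
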