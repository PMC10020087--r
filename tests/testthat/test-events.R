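test_that("a cassette-exon gene yields one SE event with the right geometry", {
  ev <- build_events(toy_se_gene())
  expect_equal(nrow(ev), 1)
  expect_equal(ev$type, "SE")
  expect_equal(ev$inclusion[[1]], "t_inc")
  expect_equal(ev$exclusion[[1]], "t_exc")
  expect_equal(c(ev$flank_up_start, ev$flank_up_end), c(100, 200))
  expect_equal(c(ev$flank_down_start, ev$flank_down_end), c(300, 400))
})

test_that("an intron-retaining pair yields one RI event", {
  ann <- bind_rows(
    tx_rows("g1", "t_ret", list(c(0, 500))),
    tx_rows("g1", "t_spl", list(c(0, 200), c(300, 500)))
  )
  ev <- build_events(ann)
  expect_equal(ev$type, "RI")
  expect_equal(ev$inclusion[[1]], "t_ret")
  expect_equal(ev$exclusion[[1]], "t_spl")
})

test_that("single-transcript genes yield no events", {
  ann <- tx_rows("g1", "t1", list(c(0, 100), c(200, 300)))
  expect_equal(nrow(build_events(ann)), 0)
})

test_that("the five-transcript toy gene yields the hand-enumerated event set", {
  ev <- build_events(toy_multi_gene())
  expect_equal(sort(ev$type), c("A5", "MX", "RI", "SE", "SE"))
  by_type <- split(ev, ev$type)

  se <- by_type$SE |> arrange(.data$flank_up_end)
  # cassette (200,300): t1 and t5 carry both junctions; cassette (320,360): t4
  expect_equal(se$inclusion, list(c("t1", "t5"), "t4"))
  expect_equal(se$exclusion, list("t2", "t2"))

  expect_equal(by_type$A5$inclusion[[1]], "t3")        # longer first exon (0,140)
  expect_equal(by_type$A5$exclusion[[1]], c("t1", "t5"))

  expect_equal(by_type$MX$inclusion[[1]], c("t1", "t5"))  # 5'-proximal exon (200,300)
  expect_equal(by_type$MX$exclusion[[1]], "t4")

  expect_equal(by_type$RI$inclusion[[1]], "t5")
  expect_equal(by_type$RI$exclusion[[1]], c("t1", "t2", "t3", "t4"))
})

test_that("event extraction is strand-symmetric under coordinate mirroring", {
  ann <- toy_multi_gene()
  ev_fwd <- build_events(ann)
  ev_rev <- build_events(mirror_annotation(ann, 800))
  # mirroring plus strand flip preserves the biological class and membership
  key <- function(ev) {
    ev |>
      mutate(inc = map_chr(.data$inclusion, paste, collapse = ","),
             exc = map_chr(.data$exclusion, paste, collapse = ",")) |>
      select("type", "inc", "exc") |>
      arrange(.data$type, .data$inc)
  }
  expect_equal(key(ev_fwd), key(ev_rev))
})

test_that("events are invariant to transcript input order", {
  ann <- toy_multi_gene()
  shuffled <- ann[withr::with_seed(1, sample(nrow(ann))), ]
  expect_equal(build_events(ann), build_events(shuffled))
})

test_that("all listed transcripts exist in their gene and sets are disjoint", {
  cfg <- sim_config(n_genes = 60, seed = 4)
  ann <- sim_annotation(cfg)
  ev <- build_events(ann)
  tx_by_gene <- split(ann$transcript_id, ann$gene_id)
  for (i in seq_len(nrow(ev))) {
    inc <- ev$inclusion[[i]]; exc <- ev$exclusion[[i]]
    expect_gt(length(inc), 0)
    expect_gt(length(exc), 0)
    expect_length(intersect(inc, exc), 0)
    expect_true(all(c(inc, exc) %in% tx_by_gene[[ev$gene_id[i]]]))
  }
})

test_that("overlapping exons within a transcript are rejected by name", {
  ann <- bind_rows(
    tx_rows("g1", "bad_tx", list(c(0, 100), c(50, 200))),
    tx_rows("g1", "t2", list(c(0, 100), c(300, 400)))
  )
  expect_error(build_events(ann), "bad_tx")
})

test_that("the simulator's planted events are recovered with type and inclusion", {
  cfg <- sim_config(n_genes = 70, seed = 3)
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann)
  ev <- build_events(ann)
  expect_equal(nrow(ev), nrow(truth))
  j <- ev |>
    mutate(inc = map_chr(.data$inclusion, 1)) |>
    inner_join(truth, by = "gene_id", suffix = c("_ev", "_tr"))
  expect_equal(j$type_ev, j$type_tr)
  expect_equal(j$inc, j$inclusion_tx)
})

test_that("the 50-nt rule flags premature stops strictly", {
  base <- tx_rows("g1", "t1", list(c(0, 200), c(300, 500)))
  cds_up_to <- function(mrna_stop) {
    # CDS from mRNA position 3 to mrna_stop on the plus strand
    if (mrna_stop <= 200) {
      exon_row("g1", "t1", 3, mrna_stop, feature = "CDS")
    } else {
      bind_rows(exon_row("g1", "t1", 3, 200, feature = "CDS"),
                exon_row("g1", "t1", 300, 300 + (mrna_stop - 200), feature = "CDS"))
    }
  }
  # last junction at mRNA position 200
  f60 <- flag_nmd(bind_rows(base, cds_up_to(140)))   # 60 nt upstream
  expect_true(f60$is_ptc)
  expect_equal(f60$stop_to_last_junction, 60)
  f50 <- flag_nmd(bind_rows(base, cds_up_to(150)))   # exactly 50: not PTC
  expect_false(f50$is_ptc)
  fin <- flag_nmd(bind_rows(base, cds_up_to(250)))   # stop inside last exon
  expect_false(fin$is_ptc)
})

test_that("NMD flags are absent without CDS and correct on the minus strand", {
  expect_equal(nrow(flag_nmd(toy_se_gene())), 0)
  # minus strand: mRNA runs right to left; stop 60 nt upstream of the last
  # junction sits in the genomically-left exon
  ann <- bind_rows(
    tx_rows("g1", "t1", list(c(0, 200), c(300, 500)), strand = "-"),
    exon_row("g1", "t1", 300, 497, strand = "-", feature = "CDS"),
    exon_row("g1", "t1", 60, 200, strand = "-", feature = "CDS")
  )
  # transcript length 400, last junction (5'->3') at mRNA 200; the CDS ends
  # at genomic 60, i.e. mRNA 340, downstream of the junction: not a PTC
  f <- flag_nmd(ann)
  expect_equal(f$stop_to_last_junction, 200 - 340)
  expect_false(f$is_ptc)
  ann2 <- bind_rows(
    tx_rows("g1", "t1", list(c(0, 200), c(300, 500)), strand = "-"),
    exon_row("g1", "t1", 360, 497, strand = "-", feature = "CDS")
  )
  f2 <- flag_nmd(ann2)                               # stop ends at mRNA 140
  expect_equal(f2$stop_to_last_junction, 60)
  expect_true(f2$is_ptc)
})

test_that("simulated PTC planting matches the recomputed flags", {
  cfg <- sim_config(n_genes = 80, seed = 12, ptc_fraction = 0.4)
  ann <- sim_annotation(cfg)
  truth <- sim_truth(ann)
  nmd <- flag_nmd(ann)
  j <- nmd |>
    inner_join(truth |> select("gene_id", "exclusion_tx", "ptc_exclusion"),
               by = "gene_id") |>
    filter(.data$transcript_id == .data$exclusion_tx)
  expect_equal(j$is_ptc, j$ptc_exclusion)
  inc <- nmd |> anti_join(j, by = "transcript_id")
  expect_false(any(inc$is_ptc))
})
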