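#' Derive alternative-splicing events from a gene annotation
#'
#' Scans every gene with at least two transcripts for local structural
#' differences and emits one event per difference, classified into the seven
#' canonical types: skipped exon (SE), retained intron (RI), mutually
#' exclusive exons (MX), alternative 5'/3' splice site (A5/A3) and
#' alternative first/last exon (AF/AL). Inclusion and exclusion transcript
#' sets contain every transcript of the gene compatible with the respective
#' form, identified through exon-exon junctions (and exact exon boundaries
#' for RI and terminal exons).
#'
#' Orientation conventions: the inclusion form is the cassette-containing
#' transcript (SE), the intron-retaining transcript (RI), the genomically
#' left alternative exon (MX), the shorter-intron form (A5/A3), and the
#' distal terminal exon (AF/AL). A5/A3 and AF/AL are strand-mirrored: the
#' same genomic configuration is A5 on `+` and A3 on `-`, AF on `+` and AL
#' on `-`. MX requires the two exons to share both flanking splice sites and
#' not overlap; A5/A3 require the alternative-boundary exons to overlap;
#' AF/AL require distinct non-overlapping terminal exons joined to a shared
#' splice site (tandem starts within one terminal exon are ignored).
#'
#' @param annotation Exon-level annotation tibble with columns `contig`,
#'   `start`, `end` (0-based half-open), `strand`, `feature`, `gene_id`,
#'   `transcript_id` (e.g. from [read_gtf()] or [sim_annotation()]).
#' @return A tibble with one row per event: `event_id` (ioe-style
#'   `gene;TYPE:contig:coords:strand`), `gene_id`, `type`, `contig`,
#'   `strand`, list columns `inclusion` and `exclusion` (transcript ids),
#'   the SE flanking introns (`flank_up_start`, `flank_up_end`,
#'   `flank_down_start`, `flank_down_end`; `NA` for other types) and a
#'   `coords` list column of defining coordinates.
#' @examples
#' ann <- sim_annotation(sim_config(n_genes = 7, seed = 1))
#' build_events(ann)
#' @export
build_events <- function(annotation) {
  assert_columns(annotation, c("contig", "start", "end", "strand", "feature",
                               "gene_id", "transcript_id"), "annotation")
  ex <- annotation |> filter(.data$feature == "exon")
  out <- ex |>
    group_by(.data$gene_id) |>
    group_map(~ gene_events(.x, .y$gene_id)) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(event_id = character(), gene_id = character(), type = character(),
                  contig = character(), strand = character(),
                  inclusion = list(), exclusion = list(),
                  flank_up_start = numeric(), flank_up_end = numeric(),
                  flank_down_start = numeric(), flank_down_end = numeric(),
                  coords = list()))
  }
  out |> arrange(.data$event_id)
}

# all events of one gene
gene_events <- function(ex, gid) {
  ctg <- ex$contig[1]
  strand <- ex$strand[1]
  txs <- split(ex, ex$transcript_id)
  if (length(txs) < 2) return(NULL)
  txs <- lapply(txs, function(t) {
    t <- t[order(t$start), ]
    check_transcript_exons(t$start, t$end, t$transcript_id[1])
    n <- nrow(t)
    list(id = t$transcript_id[1], starts = t$start, ends = t$end, n = n,
         jkeys = if (n > 1) paste(t$end[-n], t$start[-1]) else character())
  })
  tx_ids <- names(txs)
  has_junc <- function(tx, s, e) paste(s, e) %in% tx$jkeys
  has_exon <- function(tx, s, e) any(tx$starts == s & tx$ends == e)
  with_junc <- function(s, e) tx_ids[map_lgl(txs, has_junc, s, e)]
  with_juncs <- function(s1, e1, s2, e2) {
    tx_ids[map_lgl(txs, function(t) has_junc(t, s1, e1) && has_junc(t, s2, e2))]
  }
  with_exon <- function(s, e) tx_ids[map_lgl(txs, has_exon, s, e)]

  events <- list()
  seen <- character()
  add <- function(key, row) {
    if (key %in% seen) return()
    if (length(row$inclusion[[1]]) == 0 || length(row$exclusion[[1]]) == 0) return()
    seen <<- c(seen, key)
    events[[length(events) + 1]] <<- row
  }
  ev_row <- function(type, id_body, inc, exc, flank = rep(NA_real_, 4), coords) {
    tibble(event_id = glue("{gid};{type}:{ctg}:{id_body}:{strand}"),
           gene_id = gid, type = type, contig = ctg, strand = strand,
           inclusion = list(sort(unique(inc))), exclusion = list(sort(unique(exc))),
           flank_up_start = unname(flank[1]), flank_up_end = unname(flank[2]),
           flank_down_start = unname(flank[3]), flank_down_end = unname(flank[4]),
           coords = list(coords))
  }

  # --- SE: cassette exon bounded by junctions (e1,s2) (e2,s3) vs (e1,s3)
  for (t in txs) {
    if (t$n < 3) next
    for (i in 2:(t$n - 1)) {
      e1 <- t$ends[i - 1]; s2 <- t$starts[i]; e2 <- t$ends[i]; s3 <- t$starts[i + 1]
      exc <- with_junc(e1, s3)
      if (length(exc) == 0) next
      inc <- with_juncs(e1, s2, e2, s3)
      add(paste("SE", e1, s2, e2, s3),
          ev_row("SE", glue("{e1}-{s2 + 1}:{e2}-{s3 + 1}"), inc, exc,
                 flank = c(e1, s2, e2, s3),
                 coords = c(e1 = e1, s2 = s2, e2 = e2, s3 = s3)))
    }
  }

  # --- RI: exon (s1,e2) spanning the intron (e1,s2) of an (s1,e1),(s2,e2) pair
  for (t in txs) {
    if (t$n < 2) next
    for (i in 1:(t$n - 1)) {
      s1 <- t$starts[i]; e1 <- t$ends[i]; s2 <- t$starts[i + 1]; e2 <- t$ends[i + 1]
      inc <- with_exon(s1, e2)
      if (length(inc) == 0) next
      exc <- tx_ids[map_lgl(txs, function(x) {
        has_junc(x, e1, s2) && has_exon(x, s1, e1) && has_exon(x, s2, e2)
      })]
      add(paste("RI", s1, e1, s2, e2),
          ev_row("RI", glue("{s1 + 1}:{e1}-{s2 + 1}:{e2}"), inc, exc,
                 coords = c(s1 = s1, e1 = e1, s2 = s2, e2 = e2)))
    }
  }

  # intron inventory with the extremal extents of the abutting exons
  introns <- bind_rows(lapply(txs, function(t) {
    if (t$n < 2) return(NULL)
    tibble(s = t$ends[-t$n], e = t$starts[-1],
           up_s = t$starts[-t$n], dn_e = t$ends[-1])
  })) |>
    group_by(.data$s, .data$e) |>
    summarise(up_s = min(.data$up_s), dn_e = max(.data$dn_e), .groups = "drop")

  if (nrow(introns) > 1) {
    # --- alternative donor/acceptor: introns sharing one boundary whose
    # alternative-side exons overlap
    by_e <- split(seq_len(nrow(introns)), introns$e)
    for (idx in by_e[lengths(by_e) > 1]) {
      for (a in idx) for (b in idx) {
        if (introns$s[a] >= introns$s[b]) next
        d1 <- introns$s[a]; d2 <- introns$s[b]; acc <- introns$e[a]
        if (max(introns$up_s[a], introns$up_s[b]) >= d1) next  # exons must overlap
        type <- if (strand == "+") "A5" else "A3"
        inc <- with_junc(d2, acc); exc <- with_junc(d1, acc)
        add(paste("ALTL", d1, d2, acc),
            ev_row(type, glue("{d2}-{acc + 1}:{d1}-{acc + 1}"), inc, exc,
                   coords = c(d_inc = d2, d_exc = d1, a = acc)))
      }
    }
    by_s <- split(seq_len(nrow(introns)), introns$s)
    for (idx in by_s[lengths(by_s) > 1]) {
      for (a in idx) for (b in idx) {
        if (introns$e[a] >= introns$e[b]) next
        a1 <- introns$e[a]; a2 <- introns$e[b]; don <- introns$s[a]
        if (a2 >= min(introns$dn_e[a], introns$dn_e[b])) next    # exons must overlap
        type <- if (strand == "+") "A3" else "A5"
        inc <- with_junc(don, a1); exc <- with_junc(don, a2)
        add(paste("ALTR", don, a1, a2),
            ev_row(type, glue("{don}-{a1 + 1}:{don}-{a2 + 1}"), inc, exc,
                   coords = c(d = don, a_inc = a1, a_exc = a2)))
      }
    }
  }

  # --- MX: internal exons sharing both flanking splice sites, not overlapping
  internal <- bind_rows(lapply(txs, function(t) {
    if (t$n < 3) return(NULL)
    i <- 2:(t$n - 1)
    tibble(e1 = t$ends[i - 1], xs = t$starts[i], xe = t$ends[i], s4 = t$starts[i + 1])
  }))
  if (nrow(internal) > 1) {
    internal <- distinct(internal)
    for (a in seq_len(nrow(internal))) for (b in seq_len(nrow(internal))) {
      if (a == b) next
      if (internal$e1[a] != internal$e1[b] || internal$s4[a] != internal$s4[b]) next
      if (internal$xs[a] >= internal$xs[b]) next
      if (internal$xe[a] > internal$xs[b]) next   # must be mutually exclusive
      e1 <- internal$e1[a]; s4 <- internal$s4[a]
      # inclusion = the exon proximal to the transcript 5' end
      if (strand == "+") {
        xs <- internal$xs[a]; xe <- internal$xe[a]
        ys <- internal$xs[b]; ye <- internal$xe[b]
      } else {
        xs <- internal$xs[b]; xe <- internal$xe[b]
        ys <- internal$xs[a]; ye <- internal$xe[a]
      }
      inc <- with_juncs(e1, xs, xe, s4)
      exc <- with_juncs(e1, ys, ye, s4)
      add(paste("MX", e1, xs, xe, ys, ye, s4),
          ev_row("MX", glue("{e1}-{xs + 1}:{xe}-{s4 + 1}:{e1}-{ys + 1}:{ye}-{s4 + 1}"),
                 inc, exc,
                 coords = c(e1 = e1, xs = xs, xe = xe, ys = ys, ye = ye, s4 = s4)))
    }
  }

  # --- alternative terminal exons: distinct non-overlapping leftmost
  # (rightmost) exons spliced to a shared acceptor (donor)
  term <- lapply(txs, function(t) {
    if (t$n < 2) return(NULL)
    list(lf_s = t$starts[1], lf_e = t$ends[1], lf_a = t$starts[2],
         rt_s = t$starts[t$n], rt_e = t$ends[t$n], rt_d = t$ends[t$n - 1])
  })
  term <- term[!vapply(term, is.null, logical(1))]
  if (length(term) > 1) {
    for (a in seq_along(term)) for (b in seq_along(term)) {
      ta <- term[[a]]; tb <- term[[b]]
      # left pattern: AF on '+', AL on '-'; inclusion = distal (leftmost)
      if (ta$lf_a == tb$lf_a && ta$lf_s < tb$lf_s && ta$lf_e <= tb$lf_s) {
        type <- if (strand == "+") "AF" else "AL"
        acc <- ta$lf_a
        inc <- tx_ids[map_lgl(txs, function(x) {
          x$n > 1 && x$ends[1] == ta$lf_e && has_junc(x, ta$lf_e, acc)
        })]
        exc <- tx_ids[map_lgl(txs, function(x) {
          x$n > 1 && x$ends[1] == tb$lf_e && has_junc(x, tb$lf_e, acc)
        })]
        add(paste("TERML", ta$lf_e, tb$lf_e, acc),
            ev_row(type,
                   glue("{ta$lf_s + 1}:{ta$lf_e}-{acc + 1}:{tb$lf_s + 1}:{tb$lf_e}-{acc + 1}"),
                   inc, exc,
                   coords = c(x1s = ta$lf_s, x1e = ta$lf_e,
                              x2s = tb$lf_s, x2e = tb$lf_e, a = acc)))
      }
      # right pattern: AL on '+', AF on '-'; inclusion = distal (rightmost)
      if (ta$rt_d == tb$rt_d && ta$rt_e > tb$rt_e && ta$rt_s >= tb$rt_e) {
        type <- if (strand == "+") "AL" else "AF"
        don <- ta$rt_d
        inc <- tx_ids[map_lgl(txs, function(x) {
          x$n > 1 && x$starts[x$n] == ta$rt_s && has_junc(x, don, ta$rt_s)
        })]
        exc <- tx_ids[map_lgl(txs, function(x) {
          x$n > 1 && x$starts[x$n] == tb$rt_s && has_junc(x, don, tb$rt_s)
        })]
        add(paste("TERMR", ta$rt_s, tb$rt_s, don),
            ev_row(type,
                   glue("{don}-{ta$rt_s + 1}:{ta$rt_e}:{don}-{tb$rt_s + 1}:{tb$rt_e}"),
                   inc, exc,
                   coords = c(d = don, x1s = ta$rt_s, x1e = ta$rt_e,
                              x2s = tb$rt_s, x2e = tb$rt_e)))
      }
    }
  }

  if (length(events) == 0) return(NULL)
  bind_rows(events)
}

#' Flag transcripts for premature termination codons (50-nt rule)
#'
#' For every transcript with an annotated CDS, measures the distance, in mRNA
#' coordinates, from the end of the stop codon to the last exon-exon
#' junction. A transcript is flagged PTC+ (a nonsense-mediated-decay target)
#' when the stop lies strictly more than 50 nt upstream of that junction;
#' stops in the last exon (negative distance) and single-exon transcripts are
#' never flagged. Transcripts without a CDS are absent from the result.
#'
#' @inheritParams build_events
#' @return A tibble: `transcript_id`, `gene_id`, `is_ptc`,
#'   `stop_to_last_junction` (nt; `NA` for single-exon transcripts).
#' @export
flag_nmd <- function(annotation) {
  assert_columns(annotation, c("contig", "start", "end", "strand", "feature",
                               "gene_id", "transcript_id"), "annotation")
  cds_tx <- unique(annotation$transcript_id[annotation$feature == "CDS"])
  if (length(cds_tx) == 0) {
    return(tibble(transcript_id = character(), gene_id = character(),
                  is_ptc = logical(), stop_to_last_junction = numeric()))
  }
  ann <- annotation |> filter(.data$transcript_id %in% cds_tx)
  ann |>
    group_by(.data$gene_id, .data$transcript_id) |>
    group_map(function(t, key) {
      strand <- t$strand[1]
      exons <- t |> filter(.data$feature == "exon") |> arrange(.data$start)
      cds <- t |> filter(.data$feature == "CDS")
      lens <- exons$end - exons$start
      L <- sum(lens)
      n <- nrow(exons)
      if (n == 1) {
        return(tibble(transcript_id = key$transcript_id, gene_id = key$gene_id,
                      is_ptc = FALSE, stop_to_last_junction = NA_real_))
      }
      ord_lens <- if (strand == "+") lens else rev(lens)
      last_junction <- L - ord_lens[n]
      # mRNA coordinate of the stop-codon end (3'-most CDS base + 1)
      offs <- c(0, cumsum(ord_lens))[seq_len(n)]
      if (strand == "+") {
        g <- max(cds$end)
        i <- which(exons$start < g & g <= exons$end)
        stop_end <- offs[i] + (g - exons$start[i])
      } else {
        g <- min(cds$start)
        i_rev <- which(exons$start <= g & g < exons$end)
        i <- n - i_rev + 1                     # transcript-order index
        stop_end <- offs[i] + (exons$end[i_rev] - g)
      }
      d <- unname(last_junction - stop_end)
      tibble(transcript_id = key$transcript_id, gene_id = key$gene_id,
             is_ptc = d > 50, stop_to_last_junction = d)
    }) |>
    bind_rows()
}
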