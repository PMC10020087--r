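#' Simulate a multi-isoform gene annotation with planted splicing events
#'
#' Generates one gene per row of the design, each carrying exactly one
#' alternative-splicing event of an assigned type (SE, RI, MX, A5, A3, AF or
#' AL), realized by two transcripts. Every gene lives on its own contig with
#' `pad` nucleotides of flank on both sides, so downstream interval work never
#' has to resolve overlaps between genes. Each transcript gets a CDS; a
#' configurable fraction of exclusion-form transcripts is planted with a stop
#' codon more than 50 nt upstream of the last exon-exon junction (PTC+).
#'
#' The transcript realizing the *inclusion* form follows the same conventions
#' [build_events()] uses to orient events: the cassette-containing form (SE),
#' the intron-retaining form (RI), the genomically left exon (MX), the
#' shorter-intron form (A5/A3), and the distal terminal exon (AF/AL).
#'
#' @param config A [sim_config()] object.
#' @param seed Optional seed overriding `config$seed`.
#' @return A tibble of exon/CDS records with columns `contig`, `start`, `end`
#'   (0-based half-open), `strand`, `feature`, `gene_id`, `transcript_id`.
#'   Ground truth (event type, inclusion/exclusion transcripts, SE flanking
#'   introns, planted PTC status, contig lengths) is attached as the
#'   `"sim_truth"` attribute; retrieve it with [sim_truth()].
#' @examples
#' ann <- sim_annotation(sim_config(n_genes = 7, seed = 1))
#' sim_truth(ann)
#' @export
sim_annotation <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  seed <- seed %||% config$seed
  withr::with_seed(seed, sim_annotation_impl(config))
}

sim_annotation_impl <- function(config) {
  types <- names(config$event_mix)
  # largest-remainder apportionment of the event mix, then a seeded shuffle
  raw <- config$event_mix * config$n_genes
  n_k <- floor(raw)
  rem <- config$n_genes - sum(n_k)
  if (rem > 0) {
    extra <- order(raw - n_k, decreasing = TRUE)[seq_len(rem)]
    n_k[extra] <- n_k[extra] + 1
  }
  gene_types <- sample(rep(types, times = n_k))
  strands <- sample(c("+", "-"), config$n_genes, replace = TRUE)

  rows <- vector("list", config$n_genes)
  truth <- vector("list", config$n_genes)
  width <- max(4, nchar(config$n_genes) + 1)
  for (i in seq_len(config$n_genes)) {
    gid <- sprintf("g%0*d", width, i)
    g <- sim_gene(gid, gene_types[i], strands[i], config)
    rows[[i]] <- g$rows
    truth[[i]] <- g$truth
  }
  ann <- bind_rows(rows)
  attr(ann, "sim_truth") <- bind_rows(truth)
  ann
}

# geometry of one simulated gene; returns exon/CDS rows plus its truth record
sim_gene <- function(gid, type, strand, config) {
  el <- config$exon_len_range
  il <- config$intron_len_range
  rex <- function(n = 1) round(runif(n, el[1], el[2]))
  rin <- function(n = 1) round(runif(n, il[1], il[2]))
  pad <- config$pad
  ctg <- paste0("ctg_", gid)

  # archetypes are built in genomic space; on the minus strand the
  # donor/acceptor and first/last designations flip, so the archetype
  # realizing a requested type is strand-dependent for A5/A3/AF/AL
  archetype <- switch(type,
    SE = "SE", RI = "RI", MX = "MX",
    A5 = if (strand == "+") "alt_left" else "alt_right",
    A3 = if (strand == "+") "alt_right" else "alt_left",
    AF = if (strand == "+") "term_left" else "term_right",
    AL = if (strand == "+") "term_right" else "term_left"
  )

  flank <- c(NA_real_, NA_real_, NA_real_, NA_real_)
  if (archetype == "SE") {
    la <- rex(); lb <- rex(); lc <- rex(); i1 <- rin(); i2 <- rin()
    a <- c(pad, pad + la)
    b <- c(a[2] + i1, a[2] + i1 + lb)
    cc <- c(b[2] + i2, b[2] + i2 + lc)
    inc <- rbind(a, b, cc); exc <- rbind(a, cc)
    flank <- c(a[2], b[1], b[2], cc[1])
  } else if (archetype == "RI") {
    la <- rex(); lb <- rex(); i1 <- rin()
    a <- c(pad, pad + la)
    b <- c(a[2] + i1, a[2] + i1 + lb)
    inc <- rbind(c(a[1], b[2]))          # retained intron: one spanning exon
    exc <- rbind(a, b)
  } else if (archetype == "MX") {
    la <- rex(); lx <- rex(); ly <- rex(); lc <- rex()
    i1 <- rin(); i2 <- rin(); i3 <- rin()
    a <- c(pad, pad + la)
    x <- c(a[2] + i1, a[2] + i1 + lx)
    y <- c(x[2] + i2, x[2] + i2 + ly)
    cc <- c(y[2] + i3, y[2] + i3 + lc)
    # the inclusion form carries the transcript-5' proximal exon
    if (strand == "+") {
      inc <- rbind(a, x, cc); exc <- rbind(a, y, cc)
    } else {
      inc <- rbind(a, y, cc); exc <- rbind(a, x, cc)
    }
  } else if (archetype == "alt_left") {
    la <- rex(); lb <- rex(); i1 <- rin(); delta <- round(runif(1, 40, 120))
    s <- pad; d1 <- s + la; d2 <- d1 + delta
    acc <- d2 + i1
    inc <- rbind(c(s, d2), c(acc, acc + lb))   # longer exon, shorter intron
    exc <- rbind(c(s, d1), c(acc, acc + lb))
  } else if (archetype == "alt_right") {
    la <- rex(); lb <- rex(); i1 <- rin(); delta <- round(runif(1, 40, 120))
    a <- c(pad, pad + la)
    a1 <- a[2] + i1; a2 <- a1 + delta; e <- a2 + lb
    inc <- rbind(a, c(a1, e))                  # longer exon, shorter intron
    exc <- rbind(a, c(a2, e))
  } else if (archetype == "term_left") {
    l1 <- rex(); l2 <- rex(); lc <- rex(); gap <- round(runif(1, 60, 150)); i2 <- rin()
    f1 <- c(pad, pad + l1)
    f2 <- c(f1[2] + gap, f1[2] + gap + l2)
    cc <- c(f2[2] + i2, f2[2] + i2 + lc)
    inc <- rbind(f1, cc)                        # distal terminal exon
    exc <- rbind(f2, cc)
  } else { # term_right
    l1 <- rex(); l2 <- rex(); lc <- rex(); gap <- round(runif(1, 60, 150)); i1 <- rin()
    cc <- c(pad, pad + lc)
    x1 <- c(cc[2] + i1, cc[2] + i1 + l1)
    x2 <- c(x1[2] + gap, x1[2] + gap + l2)
    inc <- rbind(cc, x2)                        # distal terminal exon
    exc <- rbind(cc, x1)
  }

  tx_inc <- paste0(gid, ".t1"); tx_exc <- paste0(gid, ".t2")
  exon_rows <- function(m, tx) {
    tibble(contig = ctg, start = unname(m[, 1]), end = unname(m[, 2]),
           strand = strand, feature = "exon", gene_id = gid, transcript_id = tx)
  }
  rows <- bind_rows(exon_rows(inc, tx_inc), exon_rows(exc, tx_exc))

  ptc_exc <- runif(1) < config$ptc_fraction
  cds <- bind_rows(
    sim_cds(inc, strand, ctg, gid, tx_inc, ptc = FALSE),
    sim_cds(exc, strand, ctg, gid, tx_exc, ptc = ptc_exc)
  )
  rows <- bind_rows(rows, cds)

  contig_len <- max(rows$end) + pad
  truth <- tibble(
    gene_id = gid, type = type, contig = ctg, strand = strand,
    inclusion_tx = tx_inc, exclusion_tx = tx_exc,
    flank_up_start = flank[1], flank_up_end = flank[2],
    flank_down_start = flank[3], flank_down_end = flank[4],
    ptc_exclusion = ptc_exc, contig_length = contig_len
  )
  list(rows = rows, truth = truth)
}

# plant a CDS; for ptc = TRUE the stop ends well over 50 nt (in mRNA
# coordinates) upstream of the last exon-exon junction
sim_cds <- function(m, strand, ctg, gid, tx, ptc) {
  ex <- tibble(start = m[, 1], end = m[, 2])
  lens <- ex$end - ex$start
  L <- sum(lens)
  n <- nrow(ex)
  if (n == 1) {
    j <- NA_real_
    stop_end <- L - 5
  } else {
    ord_lens <- if (strand == "+") lens[order(ex$start)] else rev(lens[order(ex$start)])
    j <- L - ord_lens[n]                     # last junction, mRNA coords
    stop_end <- if (ptc) max(j - 80, 9) else min(j + 30, L - 5)
  }
  iv <- mrna_to_genomic(ex, strand, 3, stop_end)
  tibble(contig = ctg, start = iv$start, end = iv$end, strand = strand,
         feature = "CDS", gene_id = gid, transcript_id = tx)
}

#' Ground truth attached to a simulated annotation
#'
#' @param annotation A tibble produced by [sim_annotation()].
#' @return The per-gene ground-truth tibble (event type, inclusion and
#'   exclusion transcripts, SE flanking introns, planted PTC status and
#'   contig lengths).
#' @export
sim_truth <- function(annotation) {
  t <- attr(annotation, "sim_truth")
  if (is.null(t)) sw_abort("annotation carries no simulation ground truth")
  t
}

# reduced intronic intervals per gene (union over transcripts)
gene_introns <- function(annotation) {
  annotation |>
    filter(.data$feature == "exon") |>
    group_by(.data$gene_id, .data$contig, .data$strand, .data$transcript_id) |>
    arrange(.data$start, .by_group = TRUE) |>
    reframe(start = head(.data$end, -1), end = tail(.data$start, -1)) |>
    filter(.data$end > .data$start) |>
    distinct(.data$gene_id, .data$contig, .data$strand, .data$start, .data$end)
}
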