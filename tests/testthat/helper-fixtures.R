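library(dplyr)
library(tibble)
library(purrr)

# one exon row
exon_row <- function(gene, tx, start, end, strand = "+", contig = "c1",
                     feature = "exon") {
  tibble(contig = contig, start = start, end = end, strand = strand,
         feature = feature, gene_id = gene, transcript_id = tx)
}

# a transcript from a list of (start, end) pairs
tx_rows <- function(gene, tx, exons, strand = "+", contig = "c1") {
  bind_rows(lapply(exons, function(e) {
    exon_row(gene, tx, e[1], e[2], strand = strand, contig = contig)
  }))
}

# the two-transcript cassette-exon toy gene {A-B-C, A-C}
toy_se_gene <- function(strand = "+") {
  bind_rows(
    tx_rows("g1", "t_inc", list(c(0, 100), c(200, 300), c(400, 500)), strand),
    tx_rows("g1", "t_exc", list(c(0, 100), c(400, 500)), strand)
  )
}

# five-transcript toy gene with two SE, one A5, one MX and one RI event;
# expected inclusion/exclusion sets enumerated by hand from the junction
# definitions before the implementation was written
toy_multi_gene <- function() {
  bind_rows(
    tx_rows("g1", "t1", list(c(0, 100), c(200, 300), c(400, 500), c(600, 700))),
    tx_rows("g1", "t2", list(c(0, 100), c(400, 500), c(600, 700))),
    tx_rows("g1", "t3", list(c(0, 140), c(200, 300), c(400, 500), c(600, 700))),
    tx_rows("g1", "t4", list(c(0, 100), c(320, 360), c(400, 500), c(600, 700))),
    tx_rows("g1", "t5", list(c(0, 100), c(200, 300), c(400, 700)))
  )
}

# mirror an annotation: x -> L - x, flip strand (biological content unchanged)
mirror_annotation <- function(ann, L) {
  ann |>
    mutate(new_start = L - .data$end, new_end = L - .data$start,
           strand = ifelse(.data$strand == "+", "-", "+")) |>
    mutate(start = .data$new_start, end = .data$new_end) |>
    select(-"new_start", -"new_end")
}

# hand-made single-event table for PSI arithmetic tests
toy_event_tbl <- function(inc = "t_inc", exc = "t_exc") {
  tibble(event_id = "g1;SE:c1:100-201:300-401:+", gene_id = "g1", type = "SE",
         contig = "c1", strand = "+",
         inclusion = list(inc), exclusion = list(exc),
         flank_up_start = 100, flank_up_end = 200,
         flank_down_start = 300, flank_down_end = 400,
         coords = list(c(e1 = 100, s2 = 200, e2 = 300, s3 = 400)))
}

quant_row <- function(tx, sample, condition, tpm, count = 0) {
  tibble(transcript_id = tx, gene_id = "g1", length = 300,
         effective_length = 150, sample = sample, condition = condition,
         tpm = tpm, count = count)
}
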