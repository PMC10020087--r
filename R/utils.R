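# internal helpers shared across modules

# stop with a consistent error class
sw_abort <- function(msg, class = "splicewise_error") {
  abort(msg, class = class)
}

assert_columns <- function(df, cols, what = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    sw_abort(glue("`{what}` is missing required column(s): {paste(missing, collapse = ', ')}"))
  }
  invisible(df)
}

# check exons of one transcript are disjoint and well-formed; intervals are
# 0-based half-open so touching exons (end == next start) are also rejected:
# they would denote a spurious zero-length intron
check_transcript_exons <- function(starts, ends, transcript_id) {
  o <- order(starts)
  starts <- starts[o]; ends <- ends[o]
  if (any(ends <= starts)) {
    sw_abort(glue("transcript '{transcript_id}' has an exon with end <= start"))
  }
  if (length(starts) > 1 && any(starts[-1] < ends[-length(ends)])) {
    sw_abort(glue("transcript '{transcript_id}' has overlapping exons"))
  }
  invisible(TRUE)
}

# map mRNA coordinates (0-based, 5'->3' along the transcript) to genomic
# intervals, honouring strand; exons: tibble(start, end) genomic, any order
mrna_to_genomic <- function(exons, strand, mrna_start, mrna_end) {
  ex <- exons[order(exons$start), , drop = FALSE]
  if (strand == "-") ex <- ex[rev(seq_len(nrow(ex))), , drop = FALSE]
  lens <- ex$end - ex$start
  offs <- c(0, cumsum(lens))[seq_along(lens)]
  pieces <- list()
  for (i in seq_along(lens)) {
    lo <- max(mrna_start, offs[i])
    hi <- min(mrna_end, offs[i] + lens[i])
    if (hi <= lo) next
    if (strand == "+") {
      gs <- ex$start[i] + (lo - offs[i]); ge <- ex$start[i] + (hi - offs[i])
    } else {
      ge <- ex$end[i] - (lo - offs[i]); gs <- ex$end[i] - (hi - offs[i])
    }
    pieces[[length(pieces) + 1]] <- c(gs, ge)
  }
  if (length(pieces) == 0) return(tibble(start = numeric(), end = numeric()))
  m <- do.call(rbind, pieces)
  tibble(start = m[, 1], end = m[, 2]) |> arrange(.data$start)
}

# total mRNA length of a transcript
transcript_length <- function(exons) sum(exons$end - exons$start)

# convert an IUPAC / RNA motif to a DNA character string
motif_to_dna <- function(motif) {
  m <- toupper(motif)
  m <- gsub("U", "T", m)
  ok <- strsplit(m, "")[[1]] %in% strsplit("ACGTRYSWKMBDHVN", "")[[1]]
  if (!all(ok)) sw_abort(glue("motif '{motif}' contains non-IUPAC characters"))
  m
}

# deterministic child seed; keeps results below .Machine$integer.max
child_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 1103) %% 2147483647L)
}
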