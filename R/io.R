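#' Read a GTF annotation
#'
#' Imports exon and CDS records and converts the 1-based closed GTF
#' coordinates to the package-internal 0-based half-open convention (this is
#' the only place the conversion happens).
#'
#' @param path Path to a GTF file.
#' @return An annotation tibble: `contig`, `start`, `end`, `strand`,
#'   `feature` (`"exon"`/`"CDS"`), `gene_id`, `transcript_id`.
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) sw_abort(glue("GTF file not found: {path}"))
  gr <- rtracklayer::import(path, format = "gtf")
  keep <- as.character(gr$type) %in% c("exon", "CDS")
  gr <- gr[keep]
  tid <- gr$transcript_id
  if (is.null(tid) || anyNA(tid)) {
    bad <- if (is.null(tid)) seq_along(gr) else which(is.na(tid))
    sw_abort(glue("GTF record(s) without transcript_id (record ",
                  "{paste(head(bad, 5), collapse = ', ')} of the exon/CDS set)"))
  }
  tibble(
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    feature = as.character(gr$type),
    gene_id = gr$gene_id,
    transcript_id = tid
  )
}

#' Write an annotation tibble as GTF
#'
#' @param annotation Annotation tibble (0-based half-open coordinates).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(annotation, path) {
  assert_columns(annotation, c("contig", "start", "end", "strand", "feature",
                               "gene_id", "transcript_id"), "annotation")
  lines <- sprintf(
    '%s\tsplicewise\t%s\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
    annotation$contig, annotation$feature, as.integer(annotation$start + 1),
    as.integer(annotation$end), annotation$strand,
    annotation$gene_id, annotation$transcript_id)
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read a BED6(+summit) peak file
#'
#' Standard 0-based half-open BED. An optional 7th column gives the summit
#' offset from `start`; without it the summit is the interval midpoint.
#'
#' @param path Path to a BED file.
#' @return A peak tibble: `contig`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit` (absolute 0-based position).
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) sw_abort(glue("BED file not found: {path}"))
  raw <- readr::read_tsv(path, col_names = FALSE, comment = "#",
                         show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  if (nrow(raw) == 0) {
    return(tibble(contig = character(), start = numeric(), end = numeric(),
                  name = character(), score = numeric(), strand = character(),
                  summit = numeric()))
  }
  if (ncol(raw) < 3) sw_abort("BED file needs at least 3 columns")
  start <- suppressWarnings(as.numeric(raw[[2]]))
  end <- suppressWarnings(as.numeric(raw[[3]]))
  bad <- which(is.na(start) | is.na(end) | end <= start)
  if (length(bad) > 0) {
    sw_abort(glue("malformed BED record (end <= start or non-numeric) at line ",
                  "{paste(head(bad, 5), collapse = ', ')}"))
  }
  n <- nrow(raw)
  name <- if (ncol(raw) >= 4) raw[[4]] else sprintf("peak_%04d", seq_len(n))
  score <- if (ncol(raw) >= 5) suppressWarnings(as.numeric(raw[[5]])) else rep(0, n)
  strand <- if (ncol(raw) >= 6) raw[[6]] else rep("+", n)
  summit <- if (ncol(raw) >= 7) {
    off <- suppressWarnings(as.numeric(raw[[7]]))
    bad <- which(is.na(off) | off < 0 | start + off >= end)
    if (length(bad) > 0) {
      sw_abort(glue("summit offset outside the interval at line ",
                    "{paste(head(bad, 5), collapse = ', ')}"))
    }
    start + off
  } else {
    floor((start + end) / 2)
  }
  tibble(contig = raw[[1]], start = start, end = end, name = name,
         score = replace_na(score, 0), strand = strand, summit = summit)
}

#' Write peaks as BED6 + summit-offset
#'
#' @param peaks Peak tibble (`summit` written as an offset from `start`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  assert_columns(peaks, c("contig", "start", "end", "name", "score", "strand",
                          "summit"), "peaks")
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s\t%d",
                   peaks$contig, as.integer(peaks$start), as.integer(peaks$end),
                   peaks$name, format(peaks$score, trim = TRUE), peaks$strand,
                   as.integer(peaks$summit - peaks$start))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Read per-sample transcript quantification tables
#'
#' Each file follows the pseudoalignment-quantifier layout with header
#' `Name  Length  EffectiveLength  TPM  NumReads` (parsed by name).
#' Transcripts absent from a sample are zero-filled with a warning.
#'
#' @param paths Named character vector: sample name -> file path.
#' @param conditions Named character vector: sample name -> condition label.
#' @return A long quantification tibble: `transcript_id`, `length`,
#'   `effective_length`, `sample`, `condition`, `tpm`, `count`.
#' @export
read_quant_tables <- function(paths, conditions) {
  if (is.null(names(paths)) || any(names(paths) == "")) {
    sw_abort("`paths` must be named by sample")
  }
  missing_cond <- setdiff(names(paths), names(conditions))
  if (length(missing_cond) > 0) {
    sw_abort(glue("no condition given for sample(s): {paste(missing_cond, collapse = ', ')}"))
  }
  tabs <- imap(paths, function(p, s) {
    if (!file.exists(p)) sw_abort(glue("quantification file not found: {p}"))
    d <- readr::read_tsv(p, show_col_types = FALSE)
    need <- c("Name", "Length", "EffectiveLength", "TPM", "NumReads")
    assert_columns(d, need, p)
    tibble(transcript_id = d$Name, length = d$Length,
           effective_length = d$EffectiveLength, sample = s,
           condition = unname(conditions[s]), tpm = d$TPM, count = d$NumReads)
  })
  long <- bind_rows(tabs)
  universe <- long |> distinct(.data$transcript_id, .data$length, .data$effective_length)
  full <- tidyr::expand_grid(universe,
                             tibble(sample = names(paths),
                                    condition = unname(conditions[names(paths)])))
  out <- full |>
    left_join(long, by = c("transcript_id", "length", "effective_length",
                           "sample", "condition"))
  n_fill <- sum(is.na(out$tpm))
  if (n_fill > 0) {
    warn(glue("read_quant_tables: zero-filled {n_fill} missing transcript/sample pair(s)"))
  }
  out |> mutate(tpm = replace_na(.data$tpm, 0), count = replace_na(.data$count, 0))
}

#' Write a quantification tibble as per-sample tables
#'
#' @param quant Long quantification tibble (see [read_quant_tables()]).
#' @param dir Output directory; one `<sample>.quant.tsv` per sample.
#' @return The written paths, invisibly.
#' @export
write_quant_tables <- function(quant, dir) {
  assert_columns(quant, c("transcript_id", "length", "effective_length",
                          "sample", "tpm", "count"), "quant")
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- quant |>
    group_by(.data$sample) |>
    group_map(function(d, key) {
      p <- file.path(dir, paste0(key$sample, ".quant.tsv"))
      readr::write_tsv(
        tibble(Name = d$transcript_id, Length = d$length,
               EffectiveLength = d$effective_length, TPM = d$tpm,
               NumReads = d$count), p)
      p
    })
  invisible(unlist(paths))
}

#' Write / read the event table (ioe-like TSV)
#'
#' Columns: `event_id`, `gene_id`, `type`, comma-separated
#' `inclusion_transcripts` and `total_transcripts`, and the SE flanking
#' introns. The defining-coordinate list column is not serialized.
#'
#' @param events Event tibble from [build_events()].
#' @param path File path.
#' @return `path` invisibly ([write_event_table()]); an event tibble
#'   ([read_event_table()]).
#' @export
write_event_table <- function(events, path) {
  tab <- events |>
    mutate(inclusion_transcripts = map_chr(.data$inclusion, paste, collapse = ","),
           total_transcripts = map_chr(map2(.data$inclusion, .data$exclusion,
                                            ~ sort(c(.x, .y))), paste, collapse = ",")) |>
    select("event_id", "gene_id", "type", "contig", "strand",
           "inclusion_transcripts", "total_transcripts",
           "flank_up_start", "flank_up_end", "flank_down_start", "flank_down_end")
  readr::write_tsv(tab, path)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  d |>
    mutate(inclusion = map(strsplit(.data$inclusion_transcripts, ","), identity),
           total = map(strsplit(.data$total_transcripts, ","), identity),
           exclusion = map2(.data$total, .data$inclusion, setdiff)) |>
    select("event_id", "gene_id", "type", "contig", "strand",
           "inclusion", "exclusion",
           "flank_up_start", "flank_up_end", "flank_down_start", "flank_down_end")
}

#' Read / write a clinical survival table
#'
#' TSV with columns `patient_id`, `time`, `status`, optional `expression`,
#' and one PSI column per event.
#'
#' @param path File path.
#' @return A cohort tibble ([read_clinical()]); `path` invisibly
#'   ([write_clinical()]).
#' @export
read_clinical <- function(path) {
  d <- readr::read_tsv(path, show_col_types = FALSE)
  assert_columns(d, c("patient_id", "time", "status"), path)
  if (any(d$time <= 0, na.rm = TRUE)) sw_abort("clinical table has non-positive times")
  d
}

#' @rdname read_clinical
#' @param cohort Cohort tibble.
#' @export
write_clinical <- function(cohort, path) {
  readr::write_tsv(cohort, path)
  invisible(path)
}
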