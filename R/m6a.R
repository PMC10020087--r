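#' Assign m6A peaks to the flanking introns of skipped exons
#'
#' An SE event is flagged m6A-positive when at least one peak *summit* falls
#' inside either flanking intron of its cassette exon (summit containment,
#' not any-overlap: a peak straddling an exon-intron boundary counts only
#' where its summit lies). With `rule = "overlap"` any overlap between a
#' peak interval and a flanking intron counts instead.
#'
#' @param peaks Peak tibble with columns `contig`, `start`, `end`, `summit`
#'   (from [read_bed()] or [sim_peaks()]).
#' @param events Event tibble from [build_events()]; only SE events have
#'   flanking introns, other types are rejected.
#' @param rule `"summit"` (default) or `"overlap"`.
#' @return A tibble `event_id`, `m6a` (logical).
#' @export
assign_peaks <- function(peaks, events, rule = c("summit", "overlap")) {
  rule <- match.arg(rule)
  assert_columns(peaks, c("contig", "start", "end", "summit"), "peaks")
  events <- events |> filter(.data$type == "SE")
  if (nrow(events) == 0) return(tibble(event_id = character(), m6a = logical()))
  if (nrow(peaks) > 0) {
    # peaks living entirely on foreign contigs indicate mismatched inputs
    unmatched <- setdiff(unique(peaks$contig), unique(events$contig))
    if (length(unmatched) == length(unique(peaks$contig))) {
      sw_abort(glue("assign_peaks: no peak contig matches the annotation ",
                    "(unmatched: {paste(head(unmatched, 5), collapse = ', ')})"))
    }
  }
  introns <- bind_rows(
    events |> transmute(.data$event_id, .data$contig,
                        s = .data$flank_up_start, e = .data$flank_up_end),
    events |> transmute(.data$event_id, .data$contig,
                        s = .data$flank_down_start, e = .data$flank_down_end)
  )
  hit <- if (rule == "summit") {
    inner_join(introns, peaks |> select("contig", "summit"),
               by = join_by(contig, s <= summit, e > summit))
  } else {
    inner_join(introns, peaks |> select("contig", "start", "end"),
               by = join_by(contig, s < end, e > start))
  }
  events |>
    transmute(.data$event_id, m6a = .data$event_id %in% hit$event_id)
}

#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Sums the hypergeometric probabilities, conditional on both margins, of
#' every table at most as probable as the observed one. Tables with a zero
#' margin carry no information and return p = 1 by convention.
#'
#' @param table A 2x2 numeric matrix (or something coercible to one) of
#'   non-negative integer counts.
#' @return The two-sided p-value.
#' @examples
#' fisher_exact(matrix(c(10, 0, 0, 10), 2))
#' @export
fisher_exact <- function(table) {
  m <- as.matrix(table)
  if (!all(dim(m) == c(2, 2)) || any(m < 0) || any(m != round(m))) {
    sw_abort("fisher_exact expects a 2x2 table of non-negative integers")
  }
  a <- m[1, 1]
  r1 <- sum(m[1, ]); c1 <- sum(m[, 1]); n <- sum(m)
  if (r1 == 0 || c1 == 0 || r1 == n || c1 == n) return(1)
  support <- max(0, r1 + c1 - n):min(r1, c1)
  probs <- dhyper(support, c1, n - c1, r1)
  obs <- probs[support == a]
  sum(probs[probs <= obs * (1 + 1e-7)])
}

#' Enrichment of intronic m6A among significant splicing events
#'
#' Cross-tabulates differential-splicing significance against the m6A flag
#' over a shared event universe and tests association with [fisher_exact()].
#' Also reports the fraction of significant events that are m6A-positive.
#'
#' @param dse_flags Tibble `event_id`, `significant` (logical).
#' @param m6a_flags Tibble `event_id`, `m6a` (logical), e.g. from
#'   [assign_peaks()].
#' @return An object of class `sw_enrichment`: a list with `table` (2x2
#'   matrix, rows significant/not, columns m6A+/m6A-), `p_value`,
#'   `frac_m6a_significant`, and `n`.
#' @export
enrichment_test <- function(dse_flags, m6a_flags) {
  assert_columns(dse_flags, c("event_id", "significant"), "dse_flags")
  assert_columns(m6a_flags, c("event_id", "m6a"), "m6a_flags")
  joined <- inner_join(dse_flags, m6a_flags, by = "event_id")
  if (nrow(joined) == 0) sw_abort("enrichment_test: the flag tables share no events")
  tab <- matrix(c(
    sum(joined$significant & joined$m6a),
    sum(joined$significant & !joined$m6a),
    sum(!joined$significant & joined$m6a),
    sum(!joined$significant & !joined$m6a)
  ), nrow = 2, byrow = TRUE,
  dimnames = list(c("significant", "not_significant"), c("m6a_pos", "m6a_neg")))
  n_sig <- sum(joined$significant)
  structure(list(
    table = tab,
    p_value = fisher_exact(tab),
    frac_m6a_significant = if (n_sig > 0) tab[1, 1] / n_sig else NA_real_,
    n = nrow(joined)
  ), class = "sw_enrichment")
}

#' @export
print.sw_enrichment <- function(x, ...) {
  cat("<sw_enrichment> Fisher's exact association\n")
  print(x$table)
  cat(glue("  p = {signif(x$p_value, 4)}; ",
           "m6A+ fraction among significant = {signif(x$frac_m6a_significant, 4)}"), "\n")
  invisible(x)
}

#' @export
tidy.sw_enrichment <- function(x, ...) {
  tibble(sig_pos = x$table[1, 1], sig_neg = x$table[1, 2],
         nonsig_pos = x$table[2, 1], nonsig_neg = x$table[2, 2],
         p_value = x$p_value, frac_pos_significant = x$frac_m6a_significant,
         n = x$n)
}

#' Association between PTC status and differential splicing
#'
#' Same machinery as [enrichment_test()], with the m6A flag replaced by
#' premature-termination-codon status: an event is PTC+ when any of its
#' participating transcripts carries a stop >50 nt upstream of its last
#' junction (see [flag_nmd()]).
#'
#' @param events Event tibble from [build_events()].
#' @param nmd_flags Output of [flag_nmd()].
#' @param dse_flags Tibble `event_id`, `significant` (logical).
#' @return An `sw_enrichment` object (columns labelled `ptc_pos`/`ptc_neg`).
#' @export
ptc_association <- function(events, nmd_flags, dse_flags) {
  assert_columns(nmd_flags, c("transcript_id", "is_ptc"), "nmd_flags")
  ptc_tx <- nmd_flags$transcript_id[nmd_flags$is_ptc]
  ptc_flags <- events |>
    transmute(.data$event_id,
              m6a = map_lgl(map2(.data$inclusion, .data$exclusion, c),
                            ~ any(.x %in% ptc_tx)))
  res <- enrichment_test(dse_flags, ptc_flags)
  colnames(res$table) <- c("ptc_pos", "ptc_neg")
  res
}
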