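#' Extract strand-corrected sequence windows around peak summits
#'
#' Cuts a `2 * half_width + 1` nt window centered on every peak summit from
#' the genome; minus-strand windows are reverse-complemented so position 0
#' always reads 5' to 3' through the summit. Windows that would run off a
#' contig end are dropped and counted in the `dropped` attribute.
#'
#' @param peaks Peak tibble with `contig`, `summit` and optionally `strand`.
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @param half_width Half window size in nt (default 150).
#' @return A tibble `contig`, `summit`, `strand`, `seq` (character, length
#'   `2 * half_width + 1`).
#' @export
extract_windows <- function(peaks, genome, half_width = 150) {
  assert_columns(peaks, c("contig", "summit"), "peaks")
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (nrow(peaks) == 0) {
    return(tibble(contig = character(), summit = numeric(),
                  strand = character(), seq = character()))
  }
  strand <- if ("strand" %in% names(peaks)) peaks$strand else rep("+", nrow(peaks))
  lens <- Biostrings::width(genome)[match(peaks$contig, names(genome))]
  if (anyNA(lens)) {
    sw_abort(glue("extract_windows: contig(s) missing from the genome: ",
                  "{paste(head(unique(peaks$contig[is.na(lens)]), 5), collapse = ', ')}"))
  }
  lo <- peaks$summit - half_width            # 0-based inclusive
  hi <- peaks$summit + half_width + 1        # 0-based exclusive
  ok <- lo >= 0 & hi <= lens
  dropped <- sum(!ok)
  if (dropped > 0) inform(glue("extract_windows: dropped {dropped} clipped window(s)"))
  pk <- peaks[ok, , drop = FALSE]
  strand <- strand[ok]
  seqs <- character(nrow(pk))
  for (i in seq_len(nrow(pk))) {
    s <- Biostrings::subseq(genome[[pk$contig[i]]], start = lo[ok][i] + 1, end = hi[ok][i])
    if (identical(strand[i], "-")) s <- Biostrings::reverseComplement(s)
    seqs[i] <- as.character(s)
  }
  out <- tibble(contig = pk$contig, summit = pk$summit, strand = strand, seq = seqs)
  attr(out, "dropped") <- dropped
  out
}

#' Sample matched random intronic windows
#'
#' Draws as many windows as there are peaks, of the same length, uniformly
#' from the intronic space of the genes that contain at least one peak —
#' the operational reading of "random regions with similar properties":
#' length-matched, intron-resident, from the same gene set. Each window lies
#' entirely inside one intron; introns shorter than a window are excluded.
#'
#' @inheritParams extract_windows
#' @param annotation Exon-level annotation tibble (defines the introns).
#' @param seed Integer seed for the sampler.
#' @return A tibble of windows as in [extract_windows()].
#' @export
match_random_regions <- function(peaks, annotation, genome, half_width = 150,
                                 seed = 1L) {
  if (nrow(peaks) == 0) {
    return(tibble(contig = character(), summit = numeric(),
                  strand = character(), seq = character()))
  }
  if (is.character(genome)) genome <- Biostrings::readDNAStringSet(genome)
  genes_with_peaks <- annotation |>
    filter(.data$feature == "exon", .data$contig %in% unique(peaks$contig)) |>
    distinct(.data$gene_id) |>
    pull("gene_id")
  introns <- gene_introns(annotation) |>
    filter(.data$gene_id %in% genes_with_peaks,
           .data$end - .data$start >= 2 * half_width + 1)
  if (nrow(introns) == 0) {
    sw_abort("match_random_regions: no intron can host a window of this size")
  }
  withr::with_seed(seed, {
    # choose introns with probability proportional to the number of valid
    # summit positions, then a uniform summit within each
    avail <- introns$end - introns$start - 2 * half_width
    idx <- sample(nrow(introns), nrow(peaks), replace = TRUE, prob = avail)
    summit <- floor(introns$start[idx] + half_width + runif(nrow(peaks)) * avail[idx])
    rnd <- tibble(contig = introns$contig[idx], summit = summit,
                  strand = introns$strand[idx])
    extract_windows(rnd, genome, half_width)
  })
}

#' Positional motif density around window centers
#'
#' Counts, at every offset in `range` relative to the window center, the
#' fraction of windows with a motif match *starting* at that offset.
#' IUPAC degeneracy is honored (e.g. `DRACH`); overlapping matches count.
#'
#' @param windows Window tibble from [extract_windows()] or
#'   [match_random_regions()].
#' @param motif IUPAC motif (RNA or DNA alphabet).
#' @param range Integer positions reported, relative to the center
#'   (default -80:80).
#' @param label Group label stored in the profile (e.g. "peaks", "random").
#' @return An `sw_profile` tibble: `position`, `density`, `label`, with the
#'   window count in the `n_windows` attribute.
#' @export
density_profile <- function(windows, motif, range = -80:80, label = "peaks") {
  motif <- motif_to_dna(motif)
  n <- nrow(windows)
  counts <- setNames(numeric(length(range)), range)
  if (n > 0) {
    half <- (nchar(windows$seq[1]) - 1) / 2
    subject <- Biostrings::DNAStringSet(windows$seq)
    # fixed = "subject": IUPAC degeneracy in the motif, literal subject
    # (an N in a window resolves nothing and matches nothing)
    hits <- Biostrings::vmatchPattern(motif, subject, fixed = "subject")
    for (i in seq_len(n)) {
      starts <- Biostrings::startIndex(hits)[[i]]
      if (is.null(starts)) next
      offs <- unique(starts - 1 - half)      # offset of match start vs center
      offs <- offs[offs >= min(range) & offs <= max(range)]
      if (length(offs) > 0) {
        k <- as.character(offs)
        counts[k] <- counts[k] + 1
      }
    }
    counts <- counts / n
  }
  out <- tibble(position = range, density = unname(counts), label = label)
  class(out) <- c("sw_profile", class(out))
  attr(out, "n_windows") <- n
  out
}

#' Central motif enrichment of peak windows over matched random windows
#'
#' Compares the mean motif density inside a central band (default +/-20 nt
#' around the summit) between the peak windows and the matched random
#' windows. The ratio is tested by permuting window group labels and
#' recomputing the ratio; the one-sided p-value is the add-one frequency of
#' permuted ratios at least as large as the observed one.
#'
#' @param windows_peaks,windows_random Window tibbles.
#' @param motif IUPAC motif.
#' @param band Central band half-width in nt (default 20).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutations.
#' @return A list: `ratio`, `p_value`, `density_peaks`, `density_random`,
#'   `n_perm`.
#' @export
center_enrichment <- function(windows_peaks, windows_random, motif,
                              band = 20, n_perm = 1000, seed = 1L) {
  motif <- motif_to_dna(motif)
  n1 <- nrow(windows_peaks); n2 <- nrow(windows_random)
  if (n1 == 0 || n2 == 0) sw_abort("center_enrichment: both window sets must be non-empty")
  half <- (nchar(windows_peaks$seq[1]) - 1) / 2
  all_seq <- Biostrings::DNAStringSet(c(windows_peaks$seq, windows_random$seq))
  hits <- Biostrings::vmatchPattern(motif, all_seq, fixed = "subject")
  # per-window central-band match count (density numerator)
  central <- vapply(seq_len(n1 + n2), function(i) {
    starts <- Biostrings::startIndex(hits)[[i]]
    if (is.null(starts)) return(0)
    offs <- starts - 1 - half
    sum(offs >= -band & offs <= band)
  }, numeric(1))
  ratio_of <- function(idx1) {
    m1 <- mean(central[idx1]); m2 <- mean(central[-idx1])
    (m1 + 1e-12) / (m2 + 1e-12)
  }
  obs <- ratio_of(seq_len(n1))
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      ratio_of(sample(n1 + n2, n1))
    }, numeric(1))
  })
  list(ratio = obs,
       p_value = (1 + sum(perm >= obs - 1e-12)) / (1 + n_perm),
       mean_central_peaks = mean(central[seq_len(n1)]),
       mean_central_random = mean(central[-seq_len(n1)]),
       n_perm = n_perm)
}

#' @export
autoplot.sw_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position, y = .data$density,
                                       colour = .data$label)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "position relative to summit (nt)",
                  y = "motif-start density per window", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot peak vs random motif-density profiles
#'
#' @param profile_peaks,profile_random `sw_profile` tibbles from
#'   [density_profile()].
#' @return A ggplot object.
#' @export
plot_density_profiles <- function(profile_peaks, profile_random) {
  df <- bind_rows(as_tibble(profile_peaks), as_tibble(profile_random))
  class(df) <- c("sw_profile", class(df))
  autoplot(df)
}
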