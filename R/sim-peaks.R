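#' Simulate m6A-like peak intervals over a simulated annotation
#'
#' A configurable fraction of the flanking introns of planted differentially
#' spliced SE events receives one peak whose summit falls inside the intron;
#' background peaks are placed uniformly over the remaining intronic space at
#' `config$background_peak_rate` peaks per kilobase. Flanking introns of all
#' planted-DSE SE genes are excluded from the background so the planted set
#' is exactly the peak-bearing set when the background rate is positive.
#'
#' @inheritParams sim_splicing_truth
#' @param truth Output of [sim_splicing_truth()] for the same annotation.
#' @return A peak tibble with columns `contig`, `start`, `end`, `name`,
#'   `score`, `strand`, `summit` (absolute 0-based position), `gene_id`,
#'   `planted`.
#' @export
sim_peaks <- function(annotation, truth, config, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  st <- sim_truth(annotation) |>
    left_join(truth |> select("gene_id", "is_dse"), by = "gene_id")
  seed <- seed %||% child_seed(config$seed, 3)
  w <- config$peak_width

  withr::with_seed(seed, {
    planted <- st |>
      filter(.data$type == "SE", .data$is_dse) |>
      filter(runif(n()) < config$peak_enrichment_fraction)
    planted_rows <- NULL
    if (nrow(planted) > 0) {
      pick_up <- runif(nrow(planted)) < 0.5
      s0 <- ifelse(pick_up, planted$flank_up_start, planted$flank_down_start)
      e0 <- ifelse(pick_up, planted$flank_up_end, planted$flank_down_end)
      summit <- floor(runif(nrow(planted), s0 + 5, e0 - 5))
      planted_rows <- tibble(
        contig = planted$contig,
        start = pmax(summit - floor(w / 2), 0),
        end = summit + ceiling(w / 2),
        strand = planted$strand, summit = summit,
        gene_id = planted$gene_id, planted = TRUE
      )
    }

    # background intronic space, minus flanks of every planted-DSE SE gene
    dse_se <- st |> filter(.data$type == "SE", .data$is_dse)
    excluded <- bind_rows(
      dse_se |> transmute(.data$gene_id, start = .data$flank_up_start, end = .data$flank_up_end),
      dse_se |> transmute(.data$gene_id, start = .data$flank_down_start, end = .data$flank_down_end)
    )
    introns <- gene_introns(annotation) |>
      anti_join(excluded, by = c("gene_id", "start", "end"))
    bg_rows <- NULL
    if (config$background_peak_rate > 0 && nrow(introns) > 0) {
      n_bg <- rpois(nrow(introns), config$background_peak_rate *
                      (introns$end - introns$start) / 1000)
      idx <- rep(seq_len(nrow(introns)), n_bg)
      if (length(idx) > 0) {
        it <- introns[idx, ]
        summit <- floor(runif(nrow(it), it$start + 5, it$end - 5))
        bg_rows <- tibble(
          contig = it$contig,
          start = pmax(summit - floor(w / 2), 0),
          end = summit + ceiling(w / 2),
          strand = it$strand, summit = summit,
          gene_id = it$gene_id, planted = FALSE
        )
      }
    }

    peaks <- bind_rows(planted_rows, bg_rows)
    if (nrow(peaks) == 0) {
      return(tibble(contig = character(), start = numeric(), end = numeric(),
                    name = character(), score = numeric(), strand = character(),
                    summit = numeric(), gene_id = character(), planted = logical()))
    }
    peaks |>
      arrange(.data$contig, .data$start) |>
      mutate(name = sprintf("peak_%04d", row_number()), score = 0) |>
      select("contig", "start", "end", "name", "score", "strand",
             "summit", "gene_id", "planted")
  })
}

#' Simulate a genome with a motif planted at peak summits
#'
#' Builds one random-sequence contig per simulated gene (uniform A/C/G/T) and
#' writes the configured motif at every peak summit. On minus-strand peaks the
#' reverse complement is written ending at the summit so that the extracted,
#' strand-corrected window shows the motif starting exactly at its center.
#'
#' @inheritParams sim_peaks
#' @param peaks A peak tibble from [sim_peaks()] (may be empty).
#' @return A [Biostrings::DNAStringSet] named by contig.
#' @export
sim_genome <- function(annotation, peaks, config, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  st <- sim_truth(annotation)
  seed <- seed %||% child_seed(config$seed, 4)
  motif <- strsplit(config$motif, "")[[1]]
  motif_rc <- rev(chartr("ACGT", "TGCA", motif))
  L <- length(motif)

  withr::with_seed(seed, {
    seqs <- vector("character", nrow(st))
    for (i in seq_len(nrow(st))) {
      len <- st$contig_length[i]
      x <- sample(c("A", "C", "G", "T"), len, replace = TRUE)
      pk <- peaks[peaks$contig == st$contig[i], , drop = FALSE]
      if (nrow(pk) > 0) {
        for (j in seq_len(nrow(pk))) {
          s <- pk$summit[j]
          if (identical(pk$strand[j], "-")) {
            lo <- s - L + 2; hi <- s + 1          # 1-based, motif ends at summit
            if (lo >= 1 && hi <= len) x[lo:hi] <- motif_rc
          } else {
            lo <- s + 1; hi <- s + L              # 1-based, motif starts at summit
            if (lo >= 1 && hi <= len) x[lo:hi] <- motif
          }
        }
      }
      seqs[i] <- paste(x, collapse = "")
    }
    Biostrings::DNAStringSet(setNames(seqs, st$contig))
  })
}

#' Simulate a survival cohort driven by event PSI covariates
#'
#' Per-patient PSI values are uniform on \[0, 1\]; survival times follow an
#' exponential baseline with hazard multiplied by `exp(sum(beta * PSI))`;
#' censoring is independent with the hazard chosen so that the expected
#' censored fraction equals `config$censor_rate`. An independent log-normal
#' `expression` column is included for correlation analyses.
#'
#' @param event_ids Character vector of event identifiers; must match
#'   `config$true_betas` in length.
#' @inheritParams sim_annotation
#' @return A list with `cohort` (tibble: `patient_id`, `time`, `status`,
#'   `expression`, and one PSI column per event id) and `betas` (named truth).
#' @export
sim_cohort <- function(event_ids, config, seed = NULL) {
  stopifnot(inherits(config, "sw_sim_config"))
  k <- length(event_ids)
  if (k != length(config$true_betas)) {
    sw_abort("`event_ids` and `config$true_betas` must have the same length")
  }
  seed <- seed %||% child_seed(config$seed, 5)
  withr::with_seed(seed, {
    n <- config$n_patients
    psi <- matrix(runif(n * k), nrow = n, ncol = k, dimnames = list(NULL, event_ids))
    lp <- drop(psi %*% config$true_betas)
    rate <- config$baseline_hazard * exp(lp)
    t_event <- rexp(n, rate)
    if (config$censor_rate > 0) {
      r <- config$censor_rate
      t_cens <- rexp(n, rate * r / (1 - r))
      time <- pmin(t_event, t_cens)
      status <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      status <- rep(1L, n)
    }
    cohort <- tibble(patient_id = sprintf("p%05d", seq_len(n)),
                     time = time, status = status,
                     expression = rlnorm(n, 2, 0.5)) |>
      bind_cols(as_tibble(psi))
    list(cohort = cohort, betas = setNames(config$true_betas, event_ids))
  })
}
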