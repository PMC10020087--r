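#' Detection filter: features with reads in at least half of the samples
#'
#' Keeps features whose count is nonzero in at least `ceiling(n_samples / 2)`
#' samples; everything else is removed before normalization and testing.
#'
#' @param counts Long count tibble with columns `feature_id`, `sample`,
#'   `condition`, `count`.
#' @return The filtered tibble (a warning is raised when nothing survives).
#' @export
filter_detected <- function(counts) {
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  n_samples <- length(unique(counts$sample))
  keep <- counts |>
    group_by(.data$feature_id) |>
    summarise(n_pos = sum(.data$count > 0), .groups = "drop") |>
    filter(.data$n_pos >= ceiling(n_samples / 2))
  out <- counts |> semi_join(keep, by = "feature_id")
  if (nrow(out) == 0) warn("filter_detected: no feature passes the detection filter")
  out
}

#' Median-of-ratios size factors
#'
#' Each sample's factor is the median ratio of its counts to the row-wise
#' geometric-mean pseudo-reference, computed over features with no zero
#' count in any sample; factors are rescaled to have geometric mean 1.
#'
#' @inheritParams filter_detected
#' @return A tibble `sample`, `size_factor`.
#' @export
size_factors <- function(counts) {
  assert_columns(counts, c("feature_id", "sample", "count"), "counts")
  m <- counts_matrix(counts)
  pos <- rowSums(m == 0) == 0
  if (!any(pos)) sw_abort("size_factors: no feature is nonzero in every sample")
  logref <- rowMeans(log(m[pos, , drop = FALSE]))
  sf <- apply(m[pos, , drop = FALSE], 2, function(k) median(exp(log(k) - logref)))
  sf <- sf / exp(mean(log(sf)))
  tibble(sample = colnames(m), size_factor = unname(sf))
}

counts_matrix <- function(counts) {
  wide <- counts |>
    select("feature_id", "sample", "count") |>
    pivot_wider(names_from = "sample", values_from = "count", values_fill = 0)
  m <- as.matrix(wide[, -1])
  rownames(m) <- wide$feature_id
  m
}

condition_map <- function(counts) {
  counts |> distinct(.data$sample, .data$condition)
}

#' Fit a locally regressed mean-variance function
#'
#' Computes, per feature, the mean of the size-factor-normalized counts and
#' the within-condition pooled sample variance, then fits a local (tricube
#' weighted, locally linear) regression of log variance on log mean. The
#' returned function evaluates the fit, clamps queries to the fitted mean
#' range, and floors the result at the Poisson bound (variance >= mean). If
#' no feature shows positive variance, the fit degenerates to that bound.
#'
#' @inheritParams filter_detected
#' @param sf Size-factor tibble from [size_factors()] (computed when `NULL`).
#' @param span Local-regression bandwidth (fraction of points).
#' @return An object of class `sw_mv_fit`: use it as `fit$fn(mean)` or via
#'   `predict()`.
#' @export
fit_mean_variance <- function(counts, sf = NULL, span = 0.4) {
  assert_columns(counts, c("feature_id", "sample", "condition", "count"), "counts")
  if (is.null(sf)) sf <- size_factors(counts)
  cm <- condition_map(counts)
  reps <- cm |> count(.data$condition)
  if (all(reps$n < 2)) sw_abort("fit_mean_variance: need >= 2 replicates in some condition")

  norm <- counts |>
    left_join(sf, by = "sample") |>
    mutate(ncount = .data$count / .data$size_factor)
  per_feature <- norm |>
    group_by(.data$feature_id) |>
    summarise(mean = mean(.data$ncount), .groups = "drop")
  pooled_var <- norm |>
    group_by(.data$feature_id, .data$condition) |>
    summarise(v = var(.data$ncount), df = n() - 1, .groups = "drop") |>
    filter(.data$df > 0) |>
    group_by(.data$feature_id) |>
    summarise(variance = sum(.data$v * .data$df) / sum(.data$df), .groups = "drop")
  stats_tbl <- per_feature |> left_join(pooled_var, by = "feature_id")

  fit_data <- stats_tbl |> filter(.data$mean > 0, .data$variance > 0)
  if (nrow(fit_data) < 10) {
    fn <- function(m) pmax(m, 0)            # Poisson floor only
    lo <- hi <- NULL
  } else {
    lo <- min(fit_data$mean); hi <- max(fit_data$mean)
    # regressing log sample variances underestimates log true variance
    # (Jensen); correct with the chi-square log-moment E[log s^2] - log
    # sigma^2 = digamma(df/2) - log(df/2) at the typical residual df
    df_typ <- sum(pmax(reps$n - 1, 0))
    bias <- exp(log(df_typ / 2) - digamma(df_typ / 2))
    lfit <- loess(log(variance) ~ log(mean), data = fit_data,
                  span = span, degree = 1, family = "gaussian",
                  control = loess.control(surface = "direct"))
    fn <- function(m) {
      mc <- pmin(pmax(m, lo), hi)
      v <- exp(predict(lfit, newdata = data.frame(mean = mc))) * bias
      pmax(v, m)                             # floor at the Poisson bound
    }
  }
  structure(list(fn = fn, data = stats_tbl, span = span, range = c(lo, hi)),
            class = "sw_mv_fit")
}

#' @export
predict.sw_mv_fit <- function(object, newdata, ...) {
  object$fn(newdata)
}

#' @export
print.sw_mv_fit <- function(x, ...) {
  cat("<sw_mv_fit> locally regressed mean-variance function\n")
  cat(glue("  features: {nrow(x$data)}  span: {x$span}"), "\n")
  invisible(x)
}

#' Exact conditional negative-binomial test for differential expression
#'
#' For each feature the raw count sums in the two conditions are modeled as
#' negative binomials whose means derive from the pooled (size-factor
#' normalized) expression estimate and whose variances come from the fitted
#' mean-variance function. Conditioning on the observed total, the two-sided
#' p-value sums the probabilities of all splits of the total at most as
#' probable as the observed one. All-zero features get p = 1 by convention.
#'
#' @inheritParams fit_mean_variance
#' @param cond_a,cond_b Condition labels; the fold change is B over A.
#' @param fit Optional [fit_mean_variance()] result (computed when `NULL`).
#' @return A tibble `feature_id`, `base_mean`, `log2fc`, `p_value`, `fdr`,
#'   sorted by p-value.
#' @export
nb_test <- function(counts, cond_a, cond_b, fit = NULL, sf = NULL) {
  assert_columns(counts, c("feature_id", "sample", "condition", "count"), "counts")
  counts <- counts |> filter(.data$condition %in% c(cond_a, cond_b))
  if (is.null(sf)) sf <- size_factors(counts)
  if (is.null(fit)) fit <- fit_mean_variance(counts, sf)
  m <- counts_matrix(counts)
  cm <- condition_map(counts)
  sfv <- sf$size_factor[match(colnames(m), sf$sample)]
  in_a <- colnames(m) %in% cm$sample[cm$condition == cond_a]
  in_b <- colnames(m) %in% cm$sample[cm$condition == cond_b]
  sA <- sum(sfv[in_a]); sB <- sum(sfv[in_b])
  sA2 <- sum(sfv[in_a]^2); sB2 <- sum(sfv[in_b]^2)

  kA <- rowSums(m[, in_a, drop = FALSE])
  kB <- rowSums(m[, in_b, drop = FALSE])
  q0 <- rowMeans(sweep(m, 2, sfv, "/"))     # pooled normalized mean
  vq <- fit$fn(q0)                          # fitted variance of normalized counts
  raw_scv <- pmax(vq - q0, 0)               # excess (non-shot) variance

  p <- vapply(seq_along(kA), function(i) {
    nb_exact_p(kA[i], kB[i], q0[i],
               muA = q0[i] * sA, varA = q0[i] * sA + raw_scv[i] * sA2,
               muB = q0[i] * sB, varB = q0[i] * sB + raw_scv[i] * sB2)
  }, numeric(1))

  tibble(feature_id = rownames(m),
         base_mean = q0,
         log2fc = log2((kB / sB + 1e-8) / (kA / sA + 1e-8)),
         p_value = p,
         fdr = adjust_fdr(p)) |>
    arrange(.data$p_value, .data$feature_id)
}

# two-sided conditional p for one feature; probabilities of the per-condition
# sums under moment-matched NB laws (Poisson when at the bound)
nb_exact_p <- function(kA, kB, q0, muA, varA, muB, varB) {
  K <- kA + kB
  if (K == 0 || q0 <= 0) return(1)
  dm <- function(x, mu, v) {
    if (v > mu * (1 + 1e-8)) {
      size <- mu^2 / (v - mu)
      dnbinom(x, mu = mu, size = size)
    } else {
      dpois(x, mu)
    }
  }
  a <- 0:K
  pa <- dm(a, muA, varA)
  pb <- dm(K - a, muB, varB)
  joint <- pa * pb
  denom <- sum(joint)
  if (denom <= 0) return(1)
  obs <- joint[kA + 1]
  min(1, sum(joint[joint <= obs * (1 + 1e-7)]) / denom)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment with enforced monotonicity, as implemented by
#' [stats::p.adjust()] with `method = "BH"`.
#'
#' @param p Numeric vector of p-values.
#' @return Adjusted FDR values, same length and order as `p`.
#' @export
adjust_fdr <- function(p) {
  p.adjust(p, method = "BH")
}
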