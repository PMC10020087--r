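#' Lasso-penalized Cox model on event PSI covariates
#'
#' Fits an L1-penalized Cox proportional-hazards model of overall survival on
#' per-event PSI values (cyclic coordinate descent on the partial likelihood,
#' Breslow handling of ties). When `penalty` is `NULL` it is chosen by seeded
#' cross-validated partial likelihood; `penalty = 0` and single-covariate
#' models reduce to an unpenalized Cox fit. Patients with a missing PSI,
#' time or status are dropped (complete-case) and counted. The fitted model
#' carries the training risk scores' percentile cutoff for later
#' stratification.
#'
#' @param cohort Tibble with columns `time`, `status` (1 = event) and one
#'   PSI column per event (e.g. from [sim_cohort()] or [read_clinical()]).
#' @param events Character vector of PSI column names; defaults to every
#'   column other than `patient_id`, `time`, `status`, `expression`.
#' @param penalty L1 penalty strength (glmnet lambda); `NULL` = seeded CV.
#' @param q Percentile used for the stored high/low cutoff (default 0.75).
#' @param nfolds Cross-validation folds when `penalty` is `NULL`.
#' @param seed Seed for the cross-validation fold assignment.
#' @return An `sw_risk_model`: coefficients, penalty, percentile cutoff and
#'   training metadata. Supports [tidy()], [glance()] and [risk_score()].
#' @export
cox_lasso <- function(cohort, events = NULL, penalty = NULL, q = 0.75,
                      nfolds = 5, seed = 1L) {
  assert_columns(cohort, c("time", "status"), "cohort")
  events <- events %||% setdiff(names(cohort),
                                c("patient_id", "time", "status", "expression"))
  if (length(events) == 0) sw_abort("cox_lasso: no PSI covariates")
  dat <- cohort[, c("time", "status", events)]
  cc <- complete.cases(dat)
  if (sum(!cc) > 0) inform(glue("cox_lasso: dropped {sum(!cc)} patient(s) with missing values"))
  dat <- dat[cc, , drop = FALSE]
  if (nrow(dat) < 2 || sum(dat$status) == 0) {
    sw_abort("cox_lasso: the model is undefined without observed events")
  }
  x <- as.matrix(dat[, events, drop = FALSE])
  y <- survival::Surv(dat$time, dat$status)

  if (length(events) == 1 || (!is.null(penalty) && penalty == 0)) {
    fit <- survival::coxph(y ~ x, ties = "breslow")
    beta <- setNames(as.numeric(fit$coefficients), events)
    penalty_used <- penalty %||% 0
  } else {
    if (is.null(penalty)) {
      foldid <- withr::with_seed(seed, sample(rep(seq_len(nfolds), length.out = nrow(x))))
      cv <- glmnet::cv.glmnet(x, y, family = "cox", foldid = foldid)
      penalty_used <- cv$lambda.min
      fit <- cv$glmnet.fit
    } else {
      penalty_used <- penalty
      fit <- glmnet::glmnet(x, y, family = "cox")
    }
    beta <- setNames(as.numeric(stats::coef(fit, s = penalty_used)), events)
  }

  scores <- drop(x %*% beta)
  labels <- percentile_split(scores, q = q)
  cutoff <- if (any(labels == "high")) min(scores[labels == "high"]) else Inf
  structure(list(events = events, beta = beta, penalty = penalty_used,
                 q = q, cutoff = cutoff, n = nrow(dat),
                 n_events = sum(dat$status), n_dropped = sum(!cc)),
            class = "sw_risk_model")
}

#' @export
print.sw_risk_model <- function(x, ...) {
  cat("<sw_risk_model> penalized Cox PSI signature\n")
  cat(glue("  {length(x$events)} event(s), penalty = {signif(x$penalty, 4)}, ",
           "n = {x$n} ({x$n_events} events observed)"), "\n")
  print(round(x$beta, 4))
  invisible(x)
}

#' @export
tidy.sw_risk_model <- function(x, ...) {
  tibble(term = x$events, estimate = unname(x$beta),
         hazard_ratio = exp(unname(x$beta)))
}

#' @export
glance.sw_risk_model <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, n_dropped = x$n_dropped,
         penalty = x$penalty, n_nonzero = sum(x$beta != 0),
         q = x$q, cutoff = x$cutoff)
}

#' Patient risk scores from a fitted signature
#'
#' The risk score is the linear combination
#' `sum(beta_event * PSI_event)` over the model's events.
#'
#' @param model An `sw_risk_model` from [cox_lasso()], or a named numeric
#'   vector of coefficients.
#' @param psi Either a numeric vector of PSI values (in model event order)
#'   or a data frame containing the model's PSI columns.
#' @return A numeric score (vector input) or the input tibble with a
#'   `risk_score` column appended (data-frame input).
#' @export
risk_score <- function(model, psi) {
  beta <- if (inherits(model, "sw_risk_model")) model$beta else model
  if (is.data.frame(psi)) {
    assert_columns(psi, names(beta), "psi")
    x <- as.matrix(psi[, names(beta), drop = FALSE])
    psi |> mutate(risk_score = drop(x %*% beta))
  } else {
    if (length(psi) != length(beta)) sw_abort("risk_score: length mismatch")
    sum(beta * psi)
  }
}

#' Percentile stratification of risk scores
#'
#' Ranks patients by descending score and labels the top
#' `ceiling((1 - q) * n)` as `"high"`, the rest `"low"`. The split is
#' rank-based rather than an interpolated quantile, so group sizes are
#' convention-free (1207 patients at q = 0.75 give exactly 302 high / 905
#' low); boundary ties are broken by stable input order, with a warning.
#'
#' @param scores Numeric risk scores.
#' @param q Quantile cutoff (default 0.75).
#' @return A character vector (`"high"`/`"low"`) aligned with `scores`.
#' @export
percentile_split <- function(scores, q = 0.75) {
  n <- length(scores)
  if (n == 0) return(character())
  n_high <- ceiling((1 - q) * n)
  ord <- order(-scores, seq_len(n))          # stable: ties keep input order
  labels <- rep("low", n)
  labels[ord[seq_len(n_high)]] <- "high"
  if (n_high > 0 && n_high < n) {
    boundary <- scores[ord[n_high]]
    if (sum(scores == boundary) > 1) {
      warn("percentile_split: ties at the cutoff broken by input order")
    }
  }
  labels
}

#' Kaplan-Meier survival curves per group
#'
#' Product-limit estimates; censored subjects leave the risk set after
#' their recorded time.
#'
#' @param time Positive follow-up times.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param group Group labels (a single group when omitted).
#' @return An `sw_km` tibble: `group`, `time`, `n_risk`, `n_event`,
#'   `survival`.
#' @export
km_estimate <- function(time, status, group = NULL) {
  group <- group %||% rep("all", length(time))
  df <- data.frame(time = time, status = status, group = as.character(group))
  fit <- survival::survfit(survival::Surv(time, status) ~ group, data = df)
  strata <- if (is.null(fit$strata)) {
    rep(unique(df$group), length(fit$time))
  } else {
    rep(sub("^group=", "", names(fit$strata)), fit$strata)
  }
  out <- tibble(group = strata, time = fit$time, n_risk = fit$n.risk,
                n_event = fit$n.event, survival = fit$surv)
  class(out) <- c("sw_km", class(out))
  out
}

#' @export
autoplot.sw_km <- function(object, ...) {
  df <- as_tibble(object) |>
    group_by(.data$group) |>
    group_modify(~ bind_rows(tibble(time = 0, survival = 1), .x[, c("time", "survival")])) |>
    ungroup()
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$survival,
                                   colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "time", y = "overall survival", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Two-group log-rank test
#'
#' Observed versus expected events summed over distinct event times with the
#' hypergeometric variance.
#'
#' @inheritParams km_estimate
#' @return A list: `statistic` (chi-square, 1 df), `p_value`.
#' @export
logrank_test <- function(time, status, group) {
  if (length(unique(group)) != 2) sw_abort("logrank_test: exactly two groups required")
  df <- data.frame(time = time, status = status, group = as.character(group))
  if (sum(df$status) == 0) return(list(statistic = 0, p_value = 1))
  sd <- survival::survdiff(survival::Surv(time, status) ~ group, data = df)
  list(statistic = unname(sd$chisq), p_value = pchisq(sd$chisq, df = 1, lower.tail = FALSE))
}

#' Compare PSI distributions between two sample groups
#'
#' Two-sided rank-sum (Wilcoxon) comparison per event; a t-test is available
#' behind the `method` flag.
#'
#' @param psi_tumor,psi_normal Numeric vectors, or data frames with the same
#'   PSI columns (one test per shared column).
#' @param method `"wilcox"` (default) or `"t"`.
#' @return A tibble `event`, `p_value`.
#' @export
compare_psi_groups <- function(psi_tumor, psi_normal, method = c("wilcox", "t")) {
  method <- match.arg(method)
  one <- function(x, y) {
    x <- x[!is.na(x)]; y <- y[!is.na(y)]
    if (length(x) == 0 || length(y) == 0) return(NA_real_)
    if (method == "wilcox") {
      suppressWarnings(wilcox.test(x, y, alternative = "two.sided")$p.value)
    } else {
      stats::t.test(x, y)$p.value
    }
  }
  if (is.data.frame(psi_tumor)) {
    cols <- intersect(names(psi_tumor), names(psi_normal))
    tibble(event = cols,
           p_value = map_dbl(cols, ~ one(psi_tumor[[.x]], psi_normal[[.x]])))
  } else {
    tibble(event = "psi", p_value = one(psi_tumor, psi_normal))
  }
}

#' Pearson correlation between gene expression and event PSI
#'
#' Pairs with a missing value are dropped; a degenerate input (constant on
#' either side, or fewer than 3 complete pairs) yields an `NA` correlation.
#'
#' @param expression,psi Numeric vectors of equal length.
#' @return A tibble `r`, `p_value`, `n`.
#' @export
correlate_expression_psi <- function(expression, psi) {
  ok <- !is.na(expression) & !is.na(psi)
  x <- expression[ok]; y <- psi[ok]
  if (length(x) < 3 || sd(x) == 0 || sd(y) == 0) {
    return(tibble(r = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}
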