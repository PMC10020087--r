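test_that("risk scores are the stated linear combination", {
  beta <- c(e1 = 0.5, e2 = -1.0)
  expect_equal(risk_score(beta, c(0.6, 0.2)), 0.1)
  expect_equal(risk_score(setNames(rep(0, 3), paste0("e", 1:3)), runif(3)), 0)
  # affine in each coordinate
  grid <- seq(0, 1, by = 0.25)
  vals <- vapply(grid, function(x) risk_score(beta, c(x, 0.3)), numeric(1))
  expect_equal(diff(vals), rep(0.5 * 0.25, 4))
  # data-frame interface appends a column
  df <- tibble(e1 = c(0.2, 0.8), e2 = c(0.5, 0.1))
  expect_equal(risk_score(beta, df)$risk_score, c(0.2 * 0.5 - 0.5, 0.8 * 0.5 - 0.1))
})

test_that("percentile stratification reproduces the rank-based group sizes", {
  lab <- percentile_split(withr::with_seed(1, stats::rnorm(1207)))
  expect_equal(sum(lab == "high"), 302)
  expect_equal(sum(lab == "low"), 905)
  lab4 <- percentile_split(c(0.1, 0.4, 0.2, 0.3))
  expect_equal(sum(lab4 == "high"), 1)
  expect_equal(lab4, c("low", "high", "low", "low"))
  # property: |high| = ceiling(0.25 n) for a sweep of n
  for (n in c(1, 2, 3, 7, 100, 999, 1207, 5000)) {
    l <- percentile_split(withr::with_seed(n, stats::runif(n)))
    expect_equal(sum(l == "high"), ceiling(0.25 * n))
    expect_equal(length(l), n)
  }
  # ties at the boundary: stable input order, with a warning
  expect_warning(lt <- percentile_split(rep(1, 8)), "ties")
  expect_equal(lt, rep(c("high", "low"), c(2, 6)))
})

test_that("Kaplan-Meier matches the product-limit closed form", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(km$n_risk, c(3, 2, 1))
  # all censored: survival stays at 1
  km0 <- km_estimate(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(km0$survival == 1))
  # with zero censoring KM equals the empirical survival function
  tm <- withr::with_seed(2, rexp(500, 0.2))
  km1 <- km_estimate(tm, rep(1, 500))
  emp <- vapply(km1$time, function(t) mean(tm > t), numeric(1))
  expect_equal(km1$survival, emp, tolerance = 1e-12)
  # curves are non-increasing, within [0,1], and patient-order invariant
  expect_true(all(diff(km1$survival) <= 1e-12))
  perm <- withr::with_seed(3, sample(500))
  expect_equal(km_estimate(tm[perm], rep(1, 500))$survival, km1$survival)
})

test_that("the log-rank statistic matches a hand-computed lifetable", {
  tm <- c(1, 2, 3, 4, 5, 6); st <- rep(1, 6); gp <- rep(c("a", "b"), each = 3)
  # independent O/E/V accumulation over distinct event times
  o <- e <- v <- 0
  for (t in sort(unique(tm[st == 1]))) {
    at_risk <- tm >= t
    n <- sum(at_risk); n1 <- sum(at_risk & gp == "a")
    d <- sum(tm == t & st == 1); d1 <- sum(tm == t & st == 1 & gp == "a")
    o <- o + d1
    e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  expected <- (o - e)^2 / v
  lr <- logrank_test(tm, st, gp)
  expect_equal(lr$statistic, expected, tolerance = 1e-12)
  # identical groups: statistic 0, p = 1
  lr0 <- logrank_test(rep(tm, 2), rep(st, 2), rep(c("a", "b"), each = 6))
  expect_equal(lr0$statistic, 0)
  expect_equal(lr0$p_value, 1)
})

test_that("cox_lasso honours its limits and invariances", {
  cfg <- sim_config(n_patients = 300, true_betas = c(1, -1, 0), seed = 9)
  co <- sim_cohort(paste0("e", 1:3), cfg)$cohort
  # huge penalty drives every coefficient to zero
  m_inf <- suppressWarnings(cox_lasso(co, penalty = 50))  # all-tied scores
  expect_equal(unname(m_inf$beta), c(0, 0, 0))
  # permuting patient order leaves the fit unchanged (fixed penalty)
  m_a <- cox_lasso(co, penalty = 0.05)
  m_b <- cox_lasso(co[withr::with_seed(4, sample(nrow(co))), ], penalty = 0.05)
  expect_equal(m_a$beta, m_b$beta, tolerance = 1e-8)
  # an all-censored cohort is undefined
  co0 <- co |> mutate(status = 0L)
  expect_error(cox_lasso(co0, penalty = 0.05), "without observed events")
  # unpenalized single-covariate fit points along the log-rank trend
  co1 <- co[, c("patient_id", "time", "status", "e1")]
  m1 <- cox_lasso(co1)
  grp <- ifelse(co$e1 > stats::median(co$e1), "high", "low")
  expect_gt(m1$beta[["e1"]], 0)              # higher PSI, higher hazard
  expect_lt(stats::median(co$time[grp == "high"]),
            stats::median(co$time[grp == "low"]))
})

test_that("hazard ratios are recovered on the simulated cohort", {
  cfg <- sim_config(n_patients = 2000, true_betas = c(1.5, -1.5, 0),
                    censor_rate = 0.2, seed = 2)
  co <- sim_cohort(paste0("e", 1:3), cfg)$cohort
  m <- cox_lasso(co, penalty = 0)
  expect_true(all(abs(exp(m$beta) - exp(c(1.5, -1.5, 0))) /
                    exp(c(1.5, -1.5, 0)) < 0.15))
})

test_that("group PSI comparisons reduce to the exact rank-sum tail", {
  x <- 101:120; y <- 1:20                      # disjoint supports
  res <- compare_psi_groups(x, y)
  expect_equal(res$p_value, 2 / choose(40, 20), tolerance = 1e-12)
  same <- compare_psi_groups(1:10, 1:10)
  expect_equal(same$p_value, 1)
  # data-frame interface: one test per shared column
  df1 <- tibble(a = as.numeric(x), b = runif(20))
  df2 <- tibble(a = as.numeric(y), b = df1$b)
  res2 <- compare_psi_groups(df1, df2)
  expect_equal(res2$p_value[res2$event == "a"], 2 / choose(40, 20), tolerance = 1e-12)
  expect_equal(res2$p_value[res2$event == "b"], 1)
})

test_that("expression-PSI correlation handles exact and degenerate inputs", {
  e <- withr::with_seed(6, runif(50))
  expect_equal(correlate_expression_psi(e, 0.3 * e + 0.1)$r, 1)
  expect_true(is.na(correlate_expression_psi(e, rep(0.5, 50))$r))
  # independence: small |R| at n = 2000
  big <- withr::with_seed(7, list(e = rnorm(2000), p = runif(2000)))
  expect_lt(abs(correlate_expression_psi(big$e, big$p)$r), 0.07)
})

test_that("model accessors expose coefficients and metadata tidily", {
  cfg <- sim_config(n_patients = 400, true_betas = c(1, -1, 0), seed = 5)
  co <- sim_cohort(paste0("e", 1:3), cfg)$cohort
  m <- cox_lasso(co, penalty = 0.05)
  td <- tidy(m)
  expect_equal(td$term, paste0("e", 1:3))
  expect_equal(td$hazard_ratio, exp(td$estimate))
  gl <- glance(m)
  expect_equal(gl$n, 400)
  expect_equal(gl$q, 0.75)
})
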