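test_that("product-limit estimate matches hand fixtures", {
  # no censoring: empirical survival
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))
  # all censored: flat at 1 (no event times listed)
  km0 <- km_estimate(c(4, 7, 9), c(0, 0, 0))
  expect_length(km0$time, 0)
  expect_equal(as.numeric(survival_at(km0, 5)), 1)
  # censoring inside: S(1) = 2/3, then the last death empties the risk set
  km2 <- km_estimate(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$surv, c(2 / 3, 0))
  expect_error(km_estimate(numeric(), numeric()), "empty")
  expect_error(km_estimate(c(-1, 2), c(1, 1)), "non-negative")
})

test_that("KM equals empirical survival whenever nothing is censored", {
  set.seed(21)
  for (rep in 1:20) {
    tt <- round(rexp(60, 0.1), 1)
    km <- km_estimate(tt, rep(1, 60))
    for (t in c(0, quantile(tt, c(0.2, 0.5, 0.9), names = FALSE))) {
      expect_equal(as.numeric(survival_at(km, t)),
                   empirical_survival(tt, t), tolerance = 1e-12)
    }
  }
})

test_that("deaths-first tie handling keeps same-time censorings at risk", {
  # death and censoring both at t = 2: the censored patient counts in the
  # risk set for that death
  km <- km_estimate(c(2, 2, 5), c(1, 0, 1))
  expect_equal(km$n_risk, c(3L, 1L))
  expect_equal(km$surv, c(2 / 3, 0))
})

test_that("Greenwood variance is non-negative, zero at S = 0, and matches survfit", {
  skip_if_not_installed("survival")
  set.seed(22)
  tt <- round(rexp(80, 0.08), 1)
  ev <- rbinom(80, 1, 0.7)
  km <- km_estimate(tt, ev)
  expect_true(all(km$var >= 0))
  sf <- summary(survival::survfit(survival::Surv(tt, ev) ~ 1),
                times = km$time)
  expect_equal(km$surv, sf$surv, tolerance = 1e-10)
  nonzero <- km$surv > 0
  expect_equal(sqrt(km$var[nonzero]), sf$std.err[nonzero],
               tolerance = 1e-8)
})

test_that("step-function lookup is right-continuous with extrapolation flag", {
  km <- km_estimate(c(1, 2, 3), c(1, 1, 1))
  expect_equal(as.numeric(survival_at(km, 0)), 1)
  expect_equal(as.numeric(survival_at(km, 2.5)), 1 / 3)
  expect_equal(as.numeric(survival_at(km, 2)), 1 / 3)
  v <- survival_at(km, c(2.5, 10))
  expect_equal(attr(v, "extrapolated"), c(FALSE, TRUE))
  expect_equal(as.numeric(v), c(1 / 3, 0))
  expect_error(survival_at(km, -1), "non-negative")
})

test_that("log-rank matches the hand hypergeometric computation", {
  # identical groups: statistic 0, p = 1
  tt <- c(1, 3, 5, 1, 3, 5)
  ev <- c(1, 1, 0, 1, 1, 0)
  g <- rep(c("a", "b"), each = 3)
  lr <- logrank_test(tt, ev, g)
  expect_equal(lr$statistic, 0, tolerance = 1e-12)
  expect_equal(lr$p.value, 1)
  expect_equal(sum(lr$observed - lr$expected), 0, tolerance = 1e-10)

  # six-patient worked example against the explicit O-E / variance sums
  tt2 <- c(2, 4, 6, 3, 5, 7)
  ev2 <- c(1, 1, 1, 1, 0, 1)
  g2 <- rep(c("a", "b"), each = 3)
  lr2 <- logrank_test(tt2, ev2, g2)
  expect_equal(lr2$statistic, logrank_oracle_2group(tt2, ev2, g2),
               tolerance = 1e-10)
  expect_equal(lr2$df, 1L)

  expect_error(logrank_test(tt, ev, rep("a", 6)), "2 non-empty groups")
  expect_error(logrank_test(tt, rep(0, 6), g), "at least one event")
})

test_that("log-rank agrees with survdiff across random multi-group fixtures", {
  skip_if_not_installed("survival")
  set.seed(23)
  for (k in c(2, 3, 5)) {
    tt <- round(rexp(40 * k, 0.05), 1)
    ev <- rbinom(40 * k, 1, 0.6)
    g <- sample(k, 40 * k, replace = TRUE)
    mine <- logrank_test(tt, ev, g)
    ref <- survival::survdiff(survival::Surv(tt, ev) ~ g)
    expect_equal(mine$statistic, ref$chisq, tolerance = 1e-8)
    expect_equal(unname(mine$observed), unname(ref$obs), tolerance = 1e-10)
    expect_equal(unname(mine$expected), unname(ref$exp), tolerance = 1e-8)
  }
})

test_that("log-rank is invariant to group relabeling and monotone time maps", {
  set.seed(24)
  tt <- round(rexp(60, 0.05), 2)
  ev <- rbinom(60, 1, 0.6)
  g <- sample(3, 60, replace = TRUE)
  base <- logrank_test(tt, ev, g)$statistic
  expect_equal(logrank_test(tt, ev, c("x", "y", "z")[g])$statistic, base,
               tolerance = 1e-12)
  expect_equal(logrank_test(sqrt(tt), ev, g)$statistic, base,
               tolerance = 1e-12)
  expect_equal(logrank_test(tt * 12, ev, g)$statistic, base,
               tolerance = 1e-12)
})

test_that("log-rank rejects at the nominal rate under a permutation null", {
  set.seed(25)
  tt <- round(rexp(50, 0.05), 1)
  ev <- rbinom(50, 1, 0.7)
  n_rep <- 1000
  rej <- 0
  for (r in seq_len(n_rep)) {
    g <- sample(rep(1:2, 25))
    if (logrank_test(tt, ev, g)$p.value < 0.05) rej <- rej + 1
  }
  rate <- rej / n_rep
  expect_lt(abs(rate - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
})

test_that("Cox fit maximizes the explicitly-written partial likelihood", {
  # 8-record two-group fixture with distinct event times
  tt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- c(1, 1, 1, 0, 1, 1, 0, 1)
  x <- c(1, 1, 0, 1, 0, 1, 0, 0)
  fit <- cox_fit(tt, ev, cbind(grp = x))
  expect_true(fit$converged)
  beta_grid <- grid_maximize(function(b) cox_loglik_oracle(b, tt, ev, x),
                             -4, 4)
  expect_equal(unname(fit$coef), beta_grid, tolerance = 1e-6)
  # partial likelihood at the fit beats zero and nearby perturbations
  ll_fit <- cox_loglik_oracle(unname(fit$coef), tt, ev, x)
  expect_gte(ll_fit, cox_loglik_oracle(0, tt, ev, x))
  expect_gte(ll_fit, cox_loglik_oracle(unname(fit$coef) + 0.1, tt, ev, x))
  expect_gte(ll_fit, cox_loglik_oracle(unname(fit$coef) - 0.1, tt, ev, x))
  expect_equal(unname(fit$loglik["fit"]), ll_fit, tolerance = 1e-8)
  expect_gte(fit$loglik["fit"], fit$loglik["null"])
  # HR and CI are the exponentiated coefficient scale
  expect_equal(fit$hr, exp(unname(fit$coef)))
  expect_true(fit$ci_lower < fit$hr && fit$hr < fit$ci_upper)
})

test_that("Cox fit matches coxph under both tie conventions", {
  skip_if_not_installed("survival")
  set.seed(26)
  tt <- sample(1:15, 120, replace = TRUE)  # heavy ties
  x <- cbind(a = rnorm(120), b = rbinom(120, 1, 0.4))
  ev <- rbinom(120, 1, plogis(0.5 * x[, 1]))
  for (ties in c("breslow", "efron")) {
    mine <- cox_fit(tt, ev, x, ties = ties)
    ref <- survival::coxph(survival::Surv(tt, ev) ~ x, ties = ties)
    expect_equal(unname(mine$coef), unname(coef(ref)), tolerance = 1e-6)
    expect_equal(unname(mine$se), unname(sqrt(diag(vcov(ref)))),
                 tolerance = 1e-6)
    expect_equal(unname(mine$loglik["fit"]), ref$loglik[2],
                 tolerance = 1e-6)
  }
})

test_that("null covariates give small estimates with CI covering the null", {
  set.seed(27)
  n <- 2000
  tt <- rexp(n, 0.02)
  ev <- as.integer(tt <= 80)
  tt <- pmin(tt, 80)
  x <- rbinom(n, 1, 0.5)  # independent of outcome by construction
  fit <- cox_fit(tt, ev, cbind(noise = x))
  expect_lt(abs(unname(fit$coef)), 3 * unname(fit$se))
  expect_true(fit$ci_lower < 1 && fit$ci_upper > 1)
})

test_that("a true log-hazard of 0.7 is recovered within sampling error", {
  set.seed(28)
  n <- 2000
  x <- rbinom(n, 1, 0.5)
  u <- runif(n)
  t_ev <- 50 * (-log(u) * exp(-0.7 * x))^(1 / 1.2)
  ev <- as.integer(t_ev <= 100)
  tt <- pmin(t_ev, 100)
  fit <- cox_fit(tt, ev, cbind(arm = x))
  expect_lt(abs(unname(fit$coef) - 0.7), 3 * unname(fit$se))
})

test_that("two-group Cox score test tracks the log-rank statistic", {
  set.seed(29)
  for (rep in 1:5) {
    n <- 150
    g <- rbinom(n, 1, 0.5)
    tt <- rexp(n, 0.05 * exp(0.4 * g))
    ev <- rbinom(n, 1, 0.8)
    lr <- logrank_test(tt, ev, g)$statistic
    # score test at beta = 0: U^2 / I, the classic log-rank equivalence
    qq <- nodalstage:::cox_quantities(0, tt, ev,
                                      scale(cbind(g), scale = FALSE),
                                      "breslow")
    score_stat <- drop(qq$score^2 / qq$info)
    expect_equal(score_stat, lr, tolerance = 0.02 * max(lr, 1))
  }
})

test_that("degenerate Cox inputs are refused or flagged, not silently fit", {
  tt <- c(1, 2, 3, 4, 5, 6, 7, 8)
  ev <- rep(1, 8)
  expect_error(cox_fit(tt, ev, cbind(k = rep(1, 8))), "constant")
  x2 <- cbind(a = rnorm(8), b = 0)
  x2[, 2] <- 2 * x2[, 1]
  expect_error(cox_fit(tt, ev, x2), "collinear")
  # perfect separation: covariate sorted exactly with event order
  sep <- c(8, 7, 6, 5, 4, 3, 2, 1)
  fit <- cox_fit(tt, ev, cbind(s = sep))
  expect_false(fit$converged)
  expect_match(fit$diagnostic, "monotone|separation|iterations")
})

test_that("spearman correlation matches the rank-then-correlate oracle", {
  expect_equal(spearman_corr(1:10, (1:10)^3)$rho, 1)
  expect_equal(spearman_corr(1:10, -(1:10)^3)$rho, -1)
  expect_equal(spearman_corr(1:10, (1:10)^3)$p.value, 0)
  # tied example against the average-rank Pearson formula
  x <- c(1, 2, 2, 3, 5)
  y <- c(2, 2, 4, 4, 7)
  sc <- spearman_corr(x, y)
  expect_equal(sc$rho, spearman_oracle(x, y), tolerance = 1e-12)
  ref <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  expect_equal(sc$rho, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(sc$p.value, ref$p.value, tolerance = 1e-10)
  expect_error(spearman_corr(c(1, 1, 1), c(1, 2, 3)), "constant")
  expect_error(spearman_corr(1:2, 1:2), "at least 3")
})
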