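# shared medium cohort for the evaluation battery
eval_fixture <- local({
  co <- simulate_cohort(simulation_config(n_patients = 2500, seed = 51))
  st <- stage_cohort(co)
  list(cohort = co, staging = st, data = merge(co, st, by = "id"))
})

test_that("stratified survival conserves n and tests within strata", {
  res <- stratified_survival(eval_fixture$data, "lodds_class", "pn_class")
  expect_equal(sum(res$table$n), nrow(eval_fixture$data))
  # per-stratum rows add up to the stratum sizes
  per_stratum <- tapply(res$table$n, res$table$stratum, sum)
  expect_equal(unname(per_stratum[levels(eval_fixture$data$lodds_class)]),
               unname(table(eval_fixture$data$lodds_class)[
                 levels(eval_fixture$data$lodds_class)]))
  # cells under min_n carry no survival estimate
  small <- res$table$n < 5
  expect_true(all(is.na(res$table$surv[small])))
  expect_error(stratified_survival(eval_fixture$data, "nope", "pn_class"),
               "not present")
})

test_that("stratifying an axis by itself reports the test as undefined", {
  res <- stratified_survival(eval_fixture$data, "pn_class", "pn_class")
  expect_true(all(res$tests$note == "single class in stratum: test undefined"))
  expect_true(all(is.na(res$tests$p.value)))
})

test_that("when hazard depends only on true burden, observed axes are
           exchangeable within strata at the nominal rate", {
  # within LODDS strata the residual pN signal is weak: the within-stratum
  # log-rank across pN classes should reject far less often than across the
  # pooled cohort
  res <- stratified_survival(eval_fixture$data, "lodds_class", "pn_class")
  pooled <- logrank_test(eval_fixture$data$time, eval_fixture$data$event,
                         eval_fixture$data$pn_class)
  ok <- !is.na(res$tests$statistic)
  expect_true(all(res$tests$statistic[ok] < pooled$statistic))
})

test_that("retrieval-count correlations handle degenerate axes gracefully", {
  # all nodes positive: node ratio constant at 1
  co <- data.frame(id = as.character(1:50), tnod = 5:54, pnod = 5:54,
                   t_stage = "T2", m_stage = "M0",
                   time = seq(5, 103, 2), event = rep(c(0L, 1L), 25))
  st <- stage_cohort(co)
  res <- correlation_with_retrieval(merge(co, st, by = "id"))
  rn_row <- res[res$axis == "rn_score", ]
  expect_true(is.na(rn_row$rho))
  expect_match(rn_row$note, "not computable")
  # pnod proportional to tnod: perfect rank correlation
  pn_row <- res[res$axis == "pnod", ]
  expect_equal(pn_row$rho, 1)
})

test_that("involvement independent of retrieval keeps class correlations weak", {
  res <- correlation_with_retrieval(eval_fixture$data)
  cls <- res[res$axis == "lodds_class", ]
  expect_lt(abs(cls$rho), 0.3)
})

test_that("AUC equals the pair-counting oracle and handles edge cases", {
  set.seed(52)
  for (rep in 1:5) {
    n <- sample(20:50, 1)
    score <- sample(0:10, n, replace = TRUE)  # ties on purpose
    outcome <- rbinom(n, 1, 0.4)
    if (length(unique(outcome)) < 2) next
    d <- data.frame(time = ifelse(outcome == 1, 30, 100), event = outcome,
                    s = score)
    res <- roc_compare(d, horizon = 60, axes = "s")
    expect_equal(res$auc$auc, auc_pair_oracle(score, outcome),
                 tolerance = 1e-12)
  }
  # perfect separation
  d <- data.frame(time = c(rep(10, 5), rep(90, 5)),
                  event = c(rep(1L, 5), rep(0L, 5)),
                  s = c(6:10, 1:5))
  expect_equal(roc_compare(d, axes = "s")$auc$auc, 1)
  # all-one-outcome
  d1 <- data.frame(time = rep(10, 5), event = rep(1L, 5), s = 1:5)
  expect_error(roc_compare(d1, axes = "s"), "constant")
})

test_that("a score independent of outcome sits near AUC 0.5", {
  set.seed(53)
  n <- 5000
  d <- data.frame(time = ifelse(rbinom(n, 1, 0.3) == 1, 30, 100))
  d$event <- as.integer(d$time == 30)
  d$s <- rnorm(n)
  res <- roc_compare(d, axes = "s")
  expect_lt(abs(res$auc$auc - 0.5), 3 * res$auc$se)
})

test_that("censored-before-horizon patients are excluded and counted", {
  d <- data.frame(time = c(30, 30, 40, 70, 80, 90),
                  event = c(1L, 1L, 0L, 0L, 0L, 1L),
                  s = c(5, 4, 3, 2, 1, 6))
  res <- roc_compare(d, horizon = 60, axes = "s")
  expect_equal(res$n_excluded, 1L)  # censored at 40
  expect_equal(res$n_used, 5L)
  # death after the horizon counts as a control
  expect_equal(res$auc$n_cases, 2L)
  expect_equal(res$auc$n_controls, 3L)
})

test_that("correlated AUC contrasts match the paired DeLong reference", {
  skip_if_not_installed("pROC")
  d <- eval_fixture$data
  res <- roc_compare(d, axes = c("pnod", "lodds_score"))
  died <- d$event == 1 & d$time <= 60
  usable <- died | d$time > 60
  out <- as.integer(died[usable])
  r1 <- pROC::roc(out, d$pnod[usable], quiet = TRUE, direction = "<")
  r2 <- pROC::roc(out, d$lodds_score[usable], quiet = TRUE, direction = "<")
  expect_equal(res$auc$auc[res$auc$axis == "pnod"], as.numeric(pROC::auc(r1)),
               tolerance = 1e-10)
  expect_equal(res$auc$se[res$auc$axis == "pnod"],
               sqrt(pROC::var(r1, method = "delong")), tolerance = 1e-8)
  ref <- pROC::roc.test(r1, r2, method = "delong", paired = TRUE)
  expect_equal(res$pairwise$p.value, ref$p.value, tolerance = 1e-8)
})

test_that("composite systems report per-stage survival and global tests", {
  res <- composite_compare(eval_fixture$data)
  expect_named(res, c("TNM", "TRM", "TLM"))
  for (sys in res) {
    expect_equal(sum(sys$stages$n), nrow(eval_fixture$data))
    expect_lt(sys$logrank$p.value, 0.05)
  }
  # hazard increasing in true burden: audits should pass
  expect_true(res$TNM$monotone)
  expect_true(res$TLM$monotone)
  # duplicate systems give identical blocks
  dup <- composite_compare(eval_fixture$data,
                           systems = c(A = "tlm_group", B = "tlm_group"))
  expect_identical(dup$A, dup$B)
})

test_that("stage IA is spread across several LODDS-based stages", {
  res <- subgroup_reclassification(eval_fixture$data, "tnm_group", "IA",
                                   "tlm_group")
  expect_gte(nrow(res$table), 2)
  expect_equal(sum(res$table$n), res$n_subgroup)
  expect_equal(res$table$n_censored, res$table$n - res$table$n_event)
  # reclassifying a system by itself: one cell, test undefined
  self <- subgroup_reclassification(eval_fixture$data, "tnm_group", "IA",
                                    "tnm_group")
  expect_equal(nrow(self$table), 1)
  expect_match(self$note, "undefined")
  expect_error(
    subgroup_reclassification(eval_fixture$data, "tnm_group", "XX",
                              "tlm_group"),
    "empty subgroup")
})

test_that("composite discrimination degrades more for TNM than TLM under
           shallow retrieval", {
  # discrimination measured by the AUC of the ordinal stage codes against
  # death within 60 months: label-robust, unlike the log-rank chi-square,
  # which is dominated by how many patients each class happens to hold
  worse_tnm <- 0
  for (s in 1:5) {
    cfg <- simulation_config(n_patients = 3000, seed = 500 + s)
    pair <- simulate_migration_pair(cfg, 12)
    st_full <- stage_cohort(pair$full)
    st_red <- stage_cohort(pair$reduced)
    auc_drop <- vapply(c("tnm_group", "tlm_group"), function(col) {
      af <- roc_compare(data.frame(time = pair$full$time,
                                   event = pair$full$event,
                                   s = as.integer(st_full[[col]])),
                        axes = "s")$auc$auc
      ar <- roc_compare(data.frame(time = pair$reduced$time,
                                   event = pair$reduced$event,
                                   s = as.integer(st_red[[col]])),
                        axes = "s")$auc$auc
      af - ar
    }, numeric(1))
    if (auc_drop["tnm_group"] > auc_drop["tlm_group"]) {
      worse_tnm <- worse_tnm + 1
    }
  }
  expect_gte(worse_tnm, 4)
})

test_that("the full evaluation report assembles every block", {
  rep <- evaluate_cohort(eval_fixture$cohort, eval_fixture$staging)
  expect_s3_class(rep, "evaluation_report")
  expect_equal(rep$n, nrow(eval_fixture$cohort))
  expect_true(all(c("stratified_pn", "stratified_rn", "correlation", "roc",
                    "composite", "subgroup_ia") %in% names(rep)))
  expect_equal(nrow(rep$roc$auc), 6)
})
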