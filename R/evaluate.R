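#' Cross-stratified 5-year survival table
#'
#' For each stratum of one staging axis, tabulates the product-limit survival
#' at `horizon` months of every class of a second axis (cells below `min_n`
#' patients reported with `NA` survival), together with the within-stratum
#' log-rank test across the examined classes. When the two axes coincide
#' each stratum holds a single class and the within-stratum test is reported
#' as undefined.
#'
#' @param data Data frame holding both axes plus `time` and `event` (e.g.
#'   a cohort merged with its [stage_cohort()] result).
#' @param stratify_by,examine Column names of the stratifying and examined
#'   class axes.
#' @param horizon Survival evaluation time (months).
#' @param min_n Minimum cell size for reporting a survival estimate.
#' @return List with `table` (stratum, class, n, n_event, surv) and `tests`
#'   (stratum, statistic, df, p, note).
#' @export
stratified_survival <- function(data, stratify_by, examine, horizon = 60,
                                min_n = 5) {
  for (ax in c(stratify_by, examine)) {
    if (!ax %in% names(data)) {
      stop("axis '", ax, "' not present in data", call. = FALSE)
    }
  }
  strat <- factor(data[[stratify_by]])
  exam <- factor(data[[examine]])
  keep <- !is.na(strat) & !is.na(exam)
  data <- data[keep, ]; strat <- droplevels(strat[keep])
  exam <- droplevels(exam[keep])

  rows <- list(); tests <- list()
  for (s in levels(strat)) {
    in_s <- strat == s
    cls <- droplevels(exam[in_s])
    for (cl in levels(cls)) {
      sel <- in_s & exam == cl
      n <- sum(sel)
      surv <- if (n >= min_n) {
        as.numeric(survival_at(km_estimate(data$time[sel], data$event[sel]),
                               horizon))
      } else NA_real_
      rows[[length(rows) + 1L]] <- data.frame(
        stratum = s, class = cl, n = n, n_event = sum(data$event[sel]),
        surv = surv)
    }
    test_row <- data.frame(stratum = s, statistic = NA_real_,
                           df = NA_integer_, p.value = NA_real_,
                           note = "")
    if (nlevels(cls) < 2L) {
      test_row$note <- "single class in stratum: test undefined"
    } else if (sum(data$event[in_s]) == 0) {
      test_row$note <- "no events in stratum"
    } else {
      lr <- logrank_test(data$time[in_s], data$event[in_s], cls)
      test_row$statistic <- lr$statistic
      test_row$df <- lr$df
      test_row$p.value <- lr$p.value
    }
    tests[[length(tests) + 1L]] <- test_row
  }
  list(table = do.call(rbind, rows), tests = do.call(rbind, tests),
       stratify_by = stratify_by, examine = examine, horizon = horizon)
}

#' Spearman correlation of each staging axis with the retrieval count
#'
#' Rank correlation of the total retrieved-node count with the positive-node
#' count, the node-ratio and LODDS scores, and the ordinal class codes of the
#' three systems. Axes that are constant (correlation undefined) are reported
#' as not computable rather than erroring.
#'
#' @param data Cohort merged with staging results: needs `tnod`, `pnod`,
#'   `rn_score`, `lodds_score`, `pn_class`, `rn_class`, `lodds_class`.
#' @return Data frame with `axis`, `rho`, `p.value`, `note`.
#' @export
correlation_with_retrieval <- function(data) {
  if (!"tnod" %in% names(data)) stop("tnod column required", call. = FALSE)
  axes <- list(
    pnod = data$pnod,
    rn_score = data$rn_score,
    lodds_score = data$lodds_score,
    pn_class = as.integer(data$pn_class) - 1L,
    rn_class = as.integer(data$rn_class) - 1L,
    lodds_class = as.integer(data$lodds_class) - 1L)
  out <- lapply(names(axes), function(nm) {
    v <- axes[[nm]]
    ok <- !is.na(v) & !is.na(data$tnod)
    if (sum(ok) < 3L || diff(range(v[ok])) == 0 ||
        diff(range(data$tnod[ok])) == 0) {
      return(data.frame(axis = nm, rho = NA_real_, p.value = NA_real_,
                        note = "not computable (constant or too few values)"))
    }
    sc <- spearman_corr(data$tnod[ok], v[ok])
    data.frame(axis = nm, rho = sc$rho, p.value = sc$p.value, note = "")
  })
  do.call(rbind, out)
}

# Rank-statistic AUC with placement values for the DeLong covariance.
# outcome: 1 = case (death within horizon), 0 = control.
auc_with_placements <- function(score, outcome) {
  cases <- score[outcome == 1]
  controls <- score[outcome == 0]
  m <- length(cases); n0 <- length(controls)
  sc <- sort(controls)
  n_le <- findInterval(cases, sc)
  n_lt <- findInterval(cases, sc, left.open = TRUE)
  v10 <- (n_lt + 0.5 * (n_le - n_lt)) / n0
  ss <- sort(cases)
  m_le <- findInterval(controls, ss)
  m_lt <- findInterval(controls, ss, left.open = TRUE)
  v01 <- 1 - (m_lt + 0.5 * (m_le - m_lt)) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n0)
}

#' ROC-AUC comparison of staging axes against death within a horizon
#'
#' Defines the binary outcome as death within `horizon` months; patients
#' censored alive before the horizon carry no outcome and are excluded (the
#' count is reported). The AUC of each axis is the rank statistic (ties get
#' half credit); its variance and the pairwise correlated-AUC contrasts use
#' the paired placement-value covariance method for ROC curves estimated on
#' the same patients (DeLong). Both continuous scores and ordinal class
#' codes are evaluated.
#'
#' @param data Cohort merged with staging results.
#' @param horizon Outcome horizon in months (60 = 5-year mortality).
#' @param axes Named list of columns to evaluate; default: positive-node
#'   count, rN score, LODDS score, and the three class codes.
#' @return List with `auc` (axis, auc, se, 95% CI, cases, controls),
#'   `pairwise` (axis pair, AUC difference, z, p), `n_excluded` and
#'   `n_used`.
#' @export
roc_compare <- function(data, horizon = 60,
                        axes = c("pnod", "rn_score", "lodds_score",
                                 "pn_class", "rn_class", "lodds_class")) {
  died_by <- data$event == 1 & data$time <= horizon
  known_alive <- data$time > horizon
  usable <- died_by | known_alive
  n_excluded <- sum(!usable)
  outcome <- as.integer(died_by[usable])
  if (all(outcome == 1L) || all(outcome == 0L)) {
    stop("outcome is constant at horizon ", horizon,
         ": AUC comparison impossible", call. = FALSE)
  }

  mats <- list(); keep_axes <- character()
  for (ax in axes) {
    v <- data[[ax]][usable]
    if (is.factor(v)) v <- as.integer(v)
    if (anyNA(v)) next  # axis undefined for some patients (e.g. rN, tnod=0)
    mats[[ax]] <- v
    keep_axes <- c(keep_axes, ax)
  }
  pl <- lapply(mats, auc_with_placements, outcome = outcome)
  m <- pl[[1]]$m; n0 <- pl[[1]]$n
  V10 <- vapply(pl, function(p) p$v10, numeric(m))
  V01 <- vapply(pl, function(p) p$v01, numeric(n0))
  S <- stats::cov(V10) / m + stats::cov(V01) / n0
  aucs <- vapply(pl, function(p) p$auc, numeric(1))
  se <- sqrt(pmax(diag(S), 0))
  auc_tab <- data.frame(axis = keep_axes, auc = aucs, se = se,
                        ci_lower = pmax(0, aucs - 1.96 * se),
                        ci_upper = pmin(1, aucs + 1.96 * se),
                        n_cases = m, n_controls = n0, row.names = NULL)
  if (length(keep_axes) < 2L) {
    return(list(auc = auc_tab,
                pairwise = data.frame(axis1 = character(),
                                      axis2 = character(), diff = numeric(),
                                      z = numeric(), p.value = numeric()),
                n_excluded = n_excluded, n_used = sum(usable),
                horizon = horizon))
  }
  pairs <- utils::combn(seq_along(keep_axes), 2)
  pw <- apply(pairs, 2, function(ij) {
    i <- ij[1]; j <- ij[2]
    dv <- S[i, i] + S[j, j] - 2 * S[i, j]
    z <- if (dv > 0) (aucs[i] - aucs[j]) / sqrt(dv) else NA_real_
    data.frame(axis1 = keep_axes[i], axis2 = keep_axes[j],
               diff = aucs[i] - aucs[j], z = z,
               p.value = if (is.na(z)) NA_real_ else 2 * stats::pnorm(-abs(z)))
  })
  list(auc = auc_tab, pairwise = do.call(rbind, pw),
       n_excluded = n_excluded, n_used = sum(usable), horizon = horizon)
}

#' Compare composite staging systems on survival discrimination
#'
#' For each composite system (TNM, TRM, TLM by default): per-stage patient
#' and event counts with the survival rate at `horizon`, the global log-rank
#' test across populated stages, and a monotonicity audit checking that
#' survival does not increase across ordered stages (cells below `min_n`
#' skipped in the audit). A system with fewer than two populated stages is
#' reported, not fatal.
#'
#' @param data Cohort merged with staging results.
#' @param systems Named character vector mapping system name to its column.
#' @param horizon Survival evaluation time (months).
#' @param min_n Minimum stage size entering the monotonicity audit.
#' @return Named list per system: `stages` table, `logrank`, and
#'   `monotone` flag (`NA` when untestable).
#' @export
composite_compare <- function(data,
                              systems = c(TNM = "tnm_group",
                                          TRM = "trm_group",
                                          TLM = "tlm_group"),
                              horizon = 60, min_n = 5) {
  out <- list()
  for (nm in names(systems)) {
    col <- systems[[nm]]
    if (!col %in% names(data)) {
      stop("system column '", col, "' not present", call. = FALSE)
    }
    g <- data[[col]]
    ok <- !is.na(g)
    g <- droplevels(factor(g[ok]))
    sub <- data[ok, ]
    stages <- do.call(rbind, lapply(levels(g), function(s) {
      sel <- g == s
      data.frame(stage = s, n = sum(sel), n_event = sum(sub$event[sel]),
                 surv = as.numeric(survival_at(
                   km_estimate(sub$time[sel], sub$event[sel]), horizon)))
    }))
    res <- list(stages = stages, logrank = NULL, monotone = NA)
    if (nlevels(g) < 2L) {
      res$note <- "fewer than two populated stages"
    } else {
      res$logrank <- logrank_test(sub$time, sub$event, g)
      sv <- stages$surv[stages$n >= min_n]
      if (length(sv) >= 2L) res$monotone <- all(diff(sv) <= 1e-12)
    }
    out[[nm]] <- res
  }
  out
}

#' Reclassification of one composite stage by an alternative system
#'
#' Restricts to patients in a given stage of the base system and
#' cross-tabulates the stages the alternative system assigns them, with
#' per-class survival, censoring counts and the log-rank test across the
#' alternative classes inside the subgroup.
#'
#' @param data Cohort merged with staging results.
#' @param base_system,alt_system Column names of the two composite systems.
#' @param base_stage Stage label defining the subgroup (e.g. `"IA"`).
#' @param horizon Survival evaluation time (months).
#' @return List with `table` (alt stage, n, n_event, n_censored, surv),
#'   `logrank` (or a note when undefined) and the subgroup size.
#' @export
subgroup_reclassification <- function(data, base_system = "tnm_group",
                                      base_stage = "IA",
                                      alt_system = "tlm_group",
                                      horizon = 60) {
  for (col in c(base_system, alt_system)) {
    if (!col %in% names(data)) {
      stop("system column '", col, "' not present", call. = FALSE)
    }
  }
  sel <- !is.na(data[[base_system]]) & data[[base_system]] == base_stage
  if (!any(sel)) {
    stop("empty subgroup: no patients with ", base_system, " = ", base_stage,
         " (cohort n = ", nrow(data), ")", call. = FALSE)
  }
  sub <- data[sel, ]
  alt <- droplevels(factor(sub[[alt_system]]))
  tab <- do.call(rbind, lapply(levels(alt), function(s) {
    g <- alt == s
    data.frame(alt_stage = s, n = sum(g), n_event = sum(sub$event[g]),
               n_censored = sum(g) - sum(sub$event[g]),
               surv = as.numeric(survival_at(
                 km_estimate(sub$time[g], sub$event[g]), horizon)))
  }))
  res <- list(table = tab, n_subgroup = nrow(sub),
              base_system = base_system, base_stage = base_stage,
              alt_system = alt_system)
  if (nlevels(alt) < 2L) {
    res$note <- "single alternative class: test undefined"
  } else if (sum(sub$event) == 0) {
    res$note <- "no events in subgroup"
  } else {
    res$logrank <- logrank_test(sub$time, sub$event, alt)
  }
  res
}

#' Full evaluation report for a staged cohort
#'
#' Bundles the comparative battery: stratified survival of pN and rN classes
#' within LODDS strata, Spearman correlations of every axis with the
#' retrieval count, score- and class-based ROC-AUC comparison, composite
#' TNM/TRM/TLM discrimination, and the reclassification of the earliest
#' composite stage by the LODDS-based system.
#'
#' @param cohort Cohort data frame (with `time`, `event`, `tnod`, `pnod`).
#' @param staging Matching [stage_cohort()] output.
#' @param horizon Survival evaluation time (months).
#' @param min_n Minimum cell size for stratified displays.
#' @return List of class `evaluation_report`.
#' @export
evaluate_cohort <- function(cohort, staging, horizon = 60, min_n = 5) {
  data <- merge(cohort, staging, by = "id", sort = FALSE)
  report <- list(
    stratified_pn = stratified_survival(data, "lodds_class", "pn_class",
                                        horizon = horizon, min_n = min_n),
    stratified_rn = stratified_survival(data, "lodds_class", "rn_class",
                                        horizon = horizon, min_n = min_n),
    correlation = correlation_with_retrieval(data),
    roc = roc_compare(data, horizon = horizon),
    composite = composite_compare(data, horizon = horizon, min_n = min_n),
    subgroup_ia = tryCatch(
      subgroup_reclassification(data, "tnm_group", "IA", "tlm_group",
                                horizon = horizon),
      error = function(e) list(note = conditionMessage(e))),
    horizon = horizon, n = nrow(data))
  class(report) <- "evaluation_report"
  report
}
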