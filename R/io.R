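#' Read and validate a cohort CSV
#'
#' Expects a comma-separated, UTF-8, header-bearing file with at least the
#' columns `id`, `tnod`, `pnod`, `t_stage`, `m_stage`, `time`, `event`;
#' additional columns are kept as covariates (empty fields become `NA`).
#' Rows violating the record invariants (`pnod > tnod`, negative counts or
#' times, non-binary events, duplicated ids, unknown T/M stage) are
#' quarantined with a reason rather than silently dropped.
#'
#' @param path Path to the CSV file.
#' @return Data frame of valid records with attributes `quarantine` (the
#'   rejected rows plus a `reason` column) and `n_input`.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  required <- c("id", "tnod", "pnod", "t_stage", "m_stage", "time", "event")
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    stop("cohort file lacks required column(s): ",
         paste(miss, collapse = ", "),
         " (expected at least: ", paste(required, collapse = ", "), ")",
         call. = FALSE)
  }
  reason <- rep(NA_character_, nrow(raw))
  flag <- function(sel, why) {
    sel <- sel & is.na(reason)
    reason[sel] <<- why
  }
  num_ok <- function(v) !is.na(suppressWarnings(as.numeric(v)))
  raw$tnod <- suppressWarnings(as.numeric(raw$tnod))
  raw$pnod <- suppressWarnings(as.numeric(raw$pnod))
  raw$time <- suppressWarnings(as.numeric(raw$time))
  raw$event <- suppressWarnings(as.numeric(raw$event))
  flag(is.na(raw$tnod) | is.na(raw$pnod), "non-numeric node count")
  flag(raw$tnod < 0 | raw$pnod < 0, "negative node count")
  flag(raw$pnod > raw$tnod, "pnod > tnod")
  flag(is.na(raw$time) | raw$time < 0, "invalid time")
  flag(!raw$event %in% c(0, 1), "event not 0/1")
  flag(!raw$t_stage %in% t_stage_levels(), "unknown t_stage")
  flag(!raw$m_stage %in% c("M0", "M1"), "unknown m_stage")
  flag(duplicated(raw$id), "duplicate id")

  quarantine <- raw[!is.na(reason), , drop = FALSE]
  quarantine$reason <- reason[!is.na(reason)]
  ok <- raw[is.na(reason), , drop = FALSE]
  if (nrow(ok) == 0L) {
    stop("no valid rows in ", path, " (", nrow(raw), " quarantined)",
         call. = FALSE)
  }
  ok$tnod <- as.integer(ok$tnod)
  ok$pnod <- as.integer(ok$pnod)
  ok$event <- as.integer(ok$event)
  rownames(ok) <- NULL
  attr(ok, "quarantine") <- quarantine
  attr(ok, "n_input") <- nrow(raw)
  ok
}

#' Write a cohort CSV
#'
#' Comma-separated, header included, UTF-8, `NA` as empty field — the
#' dialect [read_cohort()] expects.
#'
#' @param cohort Cohort data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE, na = "",
                   fileEncoding = "UTF-8")
  invisible(path)
}

#' Serialize a cutpoint scheme to JSON
#'
#' @param scheme A [cutpoint_scheme()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scheme <- function(scheme, path) {
  stopifnot(inherits(scheme, "cutpoint_scheme"))
  obj <- list(axis = scheme$axis, boundaries = scheme$boundaries,
              labels = scheme$labels, convention = "(lower, upper]",
              zero_singleton = scheme$zero_singleton,
              interval = scheme$interval, provenance = scheme$provenance)
  if (!is.null(scheme$merge_log) && nrow(scheme$merge_log) > 0L) {
    obj$merge_log <- scheme$merge_log
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a cutpoint scheme from JSON
#'
#' @param path Path written by [write_scheme()].
#' @return A [cutpoint_scheme()].
#' @export
read_scheme <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cutpoint_scheme(obj$axis, obj$boundaries, labels = obj$labels,
                  zero_singleton = isTRUE(obj$zero_singleton),
                  interval = if (is.null(obj$interval)) NA_real_ else
                    obj$interval,
                  provenance = obj$provenance,
                  merge_log = obj$merge_log)
}

#' Run the full staging pipeline
#'
#' simulate (or read) a cohort, stage it on all axes, obtain the rN and
#' LODDS cutpoint schemes (fixed conventions or derived from the cohort's
#' own survival), and run the comparative evaluation; all artifacts are
#' written to `out_dir`: `cohort.csv`, `staging.csv`, scheme JSONs, the
#' evaluation report JSON and a run manifest. Deterministic given the
#' simulation seed.
#'
#' @param config A [simulation_config()] (ignored when `cohort_path` given).
#' @param out_dir Output directory, created if absent.
#' @param cohort_path Optional existing cohort CSV to read instead of
#'   simulating.
#' @param derive_schemes If `TRUE`, derive the rN and LODDS schemes from the
#'   cohort by survival-based scanning and merging; otherwise use the fixed
#'   conventional schemes.
#' @param horizon Survival evaluation time (months).
#' @return Invisibly, a list with the cohort, staging, schemes and report.
#' @export
run_pipeline <- function(config = simulation_config(), out_dir,
                         cohort_path = NULL, derive_schemes = FALSE,
                         horizon = 60) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  step <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  cohort <- step("cohort", {
    if (is.null(cohort_path)) {
      co <- simulate_cohort(config)
      write_cohort(co, file.path(out_dir, "cohort.csv"))
      co
    } else {
      read_cohort(cohort_path)
    }
  })
  schemes <- step("schemes", {
    if (derive_schemes) {
      list(rn = derive_scheme(cohort, compute_rn, interval = 0.1,
                              target_classes = 5, zero_singleton = TRUE,
                              axis = "rN", horizon = horizon),
           lodds = derive_scheme(cohort, compute_lodds, interval = 0.5,
                                 target_classes = 5, axis = "LODDS",
                                 horizon = horizon))
    } else {
      list(rn = default_rn_scheme(), lodds = default_lodds_scheme())
    }
  })
  staging <- step("staging", stage_cohort(cohort, schemes$rn, schemes$lodds))
  report <- step("evaluation",
                 evaluate_cohort(cohort, staging, horizon = horizon))

  write_scheme(schemes$rn, file.path(out_dir, "scheme_rn.json"))
  write_scheme(schemes$lodds, file.path(out_dir, "scheme_lodds.json"))
  utils::write.csv(staging, file.path(out_dir, "staging.csv"),
                   row.names = FALSE, na = "")
  jsonlite::write_json(report_to_list(report),
                       file.path(out_dir, "evaluation.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  manifest <- list(
    package = "nodalstage",
    version = as.character(utils::packageVersion("nodalstage")),
    source = if (is.null(cohort_path)) "simulated" else cohort_path,
    config = if (is.null(cohort_path)) unclass(config) else NULL,
    derive_schemes = derive_schemes, horizon = horizon,
    n_patients = nrow(cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(list(cohort = cohort, staging = staging, schemes = schemes,
                 report = report))
}

# flatten the evaluation report into plain lists for JSON output
report_to_list <- function(report) {
  comp <- lapply(report$composite, function(sys) {
    list(stages = sys$stages,
         logrank = if (!is.null(sys$logrank)) {
           list(statistic = sys$logrank$statistic, df = sys$logrank$df,
                p.value = sys$logrank$p.value)
         },
         monotone = sys$monotone)
  })
  sub <- report$subgroup_ia
  list(
    n = report$n, horizon = report$horizon,
    stratified_pn = report$stratified_pn[c("table", "tests")],
    stratified_rn = report$stratified_rn[c("table", "tests")],
    correlation = report$correlation,
    roc = report$roc[c("auc", "pairwise", "n_excluded", "n_used")],
    composite = comp,
    subgroup_ia = if (!is.null(sub$table)) {
      list(table = sub$table, n_subgroup = sub$n_subgroup,
           logrank = if (!is.null(sub$logrank)) {
             list(statistic = sub$logrank$statistic, df = sub$logrank$df,
                  p.value = sub$logrank$p.value)
           } else sub$note)
    } else sub)
}
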