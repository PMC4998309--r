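#' Lymph node ratio (rN score)
#'
#' Ratio of positive to total retrieved lymph nodes. Undefined when no nodes
#' were retrieved; such records must be excluded from ratio-based staging
#' before calling (see [stage_cohort()]).
#'
#' @param pnod Integer vector, number of metastatic (positive) nodes.
#' @param tnod Integer vector, total number of retrieved nodes (must be >= 1).
#' @return Numeric vector in `[0, 1]`.
#' @examples
#' compute_rn(3, 3)   # 1: all retrieved nodes positive
#' compute_rn(7, 28)  # 0.25
#' @export
compute_rn <- function(pnod, tnod) {
  check_node_counts(pnod, tnod)
  if (any(tnod < 1L)) {
    stop("rN is undefined when tnod = 0 (no retrieved nodes)", call. = FALSE)
  }
  pnod / tnod
}

#' Log odds of positive lymph nodes (LODDS score)
#'
#' `log((pnod + 0.5) / (tnod - pnod + 0.5))`: the log of the ratio of positive
#' to negative node counts, with 0.5 added to numerator and denominator to
#' avoid singularity at zero or full involvement. Unlike the node ratio, LODDS
#' is defined even when `tnod = 0` (it equals 0 there) and separates patients
#' with identical ratios but different retrieval counts.
#'
#' @inheritParams compute_rn
#' @param base Base of the logarithm; natural log by default. With base 10 the
#'   conventional class boundary at -4 would be unreachable for realistic
#'   retrieval counts, so natural log is the operative choice.
#' @return Numeric vector.
#' @examples
#' compute_lodds(0, 0)   # 0
#' compute_lodds(3, 3)   # log(7)
#' compute_lodds(0, 60)  # log(0.5 / 60.5), deep negative
#' @export
compute_lodds <- function(pnod, tnod, base = exp(1)) {
  check_node_counts(pnod, tnod)
  log((pnod + 0.5) / (tnod - pnod + 0.5), base = base)
}

check_node_counts <- function(pnod, tnod) {
  if (length(pnod) != length(tnod)) {
    n <- max(length(pnod), length(tnod))
    if (length(pnod) == 1L) pnod <- rep(pnod, n)
    if (length(tnod) == 1L) tnod <- rep(tnod, n)
    if (length(pnod) != length(tnod)) {
      stop("pnod and tnod must have equal length", call. = FALSE)
    }
  }
  if (any(!is.finite(pnod)) || any(!is.finite(tnod))) {
    stop("node counts must be finite", call. = FALSE)
  }
  if (any(pnod < 0) || any(tnod < 0)) {
    stop("node counts must be non-negative", call. = FALSE)
  }
  if (any(pnod > tnod)) {
    stop("pnod may not exceed tnod", call. = FALSE)
  }
  invisible(TRUE)
}

#' pN levels and composite stage labels
#' @keywords internal
pn_levels <- function() c("pN0", "pN1", "pN2", "pN3a", "pN3b")

#' @keywords internal
stage_group_levels <- function() {
  c("IA", "IB", "IIA", "IIB", "IIIA", "IIIB", "IIIC", "IV")
}

#' @keywords internal
t_stage_levels <- function() c("T1", "T2", "T3", "T4a", "T4b")

#' Number-based pathologic nodal stage (pN)
#'
#' AJCC 7th-edition nodal classification by the absolute number of metastatic
#' nodes: pN0 = 0, pN1 = 1-2, pN2 = 3-6, pN3a = 7-14, pN3b = 15 or more.
#' (The commonly printed "pN3a 7-14 / pN3b > 15" wording leaves 15 unassigned;
#' for totality a count of 15 classifies as pN3b.)
#'
#' @param pnod Non-negative integer vector of positive-node counts.
#' @return Ordered factor with levels pN0 < pN1 < pN2 < pN3a < pN3b.
#' @export
classify_pn <- function(pnod) {
  if (any(!is.finite(pnod)) || any(pnod < 0)) {
    stop("pnod must be a non-negative count", call. = FALSE)
  }
  idx <- findInterval(pnod, c(0, 1, 3, 7, 15))
  factor(pn_levels()[idx], levels = pn_levels(), ordered = TRUE)
}

#' Cutpoint scheme for a continuous nodal score
#'
#' An ordered set of interior boundaries defining `(lower, upper]` score
#' categories: class k covers `boundaries[k-1] < score <= boundaries[k]`, the
#' lowest class is closed below at -Inf and the top class open above. For
#' ratio-type axes an exact-zero singleton class (node-negative patients) can
#' sit below the scanned intervals.
#'
#' @param axis Axis name, e.g. `"rN"` or `"LODDS"`.
#' @param boundaries Strictly increasing numeric vector of interior cutpoints.
#' @param labels Optional class labels; defaults derived from `axis`.
#' @param zero_singleton If `TRUE`, scores exactly 0 form their own lowest
#'   class outside the interval classes.
#' @param interval Scan interval that produced the boundaries (`NA` for fixed
#'   schemes).
#' @param provenance `"fixed"` (taken from an established classification) or
#'   `"data-derived"`.
#' @param merge_log Data frame recording the bin merges that produced a
#'   derived scheme (see [merge_similar()]).
#' @return Object of class `cutpoint_scheme`.
#' @export
cutpoint_scheme <- function(axis, boundaries, labels = NULL,
                            zero_singleton = FALSE, interval = NA_real_,
                            provenance = c("fixed", "data-derived"),
                            merge_log = NULL) {
  provenance <- match.arg(provenance)
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 1L || any(!is.finite(boundaries))) {
    stop("boundaries must be a non-empty finite numeric vector", call. = FALSE)
  }
  if (any(diff(boundaries) <= 0)) {
    stop("boundaries must be strictly increasing", call. = FALSE)
  }
  n_class <- length(boundaries) + 1L + as.integer(zero_singleton)
  if (is.null(labels)) {
    labels <- if (isTRUE(zero_singleton)) {
      paste0(axis, seq_len(n_class) - 1L)
    } else {
      paste0(axis, seq_len(n_class))
    }
  }
  if (length(labels) != n_class) {
    stop("need ", n_class, " labels, got ", length(labels), call. = FALSE)
  }
  structure(
    list(axis = axis, boundaries = boundaries, labels = labels,
         zero_singleton = isTRUE(zero_singleton), interval = interval,
         provenance = provenance, merge_log = merge_log),
    class = "cutpoint_scheme")
}

#' @export
print.cutpoint_scheme <- function(x, ...) {
  cat("Cutpoint scheme [", x$axis, "], ", x$provenance, "\n", sep = "")
  lo <- c(if (x$zero_singleton) "{0}", "-Inf", format(x$boundaries))
  if (x$zero_singleton) {
    cat("  ", x$labels[1], ": {0}\n", sep = "")
    labs <- x$labels[-1]
  } else {
    labs <- x$labels
  }
  edges <- c(-Inf, x$boundaries, Inf)
  for (k in seq_along(labs)) {
    cat("  ", labs[k], ": (", format(edges[k]), ", ", format(edges[k + 1]),
        "]\n", sep = "")
  }
  if (!is.null(x$merge_log) && nrow(x$merge_log) > 0L) {
    cat("  derived via", nrow(x$merge_log), "bin merges\n")
  }
  invisible(x)
}

#' Conventional rN classification scheme
#'
#' rN0 = exact 0; rN1 in (0, 0.1]; rN2 in (0.1, 0.2]; rN3 in (0.2, 0.3];
#' rN4 > 0.3.
#' @return A [cutpoint_scheme()].
#' @export
default_rn_scheme <- function() {
  cutpoint_scheme("rN", c(0.1, 0.2, 0.3), zero_singleton = TRUE,
                  interval = 0.1, provenance = "fixed")
}

#' Conventional LODDS classification scheme
#'
#' LODDS1 <= -4; LODDS2 in (-4, -2.5]; LODDS3 in (-2.5, -2];
#' LODDS4 in (-2, -0.5]; LODDS5 > -0.5.
#' @return A [cutpoint_scheme()].
#' @export
default_lodds_scheme <- function() {
  cutpoint_scheme("LODDS", c(-4, -2.5, -2, -0.5), interval = 0.5,
                  provenance = "fixed")
}

#' Classify scores with a cutpoint scheme
#'
#' Applies the `(lower, upper]` convention: a score exactly on a boundary
#' belongs to the lower class. With a zero-singleton scheme, scores exactly 0
#' map to the singleton class.
#'
#' @param score Finite numeric vector.
#' @param scheme A [cutpoint_scheme()].
#' @return Ordered factor over the scheme's labels.
#' @export
classify_by_cutpoints <- function(score, scheme) {
  stopifnot(inherits(scheme, "cutpoint_scheme"))
  if (any(!is.finite(score))) {
    stop("scores must be finite", call. = FALSE)
  }
  idx <- findInterval(score, scheme$boundaries, left.open = TRUE) + 1L
  if (scheme$zero_singleton) {
    idx <- idx + 1L
    idx[score == 0] <- 1L
  }
  factor(scheme$labels[idx], levels = scheme$labels, ordered = TRUE)
}

#' AJCC 7th-edition gastric stage grouping table
#'
#' Maps (T stage, N level, M stage) to the composite stage group. The N axis
#' takes the four levels N0-N3; five-level nodal classifications collapse
#' pN3a/pN3b (or the corresponding rN/LODDS classes) onto N3 before lookup.
#' Any M1 combination is stage IV.
#'
#' @return Data frame with columns `t_stage`, `n_level`, `m_stage`, `group`,
#'   one row per combination.
#' @export
ajcc7_stage_table <- function() {
  m0 <- matrix(
    c("IA",   "IB",   "IIA",  "IIB",
      "IB",   "IIA",  "IIB",  "IIIA",
      "IIA",  "IIB",  "IIIA", "IIIB",
      "IIB",  "IIIA", "IIIB", "IIIC",
      "IIIB", "IIIB", "IIIC", "IIIC"),
    nrow = 5, byrow = TRUE,
    dimnames = list(t_stage_levels(), c("N0", "N1", "N2", "N3")))
  tab <- expand.grid(t_stage = t_stage_levels(),
                     n_level = c("N0", "N1", "N2", "N3"),
                     m_stage = c("M0", "M1"),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$group <- ifelse(tab$m_stage == "M1", "IV",
                      m0[cbind(tab$t_stage, tab$n_level)])
  tab
}

#' Composite stage group from T, nodal class and M
#'
#' Collapses a five-level nodal axis (pN, rN class or LODDS class; levels in
#' ascending order) onto N0-N3 (the two highest levels both map to N3), then
#' looks up the stage grouping table. M1 overrides to stage IV.
#'
#' @param t_stage Character or factor in T1, T2, T3, T4a, T4b.
#' @param n_class Five-level nodal class (factor or integer codes 1-5).
#' @param m_stage Character or factor, "M0" or "M1".
#' @param table Grouping table; defaults to [ajcc7_stage_table()].
#' @return Ordered factor over IA < IB < ... < IIIC < IV.
#' @export
assign_composite_stage <- function(t_stage, n_class, m_stage,
                                   table = ajcc7_stage_table()) {
  t_stage <- as.character(t_stage)
  m_stage <- as.character(m_stage)
  if (!all(t_stage %in% t_stage_levels())) {
    stop("unknown T stage: ", paste(unique(setdiff(t_stage, t_stage_levels())),
                                    collapse = ", "), call. = FALSE)
  }
  if (!all(m_stage %in% c("M0", "M1"))) {
    stop("unknown M stage: ", paste(unique(setdiff(m_stage, c("M0", "M1"))),
                                    collapse = ", "), call. = FALSE)
  }
  code <- if (is.factor(n_class)) as.integer(n_class) else as.integer(n_class)
  if (any(is.na(code)) || any(code < 1L) || any(code > 5L)) {
    stop("nodal class must be a five-level factor or codes 1..5",
         call. = FALSE)
  }
  n_level <- c("N0", "N1", "N2", "N3", "N3")[code]
  key <- paste(t_stage, n_level, m_stage)
  lut <- stats::setNames(table$group,
                         paste(table$t_stage, table$n_level, table$m_stage))
  group <- unname(lut[key])
  if (any(is.na(group))) {
    stop("grouping table does not cover: ",
         paste(unique(key[is.na(group)]), collapse = "; "), call. = FALSE)
  }
  factor(group, levels = stage_group_levels(), ordered = TRUE)
}

#' Stage a whole cohort on all three nodal axes
#'
#' Computes rN and LODDS scores, assigns pN / rN-class / LODDS-class, and
#' builds the three composite stage groups (TNM from pN, TRM from the rN
#' class, TLM from the LODDS class). Records with `tnod = 0` have no defined
#' node ratio: their `rn_score`, `rn_class` and `trm_group` are `NA` and their
#' ids are reported in the `"excluded_rn"` attribute; LODDS staging still
#' applies.
#'
#' @param cohort Data frame with columns `id`, `tnod`, `pnod`, `t_stage`,
#'   `m_stage` (e.g. from [simulate_cohort()] or [read_cohort()]).
#' @param rn_scheme,lodds_scheme Cutpoint schemes for the two score axes.
#' @param table Composite grouping table.
#' @return Data frame of per-patient staging results, one row per input
#'   record, with attribute `excluded_rn` listing ids lacking a node ratio.
#' @export
stage_cohort <- function(cohort,
                         rn_scheme = default_rn_scheme(),
                         lodds_scheme = default_lodds_scheme(),
                         table = ajcc7_stage_table()) {
  need <- c("id", "tnod", "pnod", "t_stage", "m_stage")
  miss <- setdiff(need, names(cohort))
  if (length(miss)) {
    stop("cohort lacks required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n <- nrow(cohort)
  if (n == 0L) {
    out <- data.frame(id = character(), rn_score = numeric(),
                      lodds_score = numeric())
    attr(out, "excluded_rn") <- character()
    return(out)
  }
  check_node_counts(cohort$pnod, cohort$tnod)
  has_rn <- cohort$tnod >= 1L

  rn_score <- rep(NA_real_, n)
  rn_score[has_rn] <- compute_rn(cohort$pnod[has_rn], cohort$tnod[has_rn])
  lodds_score <- compute_lodds(cohort$pnod, cohort$tnod)

  pn_class <- classify_pn(cohort$pnod)
  rn_class <- factor(rep(NA_character_, n), levels = rn_scheme$labels,
                     ordered = TRUE)
  rn_class[has_rn] <- classify_by_cutpoints(rn_score[has_rn], rn_scheme)
  lodds_class <- classify_by_cutpoints(lodds_score, lodds_scheme)

  tnm <- assign_composite_stage(cohort$t_stage, pn_class, cohort$m_stage,
                                table)
  trm <- factor(rep(NA_character_, n), levels = stage_group_levels(),
                ordered = TRUE)
  if (any(has_rn)) {
    trm[has_rn] <- assign_composite_stage(
      cohort$t_stage[has_rn], rn_class[has_rn], cohort$m_stage[has_rn], table)
  }
  tlm <- assign_composite_stage(cohort$t_stage, lodds_class, cohort$m_stage,
                                table)

  out <- data.frame(id = as.character(cohort$id),
                    rn_score = rn_score, lodds_score = lodds_score,
                    pn_class = pn_class, rn_class = rn_class,
                    lodds_class = lodds_class,
                    tnm_group = tnm, trm_group = trm, tlm_group = tlm,
                    stringsAsFactors = FALSE)
  attr(out, "excluded_rn") <- as.character(cohort$id[!has_rn])
  out
}
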