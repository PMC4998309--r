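#' Bin a nodal score and tabulate per-bin 5-year survival
#'
#' Cuts the score into `(lower, upper]` bins of width `interval` aligned to
#' `origin`, optionally keeping exact-zero scores in their own singleton bin,
#' and computes per-bin patient counts, event counts and the product-limit
#' survival at `horizon` months. Empty bins are dropped (recorded in the
#' `dropped_bins` attribute of the table).
#'
#' @param scores Finite numeric scores (e.g. node ratio or LODDS).
#' @param times,events Follow-up times and event indicators.
#' @param interval Positive scan interval (bin width).
#' @param origin Bin alignment origin (a boundary of the grid).
#' @param horizon Survival evaluation time in months (60 = 5-year rate).
#' @param zero_singleton Keep exact zeros as their own bin below the grid.
#' @param axis Axis name carried into derived schemes.
#' @return Object of class `bin_scan`: `table` (one row per non-empty bin:
#'   `lower`, `upper`, `n`, `n_event`, `surv`), the per-patient bin
#'   assignment, and the inputs needed for merging.
#' @export
scan_bins <- function(scores, times, events, interval, origin = 0,
                      horizon = 60, zero_singleton = FALSE, axis = "score") {
  if (!is.numeric(interval) || length(interval) != 1L || interval <= 0) {
    stop("interval must be a single positive number", call. = FALSE)
  }
  if (any(!is.finite(scores))) stop("scores must be finite", call. = FALSE)
  check_surv_input(times, events)
  if (length(scores) != length(times)) {
    stop("scores must match times in length", call. = FALSE)
  }

  is_zero <- zero_singleton & scores == 0
  # (lower, upper]: score on a grid point belongs to the lower bin
  k <- ceiling((scores - origin) / interval - 1e-9)
  k[is_zero] <- NA_integer_
  ks <- sort(unique(k[!is_zero]))
  lower <- origin + (ks - 1) * interval
  upper <- origin + ks * interval
  if (zero_singleton && any(is_zero)) {
    lower <- c(-Inf, lower)
    upper <- c(0, upper)
    bin_id <- ifelse(is_zero, 1L, match(k, ks) + 1L)
    singleton_bin <- 1L
  } else {
    bin_id <- match(k, ks)
    singleton_bin <- NA_integer_
  }
  nb <- length(lower)
  tab <- data.frame(bin = seq_len(nb), lower = lower, upper = upper,
                    n = tabulate(bin_id, nb), n_event = NA_integer_,
                    surv = NA_real_)
  for (b in seq_len(nb)) {
    sel <- bin_id == b
    tab$n_event[b] <- sum(events[sel])
    tab$surv[b] <- as.numeric(survival_at(km_estimate(times[sel],
                                                      events[sel]), horizon))
  }
  if (nb == 1L) {
    warning("all scores fall in a single bin", call. = FALSE)
  }
  scan <- list(table = tab, bin_id = bin_id, times = times, events = events,
               interval = interval, origin = origin, horizon = horizon,
               zero_singleton = zero_singleton && any(is_zero), axis = axis,
               singleton_bin = singleton_bin)
  class(scan) <- "bin_scan"
  scan
}

# two-group log-rank p between the patients of two merged groups;
# p = 1 when the pair carries no events (maximally similar)
pairwise_logrank_p <- function(scan, members_a, members_b) {
  sel_a <- scan$bin_id %in% members_a
  sel_b <- scan$bin_id %in% members_b
  sel <- sel_a | sel_b
  if (sum(scan$events[sel]) == 0) return(1)
  g <- ifelse(sel_a[sel], "a", "b")
  logrank_test(scan$times[sel], scan$events[sel], g)$p.value
}

group_surv <- function(scan, members) {
  sel <- scan$bin_id %in% members
  as.numeric(survival_at(km_estimate(scan$times[sel], scan$events[sel]),
                         scan$horizon))
}

#' Merge adjacent score bins with similar survival into a cutpoint scheme
#'
#' Starting from a [scan_bins()] result, iteratively merges the adjacent
#' pair of groups whose prognoses are most alike — by default the pair with
#' the largest pairwise log-rank p-value (ties broken by smaller combined n),
#' alternatively the smallest absolute difference in survival at the horizon —
#' until exactly `target_classes` remain. Groups smaller than `min_bin`
#' patients are first absorbed into the adjacent neighbour with the closer
#' survival. An exact-zero singleton bin is fixed outside the merging and
#' counts toward `target_classes`.
#'
#' @param scan A [scan_bins()] result.
#' @param target_classes Total number of classes in the final scheme
#'   (including the zero singleton if present).
#' @param criterion `"logrank"` or `"surv_diff"`.
#' @param min_bin Minimum group size before the criterion loop.
#' @return A [cutpoint_scheme()] with provenance `"data-derived"` and a
#'   `merge_log` recording every merge and its criterion value.
#' @export
merge_similar <- function(scan, target_classes,
                          criterion = c("logrank", "surv_diff"),
                          min_bin = 10) {
  stopifnot(inherits(scan, "bin_scan"))
  criterion <- match.arg(criterion)
  has_zero <- isTRUE(scan$zero_singleton)
  scan_rows <- scan$table$bin[if (has_zero) -scan$singleton_bin else TRUE]
  target_scan <- target_classes - as.integer(has_zero)
  if (target_classes < 2L) {
    stop("target_classes must be at least 2", call. = FALSE)
  }
  if (target_scan > length(scan_rows) || target_scan < 1L) {
    stop("cannot form ", target_classes, " classes from ",
         length(scan_rows) + as.integer(has_zero), " non-empty bins",
         call. = FALSE)
  }

  # groups: list of member bin ids, in score order
  groups <- as.list(scan_rows)
  log_rows <- list()
  note_merge <- function(i, value, label) {
    log_rows[[length(log_rows) + 1L]] <<- data.frame(
      left = paste(format_members(groups[[i]]), collapse = ""),
      right = paste(format_members(groups[[i + 1L]]), collapse = ""),
      criterion = label, value = value)
    groups[[i]] <<- c(groups[[i]], groups[[i + 1L]])
    groups[[i + 1L]] <<- NULL
  }
  format_members <- function(members) {
    rows <- scan$table[scan$table$bin %in% members, ]
    sprintf("(%s,%s]", format(min(rows$lower)), format(max(rows$upper)))
  }

  # pre-merge undersized groups into the neighbour with closer survival
  repeat {
    if (length(groups) <= target_scan) break
    sizes <- vapply(groups, function(m) sum(scan$table$n[scan$table$bin %in% m]),
                    numeric(1))
    small <- which(sizes < min_bin)
    if (!length(small)) break
    i <- small[1]
    if (i == 1L) {
      j <- 1L
    } else if (i == length(groups)) {
      j <- i - 1L
    } else {
      s_i <- group_surv(scan, groups[[i]])
      s_lo <- group_surv(scan, groups[[i - 1L]])
      s_hi <- group_surv(scan, groups[[i + 1L]])
      j <- if (abs(s_i - s_lo) <= abs(s_i - s_hi)) i - 1L else i
    }
    note_merge(j, NA_real_, "min_bin")
  }

  while (length(groups) > target_scan) {
    ng <- length(groups)
    crit <- numeric(ng - 1L)
    size <- numeric(ng - 1L)
    for (i in seq_len(ng - 1L)) {
      size[i] <- sum(scan$table$n[scan$table$bin %in%
                                    c(groups[[i]], groups[[i + 1L]])])
      crit[i] <- if (criterion == "logrank") {
        pairwise_logrank_p(scan, groups[[i]], groups[[i + 1L]])
      } else {
        -abs(group_surv(scan, groups[[i]]) - group_surv(scan, groups[[i + 1L]]))
      }
    }
    best <- which(crit == max(crit))
    if (length(best) > 1L) best <- best[which.min(size[best])]
    note_merge(best[1], if (criterion == "logrank") crit[best[1]]
               else -crit[best[1]], criterion)
  }

  merge_log <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(left = character(), right = character(),
               criterion = character(), value = numeric())
  boundaries <- vapply(groups[-length(groups)], function(m) {
    max(scan$table$upper[scan$table$bin %in% m])
  }, numeric(1))
  if (!length(boundaries)) {
    stop("derived scheme needs at least one boundary (target_classes >= ",
         2L + as.integer(has_zero), " scanned classes)", call. = FALSE)
  }
  cutpoint_scheme(scan$axis, boundaries, zero_singleton = has_zero,
                  interval = scan$interval, provenance = "data-derived",
                  merge_log = merge_log)
}

#' Derive a cutpoint scheme from survival data
#'
#' Composition of [scan_bins()] and [merge_similar()]: scan the score at a
#' fixed interval, tabulate survival per bin, and merge adjacent bins with
#' similar prognosis down to the requested number of classes. Deterministic
#' given the data.
#'
#' @param records Data frame with `pnod`, `tnod`, `time`, `event`.
#' @param score_fn Function of `(pnod, tnod)` returning the score, e.g.
#'   [compute_rn] or [compute_lodds].
#' @param interval Scan interval.
#' @param target_classes Final number of classes (including the zero
#'   singleton when `zero_singleton = TRUE`).
#' @param origin Grid origin.
#' @param zero_singleton Keep exact-zero scores as a fixed lowest class
#'   (the convention for ratio-type axes).
#' @param axis Axis name for the scheme.
#' @param criterion,min_bin Passed to [merge_similar()].
#' @param horizon Survival evaluation time (months).
#' @return A [cutpoint_scheme()].
#' @export
derive_scheme <- function(records, score_fn, interval, target_classes,
                          origin = 0, zero_singleton = FALSE, axis = "score",
                          criterion = c("logrank", "surv_diff"),
                          min_bin = 10, horizon = 60) {
  scores <- score_fn(records$pnod, records$tnod)
  scan <- scan_bins(scores, records$time, records$event, interval,
                    origin = origin, horizon = horizon,
                    zero_singleton = zero_singleton, axis = axis)
  merge_similar(scan, target_classes, criterion = criterion,
                min_bin = min_bin)
}
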