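#' Product-limit (Kaplan-Meier) survival estimate
#'
#' Nonparametric estimate of the survival function under right censoring.
#' Ties between deaths and censorings at the same time are resolved
#' deaths-first: a patient censored at t is still at risk for deaths at t.
#'
#' @param times Non-negative follow-up times (months).
#' @param events Binary event indicators (1 = death observed).
#' @return Object of class `km_curve`: a list with `time` (distinct event
#'   times, ascending), `n_risk`, `n_event`, `surv` (survival just after each
#'   event time), `var` (Greenwood variance), `n` and `max_time`.
#' @export
km_estimate <- function(times, events) {
  check_surv_input(times, events)
  dt <- sort(unique(times[events == 1]))
  if (length(dt) == 0L) {
    curve <- list(time = numeric(), n_risk = integer(), n_event = integer(),
                  surv = numeric(), var = numeric(),
                  n = length(times), max_time = max(times))
    class(curve) <- "km_curve"
    return(curve)
  }
  st <- sort(times)
  # suffix counts: n at risk = #{times >= t}; events tallied per distinct time
  n_risk <- length(times) - findInterval(dt, st, left.open = TRUE)
  n_event <- tabulate(match(times[events == 1], dt), nbins = length(dt))
  surv <- cumprod(1 - n_event / n_risk)
  gw_term <- ifelse(n_risk > n_event,
                    n_event / (n_risk * (n_risk - n_event)), 0)
  var <- surv^2 * cumsum(gw_term)
  var[surv == 0] <- 0
  curve <- list(time = dt, n_risk = as.integer(n_risk),
                n_event = as.integer(n_event), surv = surv, var = var,
                n = length(times), max_time = max(times))
  class(curve) <- "km_curve"
  curve
}

check_surv_input <- function(times, events, groups = NULL) {
  if (length(times) == 0L) stop("empty survival input", call. = FALSE)
  if (length(times) != length(events)) {
    stop("times and events must have equal length", call. = FALSE)
  }
  if (any(!is.finite(times)) || any(times < 0)) {
    stop("times must be finite and non-negative", call. = FALSE)
  }
  if (!all(events %in% c(0, 1))) {
    stop("events must be 0/1", call. = FALSE)
  }
  if (!is.null(groups) && length(groups) != length(times)) {
    stop("group labels must match times in length", call. = FALSE)
  }
  invisible(TRUE)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve: n =", x$n, "with", sum(x$n_event), "events over",
      length(x$time), "distinct event times\n")
  if (length(x$time)) {
    utils::head(data.frame(time = x$time, n_risk = x$n_risk,
                           n_event = x$n_event, surv = x$surv), 10) |>
      print(...)
  }
  invisible(x)
}

#' @export
as.data.frame.km_curve <- function(x, ...) {
  data.frame(time = x$time, n_risk = x$n_risk, n_event = x$n_event,
             surv = x$surv, var = x$var)
}

#' Evaluate a survival curve at given times
#'
#' Right-continuous step-function lookup. Times beyond the last observed
#' follow-up return the last value, with the `"extrapolated"` attribute set.
#'
#' @param curve A [km_estimate()] result.
#' @param t Non-negative times (months); e.g. 60 for the 5-year rate.
#' @return Numeric vector of survival probabilities with a logical attribute
#'   `extrapolated` marking lookups beyond the observed follow-up.
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"))
  if (any(!is.finite(t)) || any(t < 0)) {
    stop("t must be finite and non-negative", call. = FALSE)
  }
  idx <- findInterval(t, curve$time)
  val <- ifelse(idx == 0L, 1, curve$surv[pmax(idx, 1L)])
  attr(val, "extrapolated") <- t > curve$max_time
  val
}

#' K-group log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with hypergeometric expectations given the risk sets; the chi-square
#' statistic aggregates observed-minus-expected with the hypergeometric
#' covariance, on k - 1 degrees of freedom.
#'
#' @param times,events As in [km_estimate()].
#' @param groups Group labels (>= 2 non-empty groups; >= 1 event overall).
#' @return Object of class `logrank_result` with `statistic`, `df`,
#'   `p.value`, and per-group `n`, `observed`, `expected`.
#' @export
logrank_test <- function(times, events, groups) {
  check_surv_input(times, events, groups)
  groups <- factor(groups)
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("log-rank test needs at least 2 non-empty groups",
                   call. = FALSE)
  if (sum(events) < 1) stop("log-rank test needs at least one event",
                            call. = FALSE)
  dt <- sort(unique(times[events == 1]))
  nd <- length(dt)
  # per-group risk and event counts at every distinct event time
  n_mat <- matrix(0, nd, k)
  d_mat <- matrix(0, nd, k)
  for (g in seq_len(k)) {
    tg <- times[as.integer(groups) == g]
    n_mat[, g] <- length(tg) - findInterval(dt, sort(tg), left.open = TRUE)
    et <- times[as.integer(groups) == g & events == 1]
    d_mat[, g] <- tabulate(match(et, dt), nbins = nd)
  }
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  for (j in seq_len(nd)) {
    n_g <- n_mat[j, ]
    d_g <- d_mat[j, ]
    N <- sum(n_g); D <- sum(d_g)
    if (D == 0 || N == 0) next
    O <- O + d_g
    E <- E + n_g * D / N
    if (N > 1) {
      p <- n_g / N
      V <- V + D * (N - D) / (N - 1) * (diag(p, nrow = k) - tcrossprod(p))
    }
  }
  z <- (O - E)[-k]
  Vk <- V[-k, -k, drop = FALSE]
  stat <- tryCatch(drop(crossprod(z, solve(Vk, z))),
                   error = function(e) {
                     # singular covariance: generalized inverse via SVD
                     s <- svd(Vk)
                     pos <- s$d > max(s$d) * 1e-10
                     ginv <- s$v[, pos, drop = FALSE] %*%
                       (t(s$u[, pos, drop = FALSE]) / s$d[pos])
                     drop(crossprod(z, ginv %*% z))
                   })
  stat <- max(stat, 0)
  res <- list(statistic = stat, df = k - 1L,
              p.value = stats::pchisq(stat, k - 1L, lower.tail = FALSE),
              n = tabulate(groups, nbins = k), observed = O, expected = E,
              groups = levels(groups))
  class(res) <- "logrank_result"
  res
}

#' @export
print.logrank_result <- function(x, ...) {
  cat("Log-rank test: chi-square =", format(x$statistic, digits = 6),
      "on", x$df, "df, p =", format.pval(x$p.value), "\n")
  print(data.frame(group = x$groups, n = x$n, observed = x$observed,
                   expected = round(x$expected, 2)))
  invisible(x)
}

# Partial log-likelihood, score and information at beta.
# Breslow: each tied death contributes the full risk-set denominator;
# Efron: the l-th of d tied deaths sees the denominator reduced by
# (l-1)/d of the tied deaths' own terms.
cox_quantities <- function(beta, times, events, x, ties) {
  n <- length(times); p <- ncol(x)
  ord <- order(times, -events)  # within a time, deaths first (cosmetic)
  tt <- times[ord]; ev <- events[ord]; xx <- x[ord, , drop = FALSE]
  eta <- drop(xx %*% beta)
  eta <- pmin(eta, 500)  # guard exp overflow under diverging beta
  r <- exp(eta)

  # reverse cumulative risk-set sums (times ascending => risk set suffix)
  rev_cumsum <- function(v) rev(cumsum(rev(v)))
  S0 <- rev_cumsum(r)
  S1 <- apply(xx * r, 2, rev_cumsum)
  if (p == 1L) S1 <- matrix(S1, ncol = 1L)
  # S2 as p x p per position, stored as n x (p*p)
  S2 <- matrix(0, n, p * p)
  for (a in seq_len(p)) {
    for (b in seq_len(a)) {
      v <- rev_cumsum(xx[, a] * xx[, b] * r)
      S2[, (a - 1L) * p + b] <- v
      S2[, (b - 1L) * p + a] <- v
    }
  }

  loglik <- 0
  U <- numeric(p)
  I <- matrix(0, p, p)
  event_times <- unique(tt[ev == 1])
  first_idx <- match(event_times, tt)  # first row with that time
  for (j in seq_along(event_times)) {
    t0 <- event_times[j]
    rows <- which(tt == t0 & ev == 1)
    d <- length(rows)
    s0 <- S0[first_idx[j]]
    s1 <- S1[first_idx[j], ]
    s2 <- matrix(S2[first_idx[j], ], p, p)
    xsum <- colSums(xx[rows, , drop = FALSE])
    loglik <- loglik + sum(eta[rows])
    if (ties == "breslow" || d == 1L) {
      loglik <- loglik - d * log(s0)
      U <- U + xsum - d * s1 / s0
      I <- I + d * (s2 / s0 - tcrossprod(s1 / s0))
    } else {
      rd <- r[rows]
      s0d <- sum(rd)
      s1d <- colSums(xx[rows, , drop = FALSE] * rd)
      s2d <- crossprod(xx[rows, , drop = FALSE] * sqrt(rd))
      for (l in seq_len(d)) {
        f <- (l - 1) / d
        s0l <- s0 - f * s0d
        s1l <- s1 - f * s1d
        s2l <- s2 - f * s2d
        loglik <- loglik - log(s0l)
        U <- U + xsum / d - s1l / s0l
        I <- I + s2l / s0l - tcrossprod(s1l / s0l)
      }
    }
  }
  list(loglik = loglik, score = U, info = I)
}

#' Cox proportional-hazards fit
#'
#' Newton-Raphson maximization of the partial likelihood, with Breslow
#' (default) or Efron handling of tied event times. Standard errors come
#' from the inverse observed information; convergence is declared when the
#' sup-norm of the score drops below `tol`. Monotone likelihood (perfect
#' separation) is reported via the convergence flag rather than silently
#' returning a diverged estimate.
#'
#' @param times,events As in [km_estimate()]; at least one event required.
#' @param x Covariate matrix (or vector / data frame); no missing values,
#'   no constant columns.
#' @param ties `"breslow"` or `"efron"`.
#' @param tol Convergence tolerance on the score sup-norm.
#' @param max_iter Maximum Newton iterations.
#' @return Object of class `cox_fit`: coefficients, `se`, hazard ratios with
#'   95% CI, Wald `z` and p-values, log partial likelihood at zero and at the
#'   fit, iteration count and convergence flag.
#' @export
cox_fit <- function(times, events, x, ties = c("breslow", "efron"),
                    tol = 1e-8, max_iter = 50L) {
  ties <- match.arg(ties)
  x <- as.matrix(as.data.frame(x))
  storage.mode(x) <- "double"
  check_surv_input(times, events)
  if (nrow(x) != length(times)) {
    stop("covariate rows must match times", call. = FALSE)
  }
  if (anyNA(x)) stop("missing values in covariates", call. = FALSE)
  if (sum(events) < 1) stop("Cox fit needs at least one event", call. = FALSE)
  cn <- colnames(x)
  if (is.null(cn)) cn <- paste0("x", seq_len(ncol(x)))
  const <- apply(x, 2, function(v) diff(range(v)) == 0)
  if (any(const)) {
    stop("constant covariate column(s): ", paste(cn[const], collapse = ", "),
         call. = FALSE)
  }
  qx <- qr(scale(x, scale = FALSE))
  if (qx$rank < ncol(x)) {
    stop("collinear covariate column(s): ",
         paste(cn[qx$pivot[seq(qx$rank + 1L, ncol(x))]], collapse = ", "),
         call. = FALSE)
  }

  # center for numerical stability; leaves coefficients unchanged
  xc <- scale(x, scale = FALSE)
  p <- ncol(xc)
  beta <- numeric(p)
  q0 <- cox_quantities(beta, times, events, xc, ties)
  loglik0 <- q0$loglik
  q <- q0
  converged <- FALSE
  diagnostic <- NULL
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    if (max(abs(q$score)) < tol) { converged <- TRUE; break }
    step <- tryCatch(solve(q$info, q$score), error = function(e) NULL)
    if (is.null(step)) {
      diagnostic <- "singular information matrix"
      break
    }
    # step-halving if the likelihood does not improve
    lambda <- 1
    repeat {
      beta_new <- beta + lambda * step
      q_new <- cox_quantities(beta_new, times, events, xc, ties)
      if (is.finite(q_new$loglik) && q_new$loglik >= q$loglik - 1e-12) break
      lambda <- lambda / 2
      if (lambda < 1e-10) break
    }
    # stationary to machine precision: the Newton increment is negligible
    # even though the score sup-norm (which scales with the event count)
    # sits above the absolute tolerance
    if (max(abs(beta_new - beta)) < 1e-10 * max(1, max(abs(beta_new)))) {
      beta <- beta_new
      q <- q_new
      converged <- TRUE
      break
    }
    beta <- beta_new
    q <- q_new
    if (max(abs(beta)) > 20) {
      diagnostic <- "diverging coefficients: possible monotone likelihood (perfect separation)"
      break
    }
  }
  if (!converged && max(abs(q$score)) < tol) converged <- TRUE
  if (!converged && is.null(diagnostic)) {
    diagnostic <- paste0("score not below tolerance after ", max_iter,
                         " iterations")
  }
  se <- rep(NA_real_, p)
  cov <- tryCatch(solve(q$info), error = function(e) NULL)
  if (!is.null(cov)) se <- sqrt(pmax(diag(cov), 0))
  zval <- beta / se
  fit <- list(coef = stats::setNames(drop(beta), cn),
              se = stats::setNames(se, cn),
              hr = exp(drop(beta)),
              ci_lower = exp(drop(beta) - 1.96 * se),
              ci_upper = exp(drop(beta) + 1.96 * se),
              z = zval,
              p.value = 2 * stats::pnorm(-abs(zval)),
              loglik = c(null = loglik0, fit = q$loglik),
              score = q$score, iter = iter, converged = converged,
              diagnostic = diagnostic, ties = ties, n = length(times),
              n_event = sum(events))
  class(fit) <- "cox_fit"
  fit
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox proportional-hazards fit (", x$ties, " ties), n = ", x$n,
      ", events = ", x$n_event, "\n", sep = "")
  print(data.frame(coef = x$coef, se = x$se, HR = x$hr,
                   lower95 = x$ci_lower, upper95 = x$ci_upper,
                   z = x$z, p = x$p.value))
  if (!x$converged) cat("NOT CONVERGED:", x$diagnostic, "\n")
  invisible(x)
}

#' Spearman rank correlation
#'
#' Pearson correlation of average ranks, with the t approximation for the
#' p-value.
#'
#' @param x,y Numeric vectors of equal length >= 3; neither constant.
#' @return List with `rho` and `p.value`.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed", call. = FALSE)
  if (diff(range(x)) == 0 || diff(range(y)) == 0) {
    stop("constant vector: rank correlation undefined", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  if (abs(rho) >= 1 - 1e-15) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  list(rho = rho, p.value = p)
}
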