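# Product-limit (Kaplan-Meier) estimation and the k-group log-rank test.
#
# Authored here rather than delegated: these are the statistical core of the
# persistence analysis. Conventions follow standard survival software: at
# tied times events precede censorings; confidence intervals use the
# complementary log-log transform so bounds stay in [0, 1]; the median CI
# inverts the pointwise CI at 0.5 (Brookmeyer-Crowley style).

#' Kaplan-Meier product-limit estimate
#'
#' @param time numeric vector of observation times (>= 0).
#' @param event 0/1 vector: 1 = discontinuation event, 0 = censored.
#' @param conf_level pointwise confidence level (default 0.95).
#' @return object of class `km_curve`: vectors over the distinct observed
#'   times (`time`, `n_risk`, `n_event`, `n_censor`, `survival`,
#'   `greenwood_se`, `ci_lower`, `ci_upper`) plus `n_total`, `n_events`,
#'   `conf_level`. An all-censored input gives a curve with S identically 1.
#' @export
km_estimate <- function(time, event, conf_level = 0.95) {
  if (!length(time)) stop("need at least one observation")
  if (any(time < 0)) stop("times must be >= 0")
  if (!all(event %in% c(0, 1))) stop("event must be 0/1")
  n <- length(time)
  tt <- sort(unique(time))
  d <- as.vector(table(factor(time[event == 1], levels = tt)))
  cns <- as.vector(table(factor(time[event == 0], levels = tt)))
  n_risk <- n - c(0, cumsum(d + cns)[-length(tt)])
  s <- cumprod(1 - d / n_risk)
  varsum <- cumsum(ifelse(d > 0 & n_risk > d,
                          d / (n_risk * (n_risk - d)),
                          ifelse(d > 0, Inf, 0)))
  se <- ifelse(s > 0 & is.finite(varsum), s * sqrt(varsum), NA_real_)
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  interior <- s > 0 & s < 1 & is.finite(varsum)
  se_cll <- ifelse(interior, sqrt(varsum) / abs(log(s)), NA_real_)
  lo <- ifelse(interior, pmin(1, pmax(0, s^exp(z * se_cll))), NA_real_)
  hi <- ifelse(interior, pmin(1, pmax(0, s^exp(-z * se_cll))), NA_real_)
  structure(list(
    time = tt, n_risk = n_risk, n_event = d, n_censor = cns,
    survival = s, greenwood_se = se, ci_lower = lo, ci_upper = hi,
    n_total = n, n_events = sum(event), conf_level = conf_level
  ), class = "km_curve")
}

#' Evaluate a survival curve at a time point
#'
#' Right-continuous step-function evaluation: at an event time the post-jump
#' value is returned.
#'
#' @param curve a `km_curve`.
#' @param t time (>= 0).
#' @return list with `estimate`, `ci_lower`, `ci_upper`, `pct` (the estimate
#'   as a one-decimal percentage) and `beyond_last` (`TRUE` when `t` exceeds
#'   the last observed time, in which case the last value is carried forward).
#' @export
survival_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), t >= 0)
  i <- findInterval(t, curve$time)
  if (i == 0) {
    est <- 1; lo <- NA_real_; hi <- NA_real_
  } else {
    est <- curve$survival[i]; lo <- curve$ci_lower[i]; hi <- curve$ci_upper[i]
  }
  list(estimate = est, ci_lower = lo, ci_upper = hi,
       pct = round_half_away(100 * est, 1),
       beyond_last = t > max(curve$time))
}

#' Median survival time with confidence interval
#'
#' The median is the smallest observed time at which S(t) drops to 0.5 or
#' below; `NA` ("not reached") if S never does. The CI bounds are the
#' smallest times at which the pointwise lower / upper confidence limits
#' cross 0.5.
#'
#' @param curve a `km_curve`.
#' @return list with `median_days`, `ci_lower`, `ci_upper` (each possibly
#'   `NA`).
#' @export
km_median <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  first_at_or_below <- function(vals) {
    ok <- !is.na(vals) & vals <= 0.5
    if (any(ok)) curve$time[which(ok)[1]] else NA_real_
  }
  # once S reaches 0, its (undefined) CI is treated as having crossed too
  surv0 <- curve$survival == 0
  up <- ifelse(surv0, 0, curve$ci_upper)
  lo <- ifelse(surv0, 0, curve$ci_lower)
  # the lower CI limit sits below S, so it crosses 0.5 earliest: it bounds
  # the median from below; the upper limit crosses last and bounds it above
  list(median_days = first_at_or_below(curve$survival),
       ci_lower = first_at_or_below(lo),
       ci_upper = first_at_or_below(up))
}

#' k-group log-rank test
#'
#' At each distinct event time the observed events per group are compared
#' with their hypergeometric expectation given the risk sets; the chi-square
#' statistic is the quadratic form of the (k-1)-dimensional observed-minus-
#' expected vector with its hypergeometric covariance.
#'
#' @param time numeric vector of observation times.
#' @param event 0/1 event indicators.
#' @param group group labels (>= 2 groups, each non-empty).
#' @return list with `chi_square`, `df` (= groups - 1), `p_value`, and the
#'   per-group `observed` and `expected` event counts.
#' @export
logrank_test <- function(time, event, group) {
  g <- if (is.factor(group)) group else factor(group)
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups")
  if (any(table(g) == 0)) stop("group with zero observations")
  tt <- sort(unique(time[event == 1]))
  O <- E <- numeric(k)
  V <- matrix(0, k, k)
  gi <- as.integer(g)
  for (u in tt) {
    at <- time >= u
    n_u <- sum(at)
    ng <- tabulate(gi[at], k)
    ev <- event == 1 & time == u
    d_u <- sum(ev)
    dg <- tabulate(gi[ev], k)
    O <- O + dg
    E <- E + d_u * ng / n_u
    if (n_u > 1) {
      scale <- d_u * (n_u - d_u) / (n_u - 1)
      V <- V + scale * (diag(ng, k) * n_u - outer(ng, ng)) / n_u^2
    }
  }
  idx <- seq_len(k - 1)
  u_vec <- (O - E)[idx]
  Vi <- V[idx, idx, drop = FALSE]
  chi <- tryCatch(drop(t(u_vec) %*% solve(Vi, u_vec)), error = function(e) {
    sv <- svd(Vi)  # pseudo-inverse for degenerate risk sets
    pos <- sv$d > max(sv$d) * 1e-12
    drop(t(u_vec) %*% sv$v[, pos, drop = FALSE] %*%
           ((t(sv$u[, pos, drop = FALSE]) %*% u_vec) / sv$d[pos]))
  })
  chi <- max(0, chi)
  list(chi_square = chi, df = k - 1,
       p_value = stats::pchisq(chi, df = k - 1, lower.tail = FALSE),
       observed = stats::setNames(O, levels(g)),
       expected = stats::setNames(E, levels(g)))
}

#' Format a p-value the way clinical tables print it
#'
#' Three decimals, floored at "<0.001".
#'
#' @param p p-value in `[0, 1]`.
#' @return character scalar.
#' @export
format_p <- function(p) {
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}

#' @export
print.km_curve <- function(x, ...) {
  cat("Kaplan-Meier curve:", x$n_total, "subjects,", x$n_events, "events\n")
  med <- km_median(x)
  cat("  median:", if (is.na(med$median_days)) "not reached" else
    paste0(med$median_days, " d [", med$ci_lower, ", ", med$ci_upper, "]"), "\n")
  invisible(x)
}

#' Plot a Kaplan-Meier curve
#'
#' Step plot with pointwise confidence band.
#'
#' @param x a `km_curve`.
#' @param ... passed to [plot()].
#' @return `x`, invisibly.
#' @export
plot.km_curve <- function(x, ...) {
  t0 <- c(0, x$time)
  s0 <- c(1, x$survival)
  plot(t0, s0, type = "s", ylim = c(0, 1),
       xlab = "Days since index", ylab = "Proportion persistent", ...)
  graphics::lines(c(0, x$time), c(1, ifelse(is.na(x$ci_lower), x$survival,
                                            x$ci_lower)), type = "s", lty = 2)
  graphics::lines(c(0, x$time), c(1, ifelse(is.na(x$ci_upper), x$survival,
                                            x$ci_upper)), type = "s", lty = 2)
  invisible(x)
}
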