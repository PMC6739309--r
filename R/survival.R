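# Kaplan-Meier curves and the two-group log-rank test for the dichotomized
# cohort, backed by the survival package (survfit/survdiff). Events sharing
# a time are aggregated with the hypergeometric variance; subjects censored
# at an event time count as at risk at that time (the conventional order).

#' Kaplan-Meier product-limit estimate for one group
#'
#' @param time nonnegative follow-up times.
#' @param event binary event indicator (1 = death observed).
#' @return Object of class `km_curve`: data.frame `curve` with one row per
#'   distinct event time (`time`, `at_risk`, `events`, `survival`) plus the
#'   implicit S(0) = 1; `n` subjects.
#' @export
km_estimate <- function(time, event) {
  if (length(time) < 1) stop("need at least one subject", call. = FALSE)
  if (any(time < 0)) stop("negative follow-up time", call. = FALSE)
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  keep <- fit$n.event > 0
  curve <- data.frame(time = fit$time[keep],
                      at_risk = fit$n.risk[keep],
                      events = fit$n.event[keep],
                      survival = fit$surv[keep])
  structure(list(curve = curve, n = length(time)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("<km_curve> n=%d, %d event time(s)\n", x$n, nrow(x$curve)))
  print(x$curve)
  invisible(x)
}

#' Survival probability of a KM curve at given times
#'
#' Right-continuous step evaluation; S(t) = 1 before the first event.
#'
#' @param km a `km_curve`.
#' @param t times at which to evaluate.
#' @return Numeric vector of survival probabilities.
#' @export
km_survival_at <- function(km, t) {
  vapply(t, function(ti) {
    idx <- which(km$curve$time <= ti)
    if (!length(idx)) 1 else km$curve$survival[max(idx)]
  }, numeric(1))
}

#' Two-group log-rank test
#'
#' Standard aggregated-ties log-rank: at each distinct event time the
#' expected events and hypergeometric variance are accumulated per group;
#' the statistic is (O - E)^2 / V with p from the upper chi-square(1) tail.
#'
#' @param time follow-up times for all subjects.
#' @param event binary event indicators.
#' @param group two-level group labels.
#' @return Object of class `logrank_result`: `statistic`, `df`, `p`, and
#'   per-group `observed`, `expected`, plus the variance `v`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  g <- factor(group)
  if (nlevels(g) != 2) stop("exactly two groups required", call. = FALSE)
  if (any(table(g) == 0)) stop("both groups must be non-empty", call. = FALSE)
  if (sum(event) < 1) stop("need at least one event overall", call. = FALSE)
  sd <- survival::survdiff(survival::Surv(time, event) ~ g)
  v <- if (is.matrix(sd$var)) sd$var[1, 1] else sd$var[1]
  if (!is.finite(v) || v <= 0)
    stop("degenerate log-rank: zero variance", call. = FALSE)
  structure(list(statistic = sd$chisq, df = 1,
                 p = stats::pchisq(sd$chisq, df = 1, lower.tail = FALSE),
                 observed = stats::setNames(sd$obs, levels(g)),
                 expected = stats::setNames(sd$exp, levels(g)),
                 v = v),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("<logrank_result> chisq=%.4g on %d df, p=%.3g\n",
              x$statistic, x$df, x$p))
  print(data.frame(observed = x$observed, expected = x$expected))
  invisible(x)
}
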