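# 2x2 contingency statistics for the threshold scan, implemented from first
# principles: Fisher's exact test by minimum-likelihood summation over the
# conditional hypergeometric support, Pearson chi-square, and risk/odds
# ratios with log-scale normal CIs.

#' Construct a 2x2 confusion matrix
#'
#' Cells follow the exposure-by-outcome convention: `a` = exposed (biomarker
#' at or above the threshold) with the event, `b` = exposed without, `c` =
#' unexposed with, `d` = unexposed without. Marginals are always derived,
#' never stored.
#'
#' @param a,b,c,d nonnegative integer counts.
#' @return Object of class `confusion_matrix_2x2`.
#' @export
confusion_matrix <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(cells < 0) || any(cells != floor(cells)))
    stop("cell counts must be nonnegative integers", call. = FALSE)
  structure(as.list(cells), class = "confusion_matrix_2x2")
}

#' @export
print.confusion_matrix_2x2 <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2,
              dimnames = list(c("high", "low"), c("event", "no event")))
  cat("<confusion_matrix_2x2>\n"); print(m); invisible(x)
}

#' Tabulate a dichotomized cohort against outcomes
#'
#' @param dichotomized a `dichotomized_cohort` from
#'   [dichotomize_by_threshold()].
#' @param outcomes named binary vector (1 = event) indexed by subject id.
#' @return A [confusion_matrix()] with `a + b = |high|`, `c + d = |low|`.
#' @export
from_groups <- function(dichotomized, outcomes) {
  stopifnot(inherits(dichotomized, "dichotomized_cohort"))
  ids <- c(dichotomized$high_ids, dichotomized$low_ids)
  oc <- outcomes[ids]
  if (anyNA(oc))
    stop("outcome missing for subject(s): ",
         paste(utils::head(ids[is.na(oc)], 5), collapse = ", "),
         call. = FALSE)
  hi <- outcomes[dichotomized$high_ids]
  lo <- outcomes[dichotomized$low_ids]
  confusion_matrix(sum(hi == 1), sum(hi == 0), sum(lo == 1), sum(lo == 0))
}

#' Two-sided Fisher exact test on a 2x2 table
#'
#' Conditions on both margins and sums the hypergeometric point
#' probabilities not exceeding that of the observed table, with a relative
#' tolerance of 1e-7 to absorb floating error (the minimum-likelihood rule).
#'
#' @param m a [confusion_matrix()].
#' @return List with `p` and `degenerate` (TRUE when a zero margin forces
#'   `p = 1`).
#' @export
fisher_exact_two_sided <- function(m) {
  r1 <- m$a + m$b; r2 <- m$c + m$d
  c1 <- m$a + m$c; c2 <- m$b + m$d
  n <- r1 + r2
  if (n < 1) stop("empty table", call. = FALSE)
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    return(list(p = 1, degenerate = TRUE))
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(m$a, r1, r2, c1)
  p <- sum(probs[probs <= p_obs * (1 + 1e-7)])
  list(p = min(p, 1), degenerate = FALSE)
}

#' Pearson chi-square test on a 2x2 table
#'
#' @param m a [confusion_matrix()].
#' @param yates apply the continuity correction (|O - E| reduced by 0.5)?
#'   Off by default.
#' @return List with `statistic` and `p` (upper tail of chi-square with
#'   1 df).
#' @export
pearson_chi_square <- function(m, yates = FALSE) {
  obs <- c(m$a, m$b, m$c, m$d)
  r1 <- m$a + m$b; r2 <- m$c + m$d
  c1 <- m$a + m$c; c2 <- m$b + m$d
  n <- r1 + r2
  if (r1 == 0 || r2 == 0 || c1 == 0 || c2 == 0)
    stop("chi-square undefined: a zero margin gives zero expected counts",
         call. = FALSE)
  expected <- c(r1 * c1, r1 * c2, r2 * c1, r2 * c2) / n
  dev <- abs(obs - expected)
  if (yates) dev <- pmax(dev - 0.5, 0)
  stat <- sum(dev^2 / expected)
  list(statistic = stat, p = stats::pchisq(stat, df = 1, lower.tail = FALSE))
}

ratio_estimate <- function(estimate, ci_low, ci_high, level, corrected) {
  structure(list(estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                 level = level, corrected = corrected),
            class = "ratio_estimate")
}

#' @export
print.ratio_estimate <- function(x, ...) {
  cat(sprintf("%.3g [%.3g, %.3g] (%g%% CI%s)\n", x$estimate, x$ci_low,
              x$ci_high, 100 * x$level,
              if (x$corrected) ", continuity-corrected" else ""))
  invisible(x)
}

#' Risk ratio with a Katz log-scale confidence interval
#'
#' RR = \[a/(a+b)\] / \[c/(c+d)\]; the CI is
#' `exp(ln RR +/- z * sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. When `a` or `c`
#' is zero, the Haldane-Anscombe correction adds 0.5 to all four cells and
#' the `corrected` flag is set.
#'
#' @param m a [confusion_matrix()].
#' @param level confidence level (default 0.95).
#' @return A `ratio_estimate`.
#' @export
risk_ratio_ci <- function(m, level = 0.95) {
  if (m$a + m$b == 0 || m$c + m$d == 0)
    stop("risk ratio undefined: an exposure row is empty", call. = FALSE)
  corrected <- (m$a == 0 || m$c == 0)
  k <- if (corrected) 0.5 else 0
  a <- m$a + k; b <- m$b + k; c <- m$c + k; d <- m$d + k
  rr <- (a / (a + b)) / (c / (c + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / c - 1 / (c + d))
  z <- stats::qnorm(1 - (1 - level) / 2)
  ratio_estimate(rr, exp(log(rr) - z * se), exp(log(rr) + z * se),
                 level, corrected)
}

#' Odds ratio with a Woolf log-scale confidence interval
#'
#' OR = ad/bc; CI `exp(ln OR +/- z * sqrt(1/a + 1/b + 1/c + 1/d))`; 0.5 is
#' added to every cell when any cell is zero (flagged).
#'
#' @inheritParams risk_ratio_ci
#' @return A `ratio_estimate`.
#' @export
odds_ratio_ci <- function(m, level = 0.95) {
  if (m$a + m$b == 0 || m$c + m$d == 0)
    stop("odds ratio undefined: an exposure row is empty", call. = FALSE)
  corrected <- any(c(m$a, m$b, m$c, m$d) == 0)
  k <- if (corrected) 0.5 else 0
  a <- m$a + k; b <- m$b + k; c <- m$c + k; d <- m$d + k
  or <- (a * d) / (b * c)
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  z <- stats::qnorm(1 - (1 - level) / 2)
  ratio_estimate(or, exp(log(or) - z * se), exp(log(or) + z * se),
                 level, corrected)
}
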