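# Exhaustive cut-point discovery: every candidate threshold gets a 2x2
# confusion matrix with Fisher, chi-square and risk-ratio records; the best
# cut-off is the record minimizing the raw Fisher p.

#' Candidate thresholds for an exhaustive scan
#'
#' Candidates are the sorted unique observed values whose ">= tau" split
#' leaves both groups at or above `min_group_size`. Observed values (not
#' midpoints) form the grid, so the scan is deterministic on the stored data.
#'
#' @param values biomarker values (missing values ignored).
#' @param min_group_size smallest admissible group (default 5; set 1 for toy
#'   data).
#' @return Increasing numeric vector of candidate thresholds.
#' @export
candidate_thresholds <- function(values, min_group_size = 5) {
  v <- values[!is.na(values)]
  u <- sort(unique(v))
  if (length(u) < 2)
    stop("need at least 2 distinct values to form a threshold grid",
         call. = FALSE)
  n_high <- vapply(u, function(tau) sum(v >= tau), numeric(1))
  keep <- n_high >= min_group_size & (length(v) - n_high) >= min_group_size
  u[keep]
}

#' Scan all candidate thresholds of a biomarker
#'
#' For every candidate cut-off the cohort is dichotomized (ties go high), a
#' confusion matrix is built against the binary outcome, and Fisher exact,
#' Pearson chi-square and risk-ratio-with-CI records are attached. Records
#' are ordered by threshold.
#'
#' @param cohort a [cohort_table()].
#' @param biomarker biomarker column to scan.
#' @param outcome outcome column name (default `"outcome"`).
#' @param min_group_size group-size floor for candidates.
#' @param yates use the continuity-corrected chi-square? Default FALSE.
#' @param conf_level confidence level for the risk ratio.
#' @return A `scan_ledger`: list with `records` (one data.frame row per
#'   threshold: tau, a, b, c, d, n_high, n_low, fisher_p, chi2_stat, chi2_p,
#'   rr, rr_low, rr_high, rr_corrected, degenerate, adjusted_p), `biomarker`,
#'   `n_missing`, and the echoed `config`.
#' @export
scan_thresholds <- function(cohort, biomarker, outcome = "outcome",
                            min_group_size = 5, yates = FALSE,
                            conf_level = 0.95) {
  stopifnot(inherits(cohort, "cohort_table"))
  oc <- stats::setNames(cohort[[outcome]], cohort$subject_id)
  v <- cohort[[biomarker]]
  known <- oc[!is.na(v)]
  if (all(known == known[1], na.rm = TRUE))
    stop("all subjects share the same outcome; the scan is degenerate",
         call. = FALSE)
  taus <- candidate_thresholds(v, min_group_size)
  rows <- lapply(taus, function(tau) {
    d <- dichotomize_by_threshold(cohort, biomarker, tau)
    m <- from_groups(d, oc)
    fis <- fisher_exact_two_sided(m)
    degenerate <- fis$degenerate ||
      length(d$high_ids) < min_group_size ||
      length(d$low_ids) < min_group_size
    chi <- if (fis$degenerate) list(statistic = NA_real_, p = NA_real_)
           else pearson_chi_square(m, yates = yates)
    rr <- tryCatch(risk_ratio_ci(m, level = conf_level),
                   error = function(e) ratio_estimate(NA_real_, NA_real_,
                                                      NA_real_, conf_level,
                                                      FALSE))
    data.frame(tau = tau, a = m$a, b = m$b, c = m$c, d = m$d,
               n_high = m$a + m$b, n_low = m$c + m$d,
               fisher_p = fis$p, chi2_stat = chi$statistic, chi2_p = chi$p,
               rr = rr$estimate, rr_low = rr$ci_low, rr_high = rr$ci_high,
               rr_corrected = rr$corrected, degenerate = degenerate,
               adjusted_p = NA_real_)
  })
  structure(list(records = do.call(rbind, rows),
                 biomarker = biomarker,
                 n_missing = sum(is.na(v)),
                 config = list(outcome = outcome,
                               min_group_size = min_group_size,
                               yates = yates, conf_level = conf_level)),
            class = "scan_ledger")
}

#' @export
print.scan_ledger <- function(x, ...) {
  cat(sprintf("<scan_ledger> %s: %d candidate threshold(s), %d missing\n",
              x$biomarker, nrow(x$records), x$n_missing))
  print(utils::head(x$records, 10))
  if (nrow(x$records) > 10) cat("  ...\n")
  invisible(x)
}

#' Select the best cut-off from a scan ledger
#'
#' The best record minimizes the raw Fisher p among non-degenerate records;
#' ties are broken by larger |ln RR|, then by smaller threshold. Selection
#' uses raw (not multiplicity-adjusted) p, mirroring an uncorrected
#' exhaustive scan; the adjusted column makes the optimism visible.
#'
#' @param ledger a `scan_ledger`.
#' @return The selected record (one-row data.frame) with an attribute
#'   `criterion` echoing the rule.
#' @export
select_best_threshold <- function(ledger) {
  rec <- ledger$records[!ledger$records$degenerate, , drop = FALSE]
  if (!nrow(rec))
    stop("no non-degenerate threshold record to select from", call. = FALSE)
  ord <- order(rec$fisher_p, -abs(log(rec$rr)), rec$tau)
  best <- rec[ord[1], , drop = FALSE]
  attr(best, "criterion") <-
    "min raw Fisher p; ties by larger |ln RR|, then smaller tau"
  best
}

#' Attach multiplicity-adjusted Fisher p-values to a ledger
#'
#' Adjustment runs over the non-degenerate records only; `"none"` copies the
#' raw p. The selection rule of [select_best_threshold()] is unaffected.
#'
#' @param ledger a `scan_ledger`.
#' @param method `"bonferroni"`, `"holm"` or `"none"`.
#' @return The ledger with `adjusted_p` filled.
#' @export
adjust_ledger_pvalues <- function(ledger,
                                  method = c("bonferroni", "holm", "none")) {
  method <- match.arg(method)
  ok <- !ledger$records$degenerate
  ledger$records$adjusted_p <- NA_real_
  ledger$records$adjusted_p[ok] <-
    if (method == "none") ledger$records$fisher_p[ok]
    else stats::p.adjust(ledger$records$fisher_p[ok], method = method)
  ledger$config$adjust <- method
  ledger
}

#' Export a scan ledger as TSV
#'
#' One row per threshold with the columns of `ledger$records`.
#'
#' @param ledger a `scan_ledger`.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_ledger_tsv <- function(ledger, path) {
  utils::write.table(ledger$records, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
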