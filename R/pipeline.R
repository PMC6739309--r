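# End-to-end orchestration: simulate (or read) a cohort, scan thresholds,
# report the best cut-off with group mortality, compare survival of the
# dichotomized groups, and rank candidate models by BIC. One seed governs
# every stochastic stage.

pipeline_defaults <- function() {
  list(input = NULL,            # file path, or NULL to simulate
       generator = list(),      # overrides for sepsis_generator_config()
       biomarker = "eNAPRT",
       outcome = "outcome",
       time = "time",
       event = "event",
       scan = list(min_group_size = 5, adjust = "bonferroni",
                   yates = FALSE, conf_level = 0.95),
       models = list(candidates = NULL, pop_size = 50, generations = 100,
                     top_k = 10),
       seed = 1,
       out_dir = NULL)
}

#' Load and validate a pipeline configuration
#'
#' JSON or YAML (by extension); unknown top-level or nested keys are
#' rejected so typos cannot silently fall back to defaults.
#'
#' @param path config file (`.json`, `.yaml`/`.yml`).
#' @return Validated config list with defaults filled.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else jsonlite::fromJSON(path, simplifyVector = TRUE)
  validate_pipeline_config(raw)
}

#' Validate a pipeline configuration list
#'
#' @param config list of overrides over the defaults (see
#'   [run_pipeline()]).
#' @return Validated config with defaults applied.
#' @export
validate_pipeline_config <- function(config = list()) {
  def <- pipeline_defaults()
  unknown <- setdiff(names(config), names(def))
  if (length(unknown))
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (sec in c("scan", "models")) {
    bad <- setdiff(names(config[[sec]]), names(def[[sec]]))
    if (length(bad))
      stop("unknown config key(s) in '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  cfg <- utils::modifyList(def, config)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1)
    stop("config 'seed' must be a single number", call. = FALSE)
  stopifnot(is.character(cfg$biomarker), length(cfg$biomarker) == 1)
  cfg
}

#' Write a pipeline configuration to JSON
#'
#' @param config validated config list.
#' @param path destination `.json` file.
#' @return Invisibly, `path`.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

log_stage <- function(...) message(sprintf("[riskscan %s] ",
                                           format(Sys.time(), "%H:%M:%S")),
                                   sprintf(...))

#' Run the full risk-stratification pipeline
#'
#' Stages: (1) load the cohort from `config$input` or simulate one with
#' [generate_cohort()]; (2) [scan_thresholds()] over the configured
#' biomarker and attach multiplicity-adjusted p-values; (3) select the best
#' cut-off and report its confusion matrix, Fisher p, risk ratio with CI and
#' group mortality percentages; (4) Kaplan-Meier / log-rank comparison of
#' the dichotomized groups (when survival columns are present); (5) rank
#' candidate binomial GLMs by BIC with [ga_search()]. Progress is logged to
#' standard error; data outputs stay machine-readable.
#'
#' @param config a config list (see [validate_pipeline_config()]) or the
#'   path handling of [load_config()] done beforehand.
#' @return The report: a list with `cohort_summary`, `ledger`, `best`,
#'   `survival`, `models`, `config`, `seed` and `version`. When
#'   `config$out_dir` is set, `report.json`, `ledger.tsv` and `cohort.csv`
#'   are written there.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- validate_pipeline_config(config)

  log_stage("stage 1: cohort")
  cohort <- if (is.null(cfg$input)) {
    gen <- do.call(sepsis_generator_config,
                   c(list(seed = cfg$seed), cfg$generator))
    generate_cohort(gen)
  } else {
    read_cohort_table(cfg$input)
  }

  log_stage("stage 2: threshold scan on %s", cfg$biomarker)
  ledger <- scan_thresholds(cohort, cfg$biomarker, outcome = cfg$outcome,
                            min_group_size = cfg$scan$min_group_size,
                            yates = cfg$scan$yates,
                            conf_level = cfg$scan$conf_level)
  ledger <- adjust_ledger_pvalues(ledger, cfg$scan$adjust)

  log_stage("stage 3: best threshold")
  best <- select_best_threshold(ledger)
  best_report <- list(
    tau = best$tau,
    matrix = list(a = best$a, b = best$b, c = best$c, d = best$d),
    fisher_p = best$fisher_p,
    chi2_p = best$chi2_p,
    rr = best$rr, rr_ci = c(best$rr_low, best$rr_high),
    mortality_high_pct = round(100 * best$a / (best$a + best$b)),
    mortality_low_pct = round(100 * best$c / (best$c + best$d)),
    criterion = attr(best, "criterion"))

  surv_report <- NULL
  if (cfg$time %in% names(cohort) && cfg$event %in% names(cohort)) {
    log_stage("stage 4: survival")
    d <- dichotomize_by_threshold(cohort, cfg$biomarker, best$tau)
    grp <- ifelse(cohort$subject_id %in% d$high_ids, "high", "low")
    keep <- cohort$subject_id %in% c(d$high_ids, d$low_ids)
    lr <- logrank_test(cohort[[cfg$time]][keep], cohort[[cfg$event]][keep],
                       grp[keep])
    surv_report <- list(logrank_chisq = lr$statistic, logrank_p = lr$p,
                        observed = as.list(lr$observed),
                        expected = as.list(lr$expected))
  }

  log_stage("stage 5: model selection")
  cand <- cfg$models$candidates
  if (is.null(cand)) {
    covs <- setdiff(biomarker_names(cohort),
                    c(cfg$biomarker, "creatinine", "LDH"))
    cand <- default_candidate_effects(cfg$biomarker, covs)
  }
  gcfg <- ga_config(pop_size = cfg$models$pop_size,
                    generations = cfg$models$generations,
                    top_k = cfg$models$top_k,
                    seed = sub_seed(cfg$seed, 97))
  models <- ga_search(cohort, cand, gcfg, outcome = cfg$outcome)
  model_report <- lapply(seq_along(models$models), function(i)
    list(effects = models$models[[i]]$effects, bic = models$bic[i]))

  report <- list(
    cohort_summary = list(
      n = nrow(cohort),
      deaths = sum(cohort[[cfg$outcome]], na.rm = TRUE),
      biomarker_median = summarize_biomarker(cohort[[cfg$biomarker]])$median),
    ledger = ledger$records,
    best = best_report,
    survival = surv_report,
    models = model_report,
    config = cfg, seed = cfg$seed,
    version = as.character(utils::packageVersion("riskscan")))

  if (!is.null(cfg$out_dir)) {
    dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
    write_cohort_table(cohort, file.path(cfg$out_dir, "cohort.csv"))
    write_ledger_tsv(ledger, file.path(cfg$out_dir, "ledger.tsv"))
    jsonlite::write_json(report, file.path(cfg$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE, force = TRUE)
  }
  report
}
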