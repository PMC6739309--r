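#' Construct a cohort table
#'
#' A cohort table holds one row per subject: a unique `subject_id`, a binary
#' `outcome` (1 = died), optional right-censored survival information
#' (`time` in days and an `event` indicator), and one column per biomarker
#' (nonnegative concentrations; `NA` marks an explicitly missing measurement).
#' Units are carried as metadata only and never converted.
#'
#' @param data data.frame with at least `subject_id` and `outcome` columns.
#' @param biomarkers character vector naming the biomarker columns in `data`.
#' @param units optional named character vector of units per biomarker
#'   (metadata only).
#' @return An object of class `cohort_table` (a validated data.frame).
#' @export
cohort_table <- function(data, biomarkers = character(), units = NULL) {
  stopifnot(is.data.frame(data))
  data <- as.data.frame(data, stringsAsFactors = FALSE)
  if (!"subject_id" %in% names(data))
    stop("cohort is missing mandatory column 'subject_id'", call. = FALSE)
  if (!"outcome" %in% names(data))
    stop("cohort is missing mandatory column 'outcome'", call. = FALSE)
  missing_bm <- setdiff(biomarkers, names(data))
  if (length(missing_bm))
    stop("cohort is missing biomarker column(s): ",
         paste(missing_bm, collapse = ", "), call. = FALSE)
  data$subject_id <- as.character(data$subject_id)
  if (anyDuplicated(data$subject_id))
    stop("duplicate subject_id: ",
         paste(unique(data$subject_id[duplicated(data$subject_id)]),
               collapse = ", "), call. = FALSE)
  oc <- data$outcome
  if (!all(is.na(oc) | oc %in% c(0, 1)))
    stop("outcome must be 0/1", call. = FALSE)
  if ("time" %in% names(data) && !"event" %in% names(data))
    stop("column 'time' present without companion column 'event'",
         call. = FALSE)
  if ("time" %in% names(data)) {
    if (any(data$time < 0, na.rm = TRUE))
      stop("survival times must be nonnegative", call. = FALSE)
    if (!all(is.na(data$event) | data$event %in% c(0, 1)))
      stop("event indicator must be 0/1", call. = FALSE)
  }
  for (bm in biomarkers) {
    v <- data[[bm]]
    if (!is.numeric(v))
      stop("biomarker '", bm, "' is not numeric", call. = FALSE)
    bad <- which(!is.na(v) & (!is.finite(v) | v < 0))
    if (length(bad))
      stop("biomarker '", bm, "' has non-finite or negative value at row ",
           bad[1], call. = FALSE)
  }
  structure(data,
            biomarkers = biomarkers,
            units = units,
            class = c("cohort_table", "data.frame"))
}

#' Biomarker columns of a cohort table
#' @param cohort a `cohort_table`.
#' @return Character vector of biomarker column names.
#' @export
biomarker_names <- function(cohort) attr(cohort, "biomarkers")

#' @export
print.cohort_table <- function(x, ...) {
  cat(sprintf("<cohort_table> %d subjects, %d biomarker(s): %s\n",
              nrow(x), length(biomarker_names(x)),
              paste(biomarker_names(x), collapse = ", ")))
  cat(sprintf("  deaths: %d/%d; survival columns: %s\n",
              sum(x$outcome, na.rm = TRUE), nrow(x),
              if ("time" %in% names(x)) "time/event" else "absent"))
  invisible(x)
}

default_schema <- function() {
  list(subject_id = "subject_id", outcome = "outcome",
       time = "time", event = "event", biomarkers = NULL)
}

#' Read a cohort table from CSV/TSV
#'
#' Reads a delimited file with a header row and validates it into a
#' [cohort_table()]. The delimiter is taken from the file extension
#' (`.tsv`/`.tab` = tab, otherwise comma). Empty cells become missing
#' values, never zeros.
#'
#' @param path file to read.
#' @param schema column mapping: a list with elements `subject_id`,
#'   `outcome`, optionally `time` and `event` (source column names), and
#'   `biomarkers`, a named character vector/list mapping biomarker name to
#'   source column. `biomarkers = NULL` treats every unmapped numeric column
#'   as a biomarker under its own name.
#' @return A `cohort_table`.
#' @export
read_cohort_table <- function(path, schema = default_schema()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           na.strings = c("", "NA"), colClasses = "character")
  sch <- utils::modifyList(default_schema(), schema)
  need <- c(subject_id = sch$subject_id, outcome = sch$outcome)
  for (nm in names(need))
    if (!need[[nm]] %in% names(raw))
      stop("input lacks mandatory column '", need[[nm]], "' (", nm, ")",
           call. = FALSE)
  bm_map <- sch$biomarkers
  if (is.null(bm_map)) {
    taken <- unlist(sch[c("subject_id", "outcome", "time", "event")])
    cand <- setdiff(names(raw), taken)
    bm_map <- stats::setNames(cand, cand)
  } else {
    bm_map <- unlist(bm_map)
    absent <- setdiff(bm_map, names(raw))
    if (length(absent))
      stop("input lacks biomarker column(s): ",
           paste(absent, collapse = ", "), call. = FALSE)
  }
  parse_num <- function(col, label) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad))
      stop("non-numeric value in column '", label, "' at data row ", bad[1],
           call. = FALSE)
    v
  }
  out <- data.frame(subject_id = raw[[sch$subject_id]],
                    outcome = parse_num(sch$outcome, "outcome"),
                    stringsAsFactors = FALSE)
  if (!is.null(sch$time) && sch$time %in% names(raw)) {
    out$time <- parse_num(sch$time, "time")
    if (!is.null(sch$event) && sch$event %in% names(raw))
      out$event <- parse_num(sch$event, "event")
  }
  for (nm in names(bm_map)) out[[nm]] <- parse_num(bm_map[[nm]], nm)
  cohort_table(out, biomarkers = names(bm_map))
}

#' Write a cohort table to CSV
#'
#' Writes a header CSV; missing values are written as empty cells so the file
#' round-trips through [read_cohort_table()] unchanged.
#'
#' @param cohort a `cohort_table`.
#' @param path destination file.
#' @return Invisibly, `path`.
#' @export
write_cohort_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cohort_table"))
  ok <- tryCatch({
    utils::write.csv(as.data.frame(cohort), path, row.names = FALSE, na = "")
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok))
    stop("cannot write cohort to '", path, "': ",
         conditionMessage(ok), call. = FALSE)
  invisible(path)
}

#' Dichotomize a cohort at a biomarker threshold
#'
#' Splits subjects into a high group (`value >= tau`; ties at the threshold
#' go high, matching the ">= cut-off" group definition) and a low group
#' (`value < tau`). Subjects with a missing biomarker value are excluded and
#' counted, never imputed.
#'
#' @param cohort a `cohort_table`.
#' @param biomarker biomarker column name.
#' @param tau threshold on the concentration scale.
#' @return An object of class `dichotomized_cohort`: list with `threshold`,
#'   `biomarker`, `high_ids`, `low_ids`, `n_missing`.
#' @export
dichotomize_by_threshold <- function(cohort, biomarker, tau) {
  stopifnot(inherits(cohort, "cohort_table"))
  if (!biomarker %in% biomarker_names(cohort))
    stop("unknown biomarker '", biomarker, "'", call. = FALSE)
  v <- cohort[[biomarker]]
  if (all(is.na(v)))
    stop("all values of '", biomarker, "' are missing", call. = FALSE)
  keep <- !is.na(v)
  structure(list(threshold = tau,
                 biomarker = biomarker,
                 high_ids = cohort$subject_id[keep & v >= tau],
                 low_ids = cohort$subject_id[keep & v < tau],
                 n_missing = sum(!keep)),
            class = "dichotomized_cohort")
}

#' @export
print.dichotomized_cohort <- function(x, ...) {
  cat(sprintf("<dichotomized_cohort> %s >= %g: high n=%d, low n=%d, missing %d\n",
              x$biomarker, x$threshold, length(x$high_ids), length(x$low_ids),
              x$n_missing))
  invisible(x)
}

#' Summarize a biomarker distribution
#'
#' Median uses the midpoint-of-middle-two convention; quartiles use linear
#' interpolation (R quantile type 7) and IQR = Q3 - Q1.
#'
#' @param values numeric vector of concentrations (may contain `NA`).
#' @return List with `n`, `n_missing`, `median`, `q1`, `q3`, `iqr`.
#' @export
summarize_biomarker <- function(values) {
  n_missing <- sum(is.na(values))
  v <- values[!is.na(values)]
  if (!length(v)) stop("no non-missing values to summarize", call. = FALSE)
  q <- stats::quantile(v, c(0.25, 0.75), names = FALSE, type = 7)
  list(n = length(v), n_missing = n_missing,
       median = stats::median(v), q1 = q[1], q3 = q[2], iqr = q[2] - q[1])
}
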