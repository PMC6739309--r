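# Set-overlap summaries for differential-expression signatures (Venn
# arithmetic on gene-identifier lists).

#' Construct a gene set
#'
#' Identifiers are trimmed, upper-cased and de-duplicated; no alias
#' resolution is attempted.
#'
#' @param name label for the set.
#' @param members character vector of gene identifiers.
#' @return Object of class `gene_set`.
#' @export
gene_set <- function(name, members) {
  m <- unique(toupper(trimws(as.character(members))))
  m <- m[nzchar(m)]
  structure(list(name = name, members = m), class = "gene_set")
}

#' Read a newline-delimited gene list
#'
#' @param path file with one identifier per line.
#' @param name set label (defaults to the file name).
#' @return A [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  gene_set(name, readLines(path, warn = FALSE))
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s: %d identifier(s)\n", x$name,
              length(x$members)))
  invisible(x)
}

#' Overlap summary of two gene sets
#'
#' Exact set arithmetic: sizes, intersection, shared fractions (undefined —
#' `NA` — for an empty set, never 0) and unique counts.
#'
#' @param a,b [gene_set()] objects.
#' @return Object of class `overlap_summary` with fields `size_a`, `size_b`,
#'   `intersection`, `fraction_of_a`, `fraction_of_b`, `unique_a`,
#'   `unique_b`.
#' @export
overlap_summary <- function(a, b) {
  stopifnot(inherits(a, "gene_set"), inherits(b, "gene_set"))
  inter <- length(intersect(a$members, b$members))
  na <- length(a$members); nb <- length(b$members)
  structure(list(name_a = a$name, name_b = b$name,
                 size_a = na, size_b = nb, intersection = inter,
                 fraction_of_a = if (na) inter / na else NA_real_,
                 fraction_of_b = if (nb) inter / nb else NA_real_,
                 unique_a = na - inter, unique_b = nb - inter),
            class = "overlap_summary")
}

#' @export
print.overlap_summary <- function(x, ...) {
  fmt <- function(f) if (is.na(f)) "undefined" else sprintf("%.1f%%",
                                                            100 * f)
  cat(sprintf("<overlap_summary> |%s|=%d, |%s|=%d, shared %d (%s of %s, %s of %s)\n",
              x$name_a, x$size_a, x$name_b, x$size_b, x$intersection,
              fmt(x$fraction_of_a), x$name_a, fmt(x$fraction_of_b),
              x$name_b))
  invisible(x)
}
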