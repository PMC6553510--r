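`%||%` <- function(x, y) if (is.null(x)) y else x

stop_advcomm <- function(fmt, ..., class) {
  stop(errorCondition(sprintf(fmt, ...), class = c(class, "advcomm_error")))
}

parse_error <- function(path, line, fmt, ...) {
  stop_advcomm("%s:%d: %s", path, line, sprintf(fmt, ...),
               class = "advcomm_parse_error")
}

# counts accepted as base matrix or any Matrix class; standardize to dgCMatrix
as_count_matrix <- function(x) {
  if (is.matrix(x)) x <- as(as(as(x, "dMatrix"), "generalMatrix"), "CsparseMatrix")
  if (!methods::is(x, "CsparseMatrix"))
    x <- as(as(x, "generalMatrix"), "CsparseMatrix")
  x
}

validate_counts <- function(counts, what = "count matrix") {
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop_advcomm("%s must carry gene symbols as rownames and cell barcodes as colnames",
                 what, class = "advcomm_validation_error")
  if (anyDuplicated(rownames(counts)))
    stop_advcomm("%s has duplicated gene symbols (e.g. '%s')", what,
                 rownames(counts)[anyDuplicated(rownames(counts))],
                 class = "advcomm_validation_error")
  if (anyDuplicated(colnames(counts)))
    stop_advcomm("%s has duplicated cell barcodes (e.g. '%s')", what,
                 colnames(counts)[anyDuplicated(colnames(counts))],
                 class = "advcomm_validation_error")
  v <- counts@x
  if (length(v) && (any(v < 0) || any(v != floor(v))))
    stop_advcomm("%s contains negative or non-integer counts", what,
                 class = "advcomm_validation_error")
  invisible(counts)
}

assert_scalar_number <- function(x, name, min = -Inf, max = Inf,
                                 integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max ||
      (integer && x != floor(x)))
    stop_advcomm("'%s' must be a single %s in [%s, %s]", name,
                 if (integer) "integer" else "number", format(min), format(max),
                 class = "advcomm_validation_error")
  invisible(x)
}

# full-precision numeric formatting so written TSV round-trips exactly
format_full <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}
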