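#' Write cross-talk outputs to a directory
#'
#' Writes `interaction_matrix.tsv` (labeled cell-type-by-cell-type TSV),
#' `pair_scores.tsv` (one row per pair and ordered type pair), and
#' `chord.json` (link list plus per-type ligand/receptor contribution totals).
#' Numeric cells are written at full precision so re-reading reproduces the
#' values exactly.
#'
#' @param matrix Interaction matrix from [mean_interaction_matrix()], or `NULL`.
#' @param pair_table Table from [pair_interaction_scores()], or `NULL`.
#' @param chord Object from [chord_data()], or `NULL`.
#' @param outdir Output directory, created if missing.
#' @return Invisibly, the paths written.
#' @export
write_interaction_outputs <- function(matrix = NULL, pair_table = NULL,
                                      chord = NULL, outdir) {
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop_advcomm("cannot create output directory %s", outdir,
                 class = "advcomm_io_error")
  paths <- character()
  if (!is.null(matrix)) {
    p <- file.path(outdir, "interaction_matrix.tsv")
    write_matrix_tsv(matrix, p)
    paths <- c(paths, p)
  }
  if (!is.null(pair_table)) {
    p <- file.path(outdir, "pair_scores.tsv")
    write_table_tsv(pair_table, p)
    paths <- c(paths, p)
  }
  if (!is.null(chord)) {
    p <- file.path(outdir, "chord.json")
    jsonlite::write_json(
      list(links = chord$links, totals = chord$totals),
      p, dataframe = "rows", digits = NA, pretty = TRUE)
    paths <- c(paths, p)
  }
  invisible(paths)
}

write_matrix_tsv <- function(m, path) {
  df <- as.data.frame(apply(m, 2L, format_full), stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (nrow(m) == 1L) df <- as.data.frame(t(df), check.names = FALSE)
  df <- cbind(cell_type = rownames(m), df)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

write_table_tsv <- function(tab, path) {
  out <- tab
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_full(out[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read back a labeled interaction matrix TSV
#'
#' Inverse of the matrix writer in [write_interaction_outputs()]; values are
#' recovered at full precision.
#'
#' @param path Path to `interaction_matrix.tsv`.
#' @return A numeric matrix with cell-type row and column names.
#' @export
read_interaction_matrix <- function(path) {
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  m <- as.matrix(tab[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab[[1L]]
  m
}
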