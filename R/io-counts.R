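#' Read a genes-by-cells count matrix
#'
#' Reads raw integer counts either from a matrix-market triplet file with
#' `features.tsv` / `barcodes.tsv` sidecars (the 10x-style on-disk layout) or
#' from a dense TSV whose first column holds gene symbols and whose header row
#' holds cell barcodes. Validation happens at read time: gene symbols and
#' barcodes must be unique, counts non-negative integers, and triplet indices
#' in bounds. Malformed input raises a parse error naming the offending line.
#'
#' Triplet bodies use 1-based indices as in the matrix-market standard; they
#' are converted to the in-memory sparse representation internally.
#'
#' @param path Path to the `.mtx` or dense `.tsv` file.
#' @param dialect `"auto"` (by extension), `"triplet-mtx"`, or `"dense-tsv"`.
#' @param features,barcodes Sidecar paths for the triplet dialect. Default:
#'   `features.tsv` (or `genes.tsv`) and `barcodes.tsv` next to `path`.
#' @param case_fold If `TRUE`, gene symbols are lower-cased before the
#'   uniqueness check and all downstream matching. Default `FALSE`: mouse
#'   symbols are conventionally mixed-case and silent folding can merge
#'   distinct symbols.
#' @return A `dgCMatrix` of counts, genes in rows (rownames = symbols),
#'   cells in columns (colnames = barcodes), order as on disk.
#' @export
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("gene\tc1\tc2", "Ccl2\t0\t1", "Ccr2\t2\t0", "Actb\t5\t5"), tsv)
#' m <- read_counts(tsv)
#' sum(m)  # 13
read_counts <- function(path,
                        dialect = c("auto", "triplet-mtx", "dense-tsv"),
                        features = NULL, barcodes = NULL,
                        case_fold = FALSE) {
  dialect <- match.arg(dialect)
  if (!file.exists(path))
    stop_advcomm("count file not found: %s", path, class = "advcomm_io_error")
  if (dialect == "auto")
    dialect <- if (grepl("\\.mtx$", path, ignore.case = TRUE))
      "triplet-mtx" else "dense-tsv"
  counts <- if (dialect == "triplet-mtx")
    read_counts_mtx(path, features, barcodes)
  else
    read_counts_dense(path)
  if (case_fold) rownames(counts) <- tolower(rownames(counts))
  validate_counts(counts, what = path)
  counts
}

read_counts_mtx <- function(path, features, barcodes) {
  lines <- readLines(path)
  if (!length(lines))
    parse_error(path, 1L, "empty matrix file")
  if (!grepl("^%%MatrixMarket\\s+matrix\\s+coordinate\\s+(integer|real)\\s+general\\s*$",
             lines[[1L]]))
    parse_error(path, 1L,
                "malformed matrix-market header: '%s'", lines[[1L]])
  body_at <- which(!startsWith(lines, "%"))
  if (!length(body_at))
    parse_error(path, length(lines), "no dimension line found")
  dim_line <- body_at[[1L]]
  dims <- strsplit(trimws(lines[[dim_line]]), "\\s+")[[1L]]
  dims_n <- suppressWarnings(as.numeric(dims))
  if (length(dims) != 3L || anyNA(dims_n) || any(dims_n != floor(dims_n)))
    parse_error(path, dim_line, "dimension line must hold three integers, got '%s'",
                lines[[dim_line]])
  n_genes <- dims_n[[1L]]; n_cells <- dims_n[[2L]]; n_entries <- dims_n[[3L]]
  entry_at <- body_at[-1L]
  entry_at <- entry_at[nzchar(trimws(lines[entry_at]))]
  if (length(entry_at) != n_entries)
    parse_error(path, dim_line, "header declares %d entries but file has %d",
                n_entries, length(entry_at))
  i <- integer(n_entries); j <- integer(n_entries); x <- numeric(n_entries)
  for (k in seq_along(entry_at)) {
    ln <- entry_at[[k]]
    f <- suppressWarnings(as.numeric(strsplit(trimws(lines[[ln]]), "\\s+")[[1L]]))
    if (length(f) != 3L || anyNA(f))
      parse_error(path, ln, "expected 'gene cell count', got '%s'", lines[[ln]])
    if (f[[3L]] != floor(f[[3L]]) || f[[3L]] < 0)
      parse_error(path, ln, "non-integer or negative count %s", format(f[[3L]]))
    if (f[[1L]] < 1 || f[[1L]] > n_genes || f[[2L]] < 1 || f[[2L]] > n_cells)
      parse_error(path, ln,
                  "index (%d, %d) outside declared %d x %d matrix",
                  f[[1L]], f[[2L]], n_genes, n_cells)
    i[[k]] <- f[[1L]]; j[[k]] <- f[[2L]]; x[[k]] <- f[[3L]]
  }
  features <- features %||% existing_sidecar(path, c("features.tsv", "genes.tsv"))
  barcodes <- barcodes %||% existing_sidecar(path, "barcodes.tsv")
  genes <- read_sidecar(features)
  cells <- read_sidecar(barcodes)
  if (length(genes) != n_genes)
    parse_error(features, length(genes),
                "features sidecar has %d rows but matrix declares %d genes",
                length(genes), n_genes)
  if (length(cells) != n_cells)
    parse_error(barcodes, length(cells),
                "barcodes sidecar has %d rows but matrix declares %d cells",
                length(cells), n_cells)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n_genes, n_cells),
                       dimnames = list(genes, cells))
}

existing_sidecar <- function(mtx_path, names) {
  cand <- file.path(dirname(mtx_path), names)
  hit <- cand[file.exists(cand)]
  if (!length(hit))
    stop_advcomm("sidecar file (%s) not found alongside %s",
                 paste(names, collapse = " or "), mtx_path,
                 class = "advcomm_io_error")
  hit[[1L]]
}

read_sidecar <- function(path) {
  if (!file.exists(path))
    stop_advcomm("sidecar file not found: %s", path, class = "advcomm_io_error")
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (!nrow(tab)) parse_error(path, 1L, "empty sidecar file")
  # 10x features.tsv may carry id, symbol, type; use the symbol column if present
  if (ncol(tab) >= 2L) tab[[2L]] else tab[[1L]]
}

read_counts_dense <- function(path) {
  first <- readLines(path, n = 1L)
  if (!length(first) || !nzchar(trimws(first)))
    parse_error(path, 1L, "empty matrix file")
  tab <- read.delim(path, header = TRUE, check.names = FALSE,
                    colClasses = "character")
  if (!nrow(tab) || ncol(tab) < 2L)
    parse_error(path, 1L, "dense matrix needs a gene column plus >= 1 cell column")
  genes <- tab[[1L]]
  vals <- as.matrix(tab[, -1L, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(vals), nrow = nrow(vals)))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0L)[[1L]]
    parse_error(path, bad + 1L, "non-numeric count in row for gene '%s'",
                genes[[bad]])
  }
  if (any(num < 0) || any(num != floor(num))) {
    bad <- which(rowSums(num < 0 | num != floor(num)) > 0L)[[1L]]
    parse_error(path, bad + 1L, "negative or non-integer count for gene '%s'",
                genes[[bad]])
  }
  dimnames(num) <- list(genes, colnames(tab)[-1L])
  as_count_matrix(num)
}

#' Read a per-cell annotation table
#'
#' TSV with columns `barcode`, `cluster`, `genotype` (a header row with those
#' names is recognized; otherwise the first three columns are taken in that
#' order). Barcodes must be unique and labels non-empty.
#'
#' @param path Path to the TSV file.
#' @return A `data.frame` with character columns `barcode`, `cluster`,
#'   `genotype`.
#' @export
read_cell_annotation <- function(path) {
  if (!file.exists(path))
    stop_advcomm("annotation file not found: %s", path,
                 class = "advcomm_io_error")
  tab <- read.delim(path, header = FALSE, colClasses = "character")
  if (!nrow(tab) || ncol(tab) < 3L)
    parse_error(path, 1L, "annotation needs columns barcode, cluster, genotype")
  header <- tolower(trimws(unname(unlist(tab[1L, 1:3]))))
  if (identical(header, c("barcode", "cluster", "genotype")))
    tab <- tab[-1L, , drop = FALSE]
  if (!nrow(tab)) parse_error(path, 2L, "annotation has a header but no rows")
  ann <- data.frame(barcode = trimws(tab[[1L]]), cluster = trimws(tab[[2L]]),
                    genotype = trimws(tab[[3L]]), stringsAsFactors = FALSE)
  validate_annotation(ann, what = path)
  ann
}

validate_annotation <- function(ann, what = "annotation") {
  need <- c("barcode", "cluster", "genotype")
  if (!all(need %in% names(ann)))
    stop_advcomm("%s must have columns %s", what, paste(need, collapse = ", "),
                 class = "advcomm_validation_error")
  if (anyDuplicated(ann$barcode))
    stop_advcomm("%s: barcode '%s' annotated more than once", what,
                 ann$barcode[anyDuplicated(ann$barcode)],
                 class = "advcomm_validation_error")
  if (any(!nzchar(ann$cluster)) || any(!nzchar(ann$genotype)))
    stop_advcomm("%s: empty cluster or genotype label", what,
                 class = "advcomm_validation_error")
  invisible(ann)
}
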