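#' Cell-level quality-control thresholds
#'
#' Cells are retained when the number of detected genes lies in
#' `[min_genes, max_genes]` (inclusive: the filter removes cells expressing
#' fewer than `min_genes` or more than `max_genes` genes) and the
#' mitochondrial count fraction is at most `max_mito_fraction` (the filter
#' removes strictly greater). Mitochondrial genes are identified by a symbol
#' prefix, `"mt-"` by mouse convention.
#'
#' @param min_genes,max_genes Inclusive bounds on detected genes per cell.
#' @param max_mito_fraction Maximum tolerated mitochondrial count fraction.
#' @param mito_prefix Gene-symbol prefix marking mitochondrial genes.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_genes = 200L, max_genes = 2500L,
                          max_mito_fraction = 0.05, mito_prefix = "mt-") {
  assert_scalar_number(min_genes, "min_genes", 0, Inf, integer = TRUE)
  assert_scalar_number(max_genes, "max_genes", 0, Inf, integer = TRUE)
  if (min_genes >= max_genes)
    stop_advcomm("min_genes must be < max_genes",
                 class = "advcomm_validation_error")
  assert_scalar_number(max_mito_fraction, "max_mito_fraction", 0, 1)
  structure(list(min_genes = as.integer(min_genes),
                 max_genes = as.integer(max_genes),
                 max_mito_fraction = max_mito_fraction,
                 mito_prefix = mito_prefix),
            class = "qc_thresholds")
}

#' Filter cells on detected-gene and mitochondrial-fraction rules
#'
#' Applies the gene-count window and the mitochondrial-fraction cutoff jointly
#' in one pass (the rules are conjunctive, so order cannot change the result).
#' Boundary semantics are literal: exactly `min_genes` or `max_genes`
#' detected genes is retained, and a mitochondrial fraction exactly equal to
#' `max_mito_fraction` is retained. Idempotent: filtering an already-filtered
#' matrix removes nothing.
#'
#' @param counts Genes-by-cells count matrix (dense or sparse) with dimnames.
#' @param thresholds A [qc_thresholds()].
#' @return List with `counts` (the retained columns) and `report`, a
#'   `data.frame(barcode, n_genes, mito_fraction, removed_by)` over all input
#'   cells; `removed_by` is `""` for retained cells, otherwise a
#'   comma-joined subset of `low_gene`, `high_gene`, `high_mito`.
#' @export
filter_cells <- function(counts, thresholds = qc_thresholds()) {
  counts <- as_count_matrix(counts)
  validate_counts(counts)
  if (!inherits(thresholds, "qc_thresholds"))
    stop_advcomm("'thresholds' must come from qc_thresholds()",
                 class = "advcomm_validation_error")
  n_genes <- Matrix::colSums(counts > 0)
  total <- Matrix::colSums(counts)
  mito <- startsWith(rownames(counts), thresholds$mito_prefix)
  mito_frac <- if (any(mito))
    Matrix::colSums(counts[mito, , drop = FALSE]) / total
  else rep(0, ncol(counts))
  mito_frac[total == 0] <- NA_real_
  low <- n_genes < thresholds$min_genes
  high <- n_genes > thresholds$max_genes
  himito <- !is.na(mito_frac) & mito_frac > thresholds$max_mito_fraction
  removed_by <- vapply(seq_len(ncol(counts)), function(i)
    paste(c("low_gene", "high_gene", "high_mito")[c(low[i], high[i], himito[i])],
          collapse = ","), character(1))
  keep <- removed_by == ""
  if (!any(keep))
    stop_advcomm("all %d cells removed by QC; check thresholds", ncol(counts),
                 class = "advcomm_empty_result_error")
  report <- data.frame(barcode = colnames(counts), n_genes = as.integer(n_genes),
                       mito_fraction = as.numeric(mito_frac),
                       removed_by = removed_by, stringsAsFactors = FALSE,
                       row.names = NULL)
  list(counts = counts[, keep, drop = FALSE], report = report)
}

#' Log-normalize a count matrix
#'
#' Per cell, counts are scaled to `scale_factor` total and natural-log
#' transformed: `value(g, i) = ln(1 + scale_factor * count(g, i) / total(i))`.
#' The zero pattern and the within-cell rank order of genes are preserved
#' exactly.
#'
#' @param counts Genes-by-cells count matrix; every cell must have total
#'   count > 0 (run [filter_cells()] first).
#' @param scale_factor Per-cell target total before `log1p`; default 10,000.
#' @return A sparse `dgCMatrix` of normalized values with attribute-free
#'   dimnames matching `counts`.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  counts <- as_count_matrix(counts)
  validate_counts(counts)
  assert_scalar_number(scale_factor, "scale_factor", 1e-12, Inf)
  total <- Matrix::colSums(counts)
  if (any(total == 0))
    stop_advcomm("%d cell(s) have zero total count; apply QC filtering first",
                 sum(total == 0), class = "advcomm_validation_error")
  scaled <- counts %*% Matrix::Diagonal(x = scale_factor / total)
  norm <- scaled
  norm@x <- log1p(scaled@x)
  dimnames(norm) <- dimnames(counts)
  as_count_norm <- as(as(norm, "generalMatrix"), "CsparseMatrix")
  as_count_norm
}

select_control_genes <- function(norm, set_genes, controls_per_gene) {
  all_genes <- rownames(norm)
  mean_expr <- Matrix::rowMeans(norm)
  detect <- Matrix::rowMeans(norm > 0)
  z <- function(v) {
    s <- sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  zx <- z(mean_expr); zy <- z(detect)
  candidates <- setdiff(all_genes, set_genes)
  if (length(candidates) < controls_per_gene * length(set_genes))
    stop_advcomm(
      "need %d control genes outside the set but only %d are available",
      controls_per_gene * length(set_genes), length(candidates),
      class = "advcomm_validation_error")
  taken <- character(0)
  for (g in set_genes) {
    gi <- match(g, all_genes)
    pool <- setdiff(candidates, taken)
    pi <- match(pool, all_genes)
    d <- (zx[pi] - zx[[gi]])^2 + (zy[pi] - zy[[gi]])^2
    ord <- order(d, pi)                      # ties broken by gene order
    taken <- c(taken, pool[ord[seq_len(controls_per_gene)]])
  }
  taken
}

#' Score cells on a gene set against expression-matched controls
#'
#' For an n-gene set, selects `controls_per_gene * n` control genes once (not
#' per cell): gene mean log-expression and detection frequency are
#' standardized to z-scores across genes, and each set gene contributes its
#' `controls_per_gene` nearest non-set, not-yet-chosen genes by Euclidean
#' distance in that plane (ties broken by gene order). The per-cell score is
#' the mean normalized expression of the set genes minus the mean over the
#' pooled controls.
#'
#' @param norm Normalized genes-by-cells matrix from [log_normalize()].
#' @param genes Character vector of set gene symbols; members absent from the
#'   matrix are dropped with a warning, and an empty set after dropping is an
#'   error.
#' @param controls_per_gene Controls selected per set gene (default 10).
#' @return Numeric vector of per-cell scores, named by barcode, with the
#'   selected control genes in attribute `controls`.
#' @export
gene_set_score <- function(norm, genes, controls_per_gene = 10L) {
  assert_scalar_number(controls_per_gene, "controls_per_gene", 1, Inf,
                       integer = TRUE)
  missing <- setdiff(genes, rownames(norm))
  if (length(missing)) {
    warning(length(missing), " set gene(s) absent from the matrix dropped: ",
            paste(head(missing, 5L), collapse = ", "), call. = FALSE)
    genes <- setdiff(genes, missing)
  }
  if (!length(genes))
    stop_advcomm("gene set empty after dropping genes absent from the matrix",
                 class = "advcomm_validation_error")
  controls <- select_control_genes(norm, genes, controls_per_gene)
  score <- Matrix::colMeans(norm[genes, , drop = FALSE]) -
    Matrix::colMeans(norm[controls, , drop = FALSE])
  structure(setNames(as.numeric(score), colnames(norm)), controls = controls)
}

#' G1/S and G2/M cell-cycle scores
#'
#' Matched-control scoring ([gene_set_score()]) of the two cell-cycle phase
#' sets; plotting the two scores in a plane separates cycling from resting
#' cells.
#'
#' @param norm Normalized genes-by-cells matrix.
#' @param g1s_genes,g2m_genes Phase gene sets.
#' @param controls_per_gene Controls per set gene (default 10).
#' @return `data.frame(barcode, g1s_score, g2m_score)`.
#' @export
cycle_scores <- function(norm, g1s_genes, g2m_genes, controls_per_gene = 10L) {
  data.frame(barcode = colnames(norm),
             g1s_score = as.numeric(gene_set_score(norm, g1s_genes,
                                                   controls_per_gene)),
             g2m_score = as.numeric(gene_set_score(norm, g2m_genes,
                                                   controls_per_gene)),
             stringsAsFactors = FALSE)
}
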