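#' Per-cell-type expressing fractions
#'
#' For each cell type C and gene g, computes `f_C(g)`, the fraction of cells
#' of type C with expression strictly above zero. Positivity is invariant
#' under any strictly monotone zero-preserving transform, so raw counts and
#' log-normalized values give identical fractions; both are accepted.
#'
#' @param mat Genes-by-cells matrix, raw counts or normalized values, with
#'   dimnames.
#' @param annotation `data.frame` with columns `barcode` and `cluster` (and
#'   optionally `genotype`); every annotated barcode must be present in
#'   `mat`. Only annotated cells enter the computation.
#' @param genes Genes to tabulate; defaults to all genes in `mat`. Requested
#'   genes absent from the matrix are reported and excluded.
#' @return An `expressing_fractions` object: list with `fraction`
#'   (genes-by-types matrix of fractions), `expressed` (the underlying
#'   positive-cell counts), and `n_cells` (named cell-type sizes).
#' @export
expressing_fractions <- function(mat, annotation, genes = NULL) {
  if (!all(c("barcode", "cluster") %in% names(annotation)))
    stop_advcomm("annotation needs columns barcode and cluster",
                 class = "advcomm_validation_error")
  missing_bc <- setdiff(annotation$barcode, colnames(mat))
  if (length(missing_bc))
    stop_advcomm("%d annotated barcode(s) absent from the matrix (e.g. '%s')",
                 length(missing_bc), missing_bc[[1L]],
                 class = "advcomm_validation_error")
  types <- if (is.factor(annotation$cluster)) levels(annotation$cluster)
           else unique(annotation$cluster)
  sizes <- table(factor(annotation$cluster, levels = types))
  if (any(sizes == 0))
    stop_advcomm("cell type '%s' has no cells",
                 names(sizes)[sizes == 0][[1L]],
                 class = "advcomm_empty_result_error")
  genes <- genes %||% rownames(mat)
  absent <- setdiff(genes, rownames(mat))
  if (length(absent)) {
    message(length(absent), " requested gene(s) not detected in the matrix; excluded")
    genes <- setdiff(genes, absent)
  }
  if (!length(genes))
    stop_advcomm("no requested gene present in the matrix",
                 class = "advcomm_validation_error")
  pos <- mat[genes, annotation$barcode, drop = FALSE] > 0
  expressed <- vapply(types, function(t)
    Matrix::rowSums(pos[, annotation$cluster == t, drop = FALSE]),
    numeric(length(genes)))
  expressed <- matrix(expressed, nrow = length(genes),
                      dimnames = list(genes, types))
  n_cells <- setNames(as.integer(sizes), types)
  structure(list(fraction = sweep(expressed, 2L, n_cells, `/`),
                 expressed = expressed, n_cells = n_cells),
            class = "expressing_fractions")
}

#' @export
print.expressing_fractions <- function(x, ...) {
  cat("expressing fractions:", nrow(x$fraction), "genes x",
      length(x$n_cells), "cell types (",
      paste0(names(x$n_cells), "=", x$n_cells, collapse = ", "), ")\n")
  invisible(x)
}

# intersect pair list with the genes a fraction table covers; optional
# gene-set restriction ("both": ligand and receptor in the set; "either")
intersect_pairs <- function(fractions, pairs, restrict_to = NULL,
                            restrict_mode = c("both", "either")) {
  restrict_mode <- match.arg(restrict_mode)
  genes <- rownames(fractions$fraction)
  keep <- pairs$ligand %in% genes & pairs$receptor %in% genes
  if (any(!keep))
    message(sum(!keep), " pair(s) dropped: ligand or receptor not detected")
  pairs <- pairs[keep, , drop = FALSE]
  if (!is.null(restrict_to)) {
    keep <- if (restrict_mode == "both")
      pairs$ligand %in% restrict_to & pairs$receptor %in% restrict_to
    else pairs$ligand %in% restrict_to | pairs$receptor %in% restrict_to
    pairs <- pairs[keep, , drop = FALSE]
  }
  if (!nrow(pairs))
    stop_advcomm("empty ligand-receptor pair universe after intersection%s",
                 if (is.null(restrict_to)) "" else " and gene-set restriction",
                 class = "advcomm_empty_result_error")
  pairs
}

#' Mean ligand-receptor interaction numbers between cell types
#'
#' The mean interaction number for ordered cell types (A, B) is the number of
#' (pair, A-cell, B-cell) triples in which the ligand gene is detected in the
#' A-cell and the receptor gene in the B-cell, divided by `|A| * |B|`.
#' Algebraically this equals the sum over pairs of
#' `f_A(ligand) * f_B(receptor)`; the implementation sums the integer
#' positive-cell count products and divides once, so the result is exact.
#' Rows index the ligand cell type, columns the receptor cell type.
#'
#' @param fractions An [expressing_fractions()] object.
#' @param pairs Ligand-receptor pair `data.frame`; pairs whose genes are not
#'   covered are dropped with a message.
#' @param restrict_to Optional character vector of gene symbols (e.g. an
#'   inflammatory-response set); with `restrict_mode = "both"` (default) a
#'   pair is kept only when ligand and receptor are both members, with
#'   `"either"` when at least one is.
#' @param restrict_mode `"both"` or `"either"`.
#' @return Numeric cell-type-by-cell-type matrix with attributes `n_pairs`
#'   (pair universe size used) and `n_cells`.
#' @export
mean_interaction_matrix <- function(fractions, pairs, restrict_to = NULL,
                                    restrict_mode = c("both", "either")) {
  pairs <- intersect_pairs(fractions, pairs, restrict_to, restrict_mode)
  K <- fractions$expressed
  n <- fractions$n_cells
  num <- t(K[pairs$ligand, , drop = FALSE]) %*% K[pairs$receptor, , drop = FALSE]
  M <- num / outer(n, n)
  dimnames(M) <- list(names(n), names(n))
  attr(M, "n_pairs") <- nrow(pairs)
  attr(M, "n_cells") <- n
  M
}

#' Per-pair interaction scores between cell types
#'
#' The interaction score of pair p for ordered cell types (A, B) is the
#' number of (A-cell, B-cell) couples with ligand and receptor both detected,
#' divided by `|A| * |B|` — i.e. `f_A(ligand_p) * f_B(receptor_p)`. Summing
#' the scores over all pairs reproduces the mean interaction number exactly.
#'
#' @inheritParams mean_interaction_matrix
#' @param types Cell types to include (ordered pairs over these, self-pairs
#'   included); default all types in `fractions`. Unknown types are an error.
#' @return `data.frame(ligand, receptor, ligand_type, receptor_type,
#'   ligand_fraction, receptor_fraction, score)`.
#' @export
pair_interaction_scores <- function(fractions, pairs, types = NULL) {
  pairs <- intersect_pairs(fractions, pairs)
  all_types <- names(fractions$n_cells)
  types <- types %||% all_types
  if (length(bad <- setdiff(types, all_types)))
    stop_advcomm("unknown cell type(s): %s", paste(bad, collapse = ", "),
                 class = "advcomm_validation_error")
  K <- fractions$expressed
  n <- fractions$n_cells
  grid <- expand.grid(receptor_type = types, ligand_type = types,
                      pair = seq_len(nrow(pairs)), stringsAsFactors = FALSE)
  lig <- pairs$ligand[grid$pair]; rec <- pairs$receptor[grid$pair]
  kA <- K[cbind(lig, grid$ligand_type)]
  kB <- K[cbind(rec, grid$receptor_type)]
  nA <- n[grid$ligand_type]; nB <- n[grid$receptor_type]
  data.frame(ligand = lig, receptor = rec,
             ligand_type = grid$ligand_type,
             receptor_type = grid$receptor_type,
             ligand_fraction = kA / nA, receptor_fraction = kB / nB,
             score = (kA * kB) / (nA * nB),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Top-ranked ligand-receptor interactions
#'
#' Sorts a pair-interaction table by score, descending, with a deterministic
#' tie-break: ligand symbol, then receptor symbol, then ligand and receptor
#' cell type (byte-order lexicographic). Returns the first `min(k, nrow)`
#' records.
#'
#' @param table Output of [pair_interaction_scores()].
#' @param k Number of records to return (e.g. 200 for ligand enrichment, 50
#'   for a supplementary-style top list).
#' @return The top records, same columns as `table`.
#' @export
rank_top_pairs <- function(table, k) {
  assert_scalar_number(k, "k", 1, Inf, integer = TRUE)
  ord <- order(-table$score, table$ligand, table$receptor,
               table$ligand_type, table$receptor_type, method = "radix")
  out <- table[ord[seq_len(min(k, nrow(table)))], , drop = FALSE]
  row.names(out) <- NULL
  out
}

#' Chord-diagram data for selected interactions
#'
#' One link per (pair, ligand type, receptor type) record carrying the score
#' and both expressing fractions; link color conventionally encodes the
#' ligand cell type, and a self-link (A to A) depicts interaction within that
#' type. Per-type totals give each type's summed contribution as ligand and
#' as receptor, so band lengths of a circular plot are reconstructible.
#'
#' @param table Output of [pair_interaction_scores()].
#' @param pair_subset Optional restriction: a `data.frame` with `ligand` and
#'   `receptor` columns, or a character vector of `"Ligand-Receptor"` names.
#' @return A `chord_data` list with `links` and `totals` data frames.
#' @export
chord_data <- function(table, pair_subset = NULL) {
  if (!is.null(pair_subset)) {
    want <- if (is.data.frame(pair_subset))
      paste(pair_subset$ligand, pair_subset$receptor, sep = "-")
    else pair_subset
    table <- table[paste(table$ligand, table$receptor, sep = "-") %in% want, ,
                   drop = FALSE]
  }
  if (!nrow(table))
    stop_advcomm("no interaction records left after pair subsetting",
                 class = "advcomm_empty_result_error")
  links <- data.frame(ligand_type = table$ligand_type,
                      receptor_type = table$receptor_type,
                      pair = paste(table$ligand, table$receptor, sep = "-"),
                      score = table$score,
                      ligand_fraction = table$ligand_fraction,
                      receptor_fraction = table$receptor_fraction,
                      stringsAsFactors = FALSE, row.names = NULL)
  types <- sort(unique(c(links$ligand_type, links$receptor_type)))
  totals <- data.frame(
    cell_type = types,
    as_ligand = vapply(types, function(t)
      sum(links$score[links$ligand_type == t]), numeric(1)),
    as_receptor = vapply(types, function(t)
      sum(links$score[links$receptor_type == t]), numeric(1)),
    stringsAsFactors = FALSE, row.names = NULL)
  structure(list(links = links, totals = totals), class = "chord_data")
}

#' Compare interaction matrices between genotypes
#'
#' Element-wise regularized log2 ratio `log2((M_ko + eps) / (M_wt + eps))`
#' between two interaction matrices computed on the same cell types and pair
#' universe; positive entries mean stronger cross-talk in the second
#' (knockout) condition. The default `epsilon` is `1 / (N_wt * N_ko)` — the
#' smallest resolvable score given the two total cell numbers.
#'
#' @param M_wt,M_ko Matrices from [mean_interaction_matrix()] for the two
#'   genotypes; identical row/column labels required.
#' @param epsilon Regularizer; default as above (requires the `n_cells`
#'   attributes the constructor attaches).
#' @return List with `log2_ratio`, `wt`, `ko`, and `epsilon`.
#' @export
compare_genotypes <- function(M_wt, M_ko, epsilon = NULL) {
  if (!identical(dimnames(M_wt), dimnames(M_ko))) {
    mism <- union(setdiff(rownames(M_wt), rownames(M_ko)),
                  setdiff(rownames(M_ko), rownames(M_wt)))
    stop_advcomm("cell-type labels differ between genotypes: %s",
                 paste(if (length(mism)) mism else "(ordering differs)",
                       collapse = ", "),
                 class = "advcomm_validation_error")
  }
  if (is.null(epsilon)) {
    n_wt <- attr(M_wt, "n_cells"); n_ko <- attr(M_ko, "n_cells")
    if (is.null(n_wt) || is.null(n_ko))
      stop_advcomm("matrices carry no n_cells attribute; supply epsilon",
                   class = "advcomm_validation_error")
    epsilon <- 1 / (sum(n_wt) * sum(n_ko))
  }
  assert_scalar_number(epsilon, "epsilon", 1e-300, Inf)
  ratio <- log2((unclass_matrix(M_ko) + epsilon) /
                  (unclass_matrix(M_wt) + epsilon))
  list(log2_ratio = ratio, wt = unclass_matrix(M_wt),
       ko = unclass_matrix(M_ko), epsilon = epsilon)
}

unclass_matrix <- function(m) {
  attr(m, "n_pairs") <- NULL; attr(m, "n_cells") <- NULL
  m
}

#' Downsampling robustness of the interaction matrix
#'
#' Cell-type sizes enter the score only through the denominators, but unequal
#' sizes can still be suspected of driving interaction patterns. This check
#' repeatedly downsamples every cell type, without replacement, to the
#' smallest type's size, recomputes the mean interaction matrix, and returns
#' the across-repeat mean and standard deviation per entry. With equal type
#' sizes every repeat uses all cells and the dispersion is exactly zero.
#'
#' @param mat Genes-by-cells matrix (counts or normalized).
#' @param annotation `data.frame(barcode, cluster, ...)`; every type needs at
#'   least 2 cells.
#' @param pairs Ligand-receptor pair `data.frame`.
#' @param repeats Number of downsampling repeats (>= 1).
#' @param seed Seed making the repeat stream reproducible.
#' @return List with `mean` and `sd` matrices (types x types), `n_per_type`
#'   (the common downsampled size), and `repeats`.
#' @export
downsample_robustness <- function(mat, annotation, pairs, repeats = 100L,
                                  seed = 1L) {
  assert_scalar_number(repeats, "repeats", 1, Inf, integer = TRUE)
  assert_scalar_number(seed, "seed", integer = TRUE)
  sizes <- table(annotation$cluster)
  if (any(sizes < 2L))
    stop_advcomm("cell type '%s' has fewer than 2 cells; downsampling degenerate",
                 names(sizes)[sizes < 2L][[1L]],
                 class = "advcomm_validation_error")
  n_min <- min(sizes)
  genes <- unique(c(pairs$ligand, pairs$receptor))
  genes <- intersect(genes, rownames(mat))
  by_type <- split(annotation$barcode, annotation$cluster)
  set.seed(seed)
  draws <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cells <- unlist(lapply(by_type, function(b) sample(b, n_min)),
                    use.names = FALSE)
    ann <- annotation[match(cells, annotation$barcode), , drop = FALSE]
    fr <- expressing_fractions(mat, ann, genes = genes)
    draws[[r]] <- unclass_matrix(mean_interaction_matrix(fr, pairs))
  }
  a <- array(unlist(draws), dim = c(dim(draws[[1L]]), repeats))
  m <- apply(a, c(1L, 2L), mean)
  # identical draws (equal type sizes) must yield dispersion exactly zero
  s <- apply(a, c(1L, 2L), function(x)
    if (max(x) == min(x)) 0 else sd(x))
  if (repeats == 1L) s[] <- NA_real_
  dimnames(m) <- dimnames(s) <- dimnames(draws[[1L]])
  list(mean = m, sd = s, n_per_type = as.integer(n_min),
       repeats = as.integer(repeats))
}
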