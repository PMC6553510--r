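#' Hypergeometric over-representation of a query gene list
#'
#' For each gene set, tests whether the query list overlaps the set more than
#' expected by chance given a detection universe: with universe size N, set
#' size m (after intersection with the universe), query size q and overlap k,
#' the one-sided p-value is the upper hypergeometric tail P(X >= k), and fold
#' enrichment is `(k/q) / (m/N)`. P-values are Benjamini-Hochberg adjusted
#' across sets. Depletion is not tested.
#'
#' A typical query is the ligand list of the top-ranked interactions from
#' [rank_top_pairs()]; the recommended universe is all genes detected in the
#' count matrix, matching the universe the interaction analysis operates in.
#'
#' @param query Character vector of query gene symbols; genes outside the
#'   universe are dropped with a warning, and an empty query after the
#'   intersection is an error.
#' @param sets Named list of gene sets (see [read_gene_sets()]).
#' @param universe Character vector of background gene symbols; deduplicated.
#' @return `data.frame(set, overlap, query_size, set_size, universe_size,
#'   fold_enrichment, p_value, q_value)`, ordered by p-value.
#' @export
#' @examples
#' overrepresentation(paste0("g", 1:5),
#'                    list(s = paste0("g", 1:5)), paste0("g", 1:20))
overrepresentation <- function(query, sets, universe) {
  universe <- unique(universe)
  if (!length(universe))
    stop_advcomm("empty universe", class = "advcomm_validation_error")
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop_advcomm("'sets' must be a uniquely named list",
                 class = "advcomm_validation_error")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warning(length(outside), " query gene(s) outside the universe dropped: ",
            paste(head(outside, 5L), collapse = ", "), call. = FALSE)
    query <- intersect(query, universe)
  }
  if (!length(query))
    stop_advcomm("query empty after intersection with the universe",
                 class = "advcomm_empty_result_error")
  N <- length(universe); q <- length(query)
  res <- lapply(names(sets), function(nm) {
    members <- intersect(unique(sets[[nm]]), universe)
    m <- length(members)
    k <- length(intersect(query, members))
    data.frame(set = nm, overlap = k, query_size = q, set_size = m,
               universe_size = N,
               fold_enrichment = if (m > 0) (k / q) / (m / N) else NA_real_,
               p_value = phyper(k - 1L, m, N - m, q, lower.tail = FALSE),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q_value <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set, method = "radix"), , drop = FALSE]
  row.names(out) <- NULL
  out
}
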