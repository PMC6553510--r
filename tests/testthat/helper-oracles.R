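# Independent oracles, deliberately naive.

# Literal counting rule: for every pair and every ordered (ligand cell,
# receptor cell) couple, count the triple when both genes are detected, then
# divide by the product of the two type sizes.
oracle_mean_interaction <- function(counts, annotation, pairs) {
  x <- as.matrix(counts)
  types <- unique(annotation$cluster)
  M <- matrix(0, length(types), length(types), dimnames = list(types, types))
  cells_of <- split(annotation$barcode, annotation$cluster)
  for (A in types) for (B in types) {
    total <- 0L
    for (p in seq_len(nrow(pairs))) {
      l <- pairs$ligand[[p]]; r <- pairs$receptor[[p]]
      if (!(l %in% rownames(x)) || !(r %in% rownames(x))) next
      for (i in cells_of[[A]]) for (j in cells_of[[B]])
        if (x[l, i] > 0 && x[r, j] > 0) total <- total + 1L
    }
    M[A, B] <- total / (length(cells_of[[A]]) * length(cells_of[[B]]))
  }
  M
}

# Upper hypergeometric tail by exhaustive enumeration of the mass function.
oracle_hyper_tail <- function(k, m, N, q) {
  js <- k:min(m, q)
  sum(choose(m, js) * choose(N - m, q - js)) / choose(N, q)
}

# Benjamini-Hochberg step-up written from the definition.
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# Small random instance for fuzzing: counts, annotation, pair list.
random_instance <- function(n_cells = sample(4:50, 1), n_genes = sample(3:20, 1),
                            n_pairs = sample(1:10, 1), n_types = sample(2:4, 1)) {
  genes <- sprintf("g%02d", seq_len(n_genes))
  cells <- sprintf("c%02d", seq_len(n_cells))
  counts <- matrix(rbinom(n_genes * n_cells, 4, 0.3), n_genes,
                   dimnames = list(genes, cells))
  cluster <- sample(LETTERS[seq_len(n_types)], n_cells, replace = TRUE)
  # guarantee every type non-empty
  cluster[seq_len(n_types)] <- LETTERS[seq_len(n_types)]
  ann <- data.frame(barcode = cells, cluster = cluster, genotype = "wt",
                    stringsAsFactors = FALSE)
  pairs <- unique(data.frame(ligand = sample(genes, n_pairs, replace = TRUE),
                             receptor = sample(genes, n_pairs, replace = TRUE),
                             stringsAsFactors = FALSE))
  list(counts = counts, annotation = ann, pairs = pairs)
}
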