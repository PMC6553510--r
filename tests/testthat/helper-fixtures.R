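# File fixtures are written to tempdirs at test time; nothing binary ships.

write_dense_fixture <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "counts.tsv")
  writeLines(c("gene\tcell1\tcell2",
               "Ccl2\t0\t1", "Ccr2\t2\t0", "Actb\t5\t5"), path)
  path
}

write_mtx_fixture <- function(counts,
                              dir = withr::local_tempdir(.local_envir = parent.frame())) {
  path <- file.path(dir, "matrix.mtx")
  nz <- which(counts != 0, arr.ind = TRUE)
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               "% synthetic fixture",
               paste(nrow(counts), ncol(counts), nrow(nz)),
               sprintf("%d %d %d", nz[, 1], nz[, 2], counts[nz])), path)
  writeLines(rownames(counts), file.path(dir, "features.tsv"))
  writeLines(colnames(counts), file.path(dir, "barcodes.tsv"))
  path
}

small_counts <- function() {
  matrix(c(0, 1, 2, 0, 5, 5), nrow = 3, byrow = TRUE,
         dimnames = list(c("Ccl2", "Ccr2", "Actb"), c("cell1", "cell2")))
}

# one simulation under the default spec, shared across test files
default_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      spec <- synthetic_spec(
        seed = 1,
        planted_fractions = data.frame(
          genotype = rep(c("wt", "apoe_ko"), each = 4),
          cluster = rep(c("Mesen_II", "Mesen_II", "Mac_inflammatory",
                          "Mac_inflammatory"), 2),
          gene = rep(c("Gene0001", "Gene0002", "Gene0003", "Gene0004"), 2),
          fraction = c(0.6, 0.4, 0.5, 0.3, 0.9, 0.7, 0.8, 0.5)))
      cache <<- c(simulate_adventitia(spec), list(spec = spec))
    }
    cache
  }
})

# cells laid out to sit exactly on and just beyond each QC boundary
boundary_counts <- function() {
  n_genes <- 2600
  genes <- c(sprintf("Gene%04d", seq_len(n_genes - 2)), "mt-Nd1", "mt-Co1")
  cells <- c("at199", "at200", "at2500", "at2501", "mito_at", "mito_over")
  m <- matrix(0, n_genes, length(cells), dimnames = list(genes, cells))
  m[seq_len(199), "at199"] <- 1
  m[seq_len(200), "at200"] <- 1
  m[seq_len(2500), "at2500"] <- 1
  m[seq_len(2501), "at2501"] <- 1
  # mito fraction exactly 0.05: 20 mito counts in a total of 400
  m[seq_len(380), "mito_at"] <- 1
  m["mt-Nd1", "mito_at"] <- 20
  # fraction 21/400 > 0.05
  m[seq_len(379), "mito_over"] <- 1
  m["mt-Nd1", "mito_over"] <- 21
  m
}

planted_pairs <- function() {
  data.frame(ligand = c("Gene0001", "Gene0002"),
             receptor = c("Gene0003", "Gene0004"),
             stringsAsFactors = FALSE)
}
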