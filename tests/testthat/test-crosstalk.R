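unclass_m <- function(m) { attributes(m) <- attributes(m)["dim"]; m }
unclass_m2 <- function(m) { attr(m, "n_pairs") <- NULL; attr(m, "n_cells") <- NULL; m }

four_five <- function() {
  # cluster A: 4 cells, 2 expressing the ligand; cluster B: 5 cells, 3
  # expressing the receptor
  genes <- c("Ccl2", "Ccr2", "Actb")
  cells <- sprintf("c%d", 1:9)
  m <- matrix(0, 3, 9, dimnames = list(genes, cells))
  m["Ccl2", c("c1", "c2")] <- c(3, 1)
  m["Ccr2", c("c5", "c6", "c7")] <- 1
  m["Actb", ] <- 2
  ann <- data.frame(barcode = cells,
                    cluster = rep(c("A", "B"), c(4, 5)),
                    genotype = "wt", stringsAsFactors = FALSE)
  list(counts = m, annotation = ann,
       pairs = data.frame(ligand = "Ccl2", receptor = "Ccr2",
                          stringsAsFactors = FALSE))
}

test_that("expressing fractions are direct positive-cell counts", {
  fx <- four_five()
  fr <- expressing_fractions(fx$counts, fx$annotation)
  expect_equal(fr$fraction["Ccl2", "A"], 0.5)       # 2 of 4
  expect_equal(fr$fraction["Ccr2", "B"], 3 / 5)
  expect_equal(unname(fr$n_cells), c(4L, 5L))
  # an all-zero gene has fraction 0 in every type
  fx$counts["Ccl2", ] <- 0
  fr0 <- expressing_fractions(fx$counts, fx$annotation)
  expect_equal(unname(fr0$fraction["Ccl2", ]), c(0, 0))
})

test_that("fractions are identical on raw counts and log-normalized values", {
  sim <- default_sim()
  qc <- filter_cells(sim$counts)
  ann <- sim$annotation[match(colnames(qc$counts), sim$annotation$barcode), ]
  norm <- log_normalize(qc$counts)
  g <- c("Gene0001", "Gene0002", "Gene0003", "Gene0004", "mt-Nd1")
  fr_raw <- expressing_fractions(qc$counts, ann, genes = g)
  fr_norm <- expressing_fractions(norm, ann, genes = g)
  expect_identical(fr_raw$fraction, fr_norm$fraction)
  expect_identical(fr_raw$expressed, fr_norm$expressed)
})

test_that("annotation preconditions are enforced", {
  fx <- four_five()
  bad <- rbind(fx$annotation,
               data.frame(barcode = "ghost", cluster = "A", genotype = "wt"))
  expect_error(expressing_fractions(fx$counts, bad), "ghost",
               class = "advcomm_validation_error")
  lev <- fx$annotation
  lev$cluster <- factor(lev$cluster, levels = c("A", "B", "C"))
  expect_error(expressing_fractions(fx$counts, lev), "C",
               class = "advcomm_empty_result_error")
})

test_that("mean interaction number reproduces the worked 0.3 example", {
  fx <- four_five()
  fr <- expressing_fractions(fx$counts, fx$annotation)
  M <- mean_interaction_matrix(fr, fx$pairs)
  expect_equal(M["A", "B"], (2 * 3) / (4 * 5))
  expect_identical(unclass_m(M), unclass_m(oracle_mean_interaction(
    fx$counts, fx$annotation, fx$pairs)))
})

test_that("mean interaction equals the literal triple loop on fuzzed instances", {
  set.seed(101)
  for (i in 1:30) {
    inst <- random_instance()
    fr <- expressing_fractions(inst$counts, inst$annotation)
    M <- mean_interaction_matrix(fr, inst$pairs)
    O <- oracle_mean_interaction(inst$counts, inst$annotation, inst$pairs)
    expect_identical(unclass_m(M), unclass_m(O[rownames(M), colnames(M)]))
  }
})

test_that("saturated expression reaches the pair-count upper bound", {
  genes <- c("g1", "g2", "g3", "g4", "g5", "g6")
  m <- matrix(1, 6, 6, dimnames = list(genes, paste0("c", 1:6)))
  ann <- data.frame(barcode = paste0("c", 1:6),
                    cluster = rep(c("A", "B"), each = 3), genotype = "wt")
  pairs <- data.frame(ligand = c("g1", "g2", "g3"),
                      receptor = c("g4", "g5", "g6"))
  fr <- expressing_fractions(m, ann)
  M <- mean_interaction_matrix(fr, pairs)
  expect_true(all(unclass_m(M) == 3))
})

test_that("gene-set restriction filters the pair universe", {
  genes <- paste0("g", 1:6)
  m <- matrix(1, 6, 4, dimnames = list(genes, paste0("c", 1:4)))
  ann <- data.frame(barcode = paste0("c", 1:4),
                    cluster = rep(c("A", "B"), each = 2), genotype = "wt")
  pairs <- data.frame(ligand = c("g1", "g2"), receptor = c("g4", "g5"))
  fr <- expressing_fractions(m, ann)
  expect_equal(attr(mean_interaction_matrix(fr, pairs,
                                            restrict_to = c("g1", "g4")),
                    "n_pairs"), 1L)
  # "either" mode keeps pairs with one member in the set
  expect_equal(attr(mean_interaction_matrix(fr, pairs, restrict_to = "g2",
                                            restrict_mode = "either"),
                    "n_pairs"), 1L)
  expect_error(mean_interaction_matrix(fr, pairs, restrict_to = "g6"),
               class = "advcomm_empty_result_error")
})

test_that("pair scores are fraction products, directed, and sum to M", {
  fx <- four_five()
  fr <- expressing_fractions(fx$counts, fx$annotation)
  tab <- pair_interaction_scores(fr, fx$pairs)
  get <- function(A, B) tab$score[tab$ligand_type == A & tab$receptor_type == B]
  expect_equal(get("A", "B"), 0.5 * 0.6)
  expect_equal(get("B", "A"), 0)              # direction matters
  M <- mean_interaction_matrix(fr, fx$pairs)
  for (A in c("A", "B")) for (B in c("A", "B"))
    expect_equal(sum(tab$score[tab$ligand_type == A & tab$receptor_type == B]),
                 M[A, B], tolerance = 1e-15)
  expect_error(pair_interaction_scores(fr, fx$pairs, types = "Z"),
               class = "advcomm_validation_error")
})

test_that("outputs are invariant to cell and pair permutations", {
  set.seed(33)
  inst <- random_instance(n_cells = 30, n_genes = 12, n_pairs = 6)
  fr <- expressing_fractions(inst$counts, inst$annotation)
  M1 <- mean_interaction_matrix(fr, inst$pairs)
  perm_cells <- sample(ncol(inst$counts))
  perm_pairs <- sample(nrow(inst$pairs))
  fr2 <- expressing_fractions(inst$counts[, perm_cells],
                              inst$annotation[perm_cells, ])
  M2 <- mean_interaction_matrix(fr2, inst$pairs[perm_pairs, ])
  expect_equal(M1[rownames(M2), colnames(M2)], M2, ignore_attr = TRUE)
})

test_that("top-pair ranking is score-descending with lexicographic ties", {
  tab <- data.frame(ligand = c("Ccl7", "Ccl2", "Apoe"),
                    receptor = c("Ccr2", "Ccr2", "Lrp1"),
                    ligand_type = "A", receptor_type = "B",
                    ligand_fraction = 1, receptor_fraction = 1,
                    score = c(0.3, 0.3, 0.1), stringsAsFactors = FALSE)
  top <- rank_top_pairs(tab, 2)
  expect_equal(top$ligand, c("Ccl2", "Ccl7"))
  expect_equal(nrow(rank_top_pairs(tab, 10)), 3)   # no padding
  fx <- four_five()
  fr <- expressing_fractions(fx$counts, fx$annotation)
  all_scores <- pair_interaction_scores(fr, fx$pairs)
  expect_equal(rank_top_pairs(all_scores, 1)$score, 0.3)
})

test_that("chord data keeps both fractions and conserves totals", {
  tab <- data.frame(ligand = c("Cxcl12", "Ccl2"), receptor = c("Cxcr4", "Ccr2"),
                    ligand_type = c("Mac_14", "Mesen_II"),
                    receptor_type = c("Mac_7", "Mesen_II"),
                    ligand_fraction = c(0.8, 0.5),
                    receptor_fraction = c(0.4, 0.2),
                    score = c(0.32, 0.1), stringsAsFactors = FALSE)
  ch <- chord_data(tab, pair_subset = "Cxcl12-Cxcr4")
  expect_equal(nrow(ch$links), 1)
  expect_equal(ch$totals$as_ligand[ch$totals$cell_type == "Mac_14"], 0.32)
  expect_equal(ch$totals$as_receptor[ch$totals$cell_type == "Mac_7"], 0.32)
  # a self-link contributes to the same type on both ends
  full <- chord_data(tab)
  self <- full$totals[full$totals$cell_type == "Mesen_II", ]
  expect_equal(self$as_ligand, 0.1)
  expect_equal(self$as_receptor, 0.1)
  expect_equal(sum(full$totals$as_ligand), sum(tab$score))
  expect_equal(sum(full$totals$as_receptor), sum(tab$score))
  expect_error(chord_data(tab, pair_subset = "Nope-Nada"),
               class = "advcomm_empty_result_error")
})

test_that("genotype comparison is a regularized log2 ratio", {
  M <- matrix(c(0.1, 0, 0.4, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  same <- compare_genotypes(M, M, epsilon = 1e-4)
  expect_true(all(same$log2_ratio == 0))
  Mk <- M; Mk["A", "A"] <- 0.2
  cg <- compare_genotypes(M, Mk, epsilon = 1e-12)
  expect_equal(cg$log2_ratio["A", "A"], 1, tolerance = 1e-6)
  expect_equal(cg$log2_ratio["B", "B"], 0)      # 0 vs 0 stays 0
  bad <- M; rownames(bad) <- c("A", "C")
  expect_error(compare_genotypes(M, bad), "C",
               class = "advcomm_validation_error")
  # default epsilon comes from the two total cell numbers
  attr(M, "n_cells") <- c(A = 10L, B = 10L)
  Mk2 <- M
  attr(Mk2, "n_cells") <- c(A = 25L, B = 25L)
  expect_equal(compare_genotypes(M, Mk2)$epsilon, 1 / (20 * 50))
})

test_that("downsampling is deterministic, exact for equal sizes, unbiased otherwise", {
  fx <- four_five()
  # equal sizes: 4 + 4 cells
  m <- fx$counts[, 1:8]
  ann <- fx$annotation[1:8, ]
  r1 <- downsample_robustness(m, ann, fx$pairs, repeats = 5, seed = 3)
  expect_true(all(r1$sd == 0))
  fr <- expressing_fractions(m, ann, genes = c("Ccl2", "Ccr2"))
  expect_equal(r1$mean, unclass_m2(mean_interaction_matrix(fr, fx$pairs)))
  r2 <- downsample_robustness(m, ann, fx$pairs, repeats = 5, seed = 3)
  expect_identical(r1, r2)
  one <- fx$annotation; one$cluster[1:3] <- "B"
  expect_error(downsample_robustness(fx$counts, one, fx$pairs, 5, 1),
               class = "advcomm_validation_error")
})
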