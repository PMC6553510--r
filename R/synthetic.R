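mouse_mito_symbols <- c("mt-Nd1", "mt-Nd2", "mt-Co1", "mt-Co2", "mt-Atp8",
                        "mt-Atp6", "mt-Co3", "mt-Nd3", "mt-Nd4l", "mt-Nd4",
                        "mt-Nd5", "mt-Nd6", "mt-Cytb")

default_cluster_pool <- c("Mesen_I", "Mesen_II", "Mesen_III", "Mesen_IV",
                          "Mac_resident", "Mac_inflammatory", "T_cell",
                          "B_cell", "NK", "Adv_EC", "Lymph_EC", "SMC",
                          "ILC2", "Neuron", "Pericyte")

#' Specification for a synthetic two-genotype single-cell dataset
#'
#' Describes a clustered genes-by-cells count simulation: negative-binomial
#' baseline counts with per-gene and per-cluster mean multipliers,
#' mitochondrial genes (`mt-` prefix), planted per-(genotype, cluster, gene)
#' expressing fractions, and planted quality-control offender cells that each
#' violate exactly one QC rule. The default scale mirrors a two-condition
#' mouse adventitia experiment at desk size: two genotypes ("wt",
#' "apoe_ko") times six clusters (mesenchyme subsets plus macrophage types)
#' times 300 cells, 3,000 nuclear genes plus 13 mitochondrial genes.
#'
#' `nb_dispersion` is the overdispersion in the variance function
#' `var = mu + dispersion * mu^2` (the NB size parameter is its reciprocal).
#'
#' @param n_clusters Number of cell clusters per genotype.
#' @param cells_per_cluster Cells per cluster per genotype.
#' @param n_genes Number of non-mitochondrial genes. The high-gene offender
#'   class needs more than 2,500 expressible genes, so the default keeps
#'   `n_genes + n_mito_genes` above that bound.
#' @param n_mito_genes Number of mitochondrial genes (named with the mouse
#'   `mt-` symbols, then `mt-extraNN`).
#' @param baseline_mean Baseline NB mean per gene per cell before multipliers.
#' @param nb_dispersion NB overdispersion (see above).
#' @param planted_fractions `data.frame(genotype, cluster, gene, fraction)`
#'   of target expressing fractions in `[0, 1]`; expression of each listed
#'   gene in the listed cells is Bernoulli-gated so the expected fraction of
#'   cells with count > 0 equals the target.
#' @param qc_low_fraction,qc_high_fraction,qc_mito_fraction Proportions of
#'   cells converted into QC offenders (too few expressed genes, too many
#'   expressed genes, high mitochondrial fraction); must sum to < 1.
#' @param genotypes Genotype labels.
#' @param clusters Cluster labels; default draws from an adventitia-flavored
#'   pool (Mesen I-IV, macrophages, ...).
#' @param seed Integer seed; all randomness flows from it.
#' @return A validated `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_clusters = 6L, cells_per_cluster = 300L,
                           n_genes = 3000L, n_mito_genes = 13L,
                           baseline_mean = 0.3, nb_dispersion = 0.5,
                           planted_fractions = NULL,
                           qc_low_fraction = 0.02, qc_high_fraction = 0.02,
                           qc_mito_fraction = 0.02,
                           genotypes = c("wt", "apoe_ko"),
                           clusters = NULL, seed = 1L) {
  assert_scalar_number(n_clusters, "n_clusters", 1, Inf, integer = TRUE)
  assert_scalar_number(cells_per_cluster, "cells_per_cluster", 1, Inf,
                       integer = TRUE)
  assert_scalar_number(n_genes, "n_genes", 1, Inf, integer = TRUE)
  assert_scalar_number(n_mito_genes, "n_mito_genes", 0, Inf, integer = TRUE)
  assert_scalar_number(baseline_mean, "baseline_mean", 1e-12, Inf)
  assert_scalar_number(nb_dispersion, "nb_dispersion", 1e-12, Inf)
  for (nm in c("qc_low_fraction", "qc_high_fraction", "qc_mito_fraction"))
    assert_scalar_number(get(nm), nm, 0, 1 - 1e-12)
  if (qc_low_fraction + qc_high_fraction + qc_mito_fraction >= 1)
    stop_advcomm("offender proportions must sum to < 1",
                 class = "advcomm_validation_error")
  assert_scalar_number(seed, "seed", integer = TRUE)
  if (is.null(clusters)) {
    clusters <- if (n_clusters <= length(default_cluster_pool))
      default_cluster_pool[seq_len(n_clusters)]
    else sprintf("cluster_%02d", seq_len(n_clusters))
  }
  if (length(clusters) != n_clusters || anyDuplicated(clusters))
    stop_advcomm("'clusters' must hold %d unique labels", n_clusters,
                 class = "advcomm_validation_error")
  if (length(genotypes) < 1L || anyDuplicated(genotypes))
    stop_advcomm("'genotypes' must hold unique labels",
                 class = "advcomm_validation_error")
  mito <- if (n_mito_genes <= length(mouse_mito_symbols))
    mouse_mito_symbols[seq_len(n_mito_genes)]
  else c(mouse_mito_symbols,
         sprintf("mt-extra%02d", seq_len(n_mito_genes - length(mouse_mito_symbols))))
  gene_names <- c(sprintf("Gene%04d", seq_len(n_genes)), mito)
  if (!is.null(planted_fractions)) {
    pf <- planted_fractions
    need <- c("genotype", "cluster", "gene", "fraction")
    if (!is.data.frame(pf) || !all(need %in% names(pf)))
      stop_advcomm("planted_fractions needs columns %s",
                   paste(need, collapse = ", "),
                   class = "advcomm_validation_error")
    if (any(!pf$genotype %in% genotypes) || any(!pf$cluster %in% clusters))
      stop_advcomm("planted_fractions references unknown genotype or cluster",
                   class = "advcomm_validation_error")
    if (any(!pf$gene %in% gene_names))
      stop_advcomm("planted gene(s) not in the generated gene list: %s",
                   paste(unique(setdiff(pf$gene, gene_names)), collapse = ", "),
                   class = "advcomm_validation_error")
    if (any(pf$fraction < 0 | pf$fraction > 1))
      stop_advcomm("planted fractions must lie in [0, 1]",
                   class = "advcomm_validation_error")
    if (anyDuplicated(pf[c("genotype", "cluster", "gene")]))
      stop_advcomm("duplicate planted_fractions record",
                   class = "advcomm_validation_error")
  }
  structure(list(n_clusters = as.integer(n_clusters),
                 cells_per_cluster = as.integer(cells_per_cluster),
                 n_genes = as.integer(n_genes),
                 n_mito_genes = as.integer(n_mito_genes),
                 baseline_mean = baseline_mean, nb_dispersion = nb_dispersion,
                 planted_fractions = planted_fractions,
                 qc_low_fraction = qc_low_fraction,
                 qc_high_fraction = qc_high_fraction,
                 qc_mito_fraction = qc_mito_fraction,
                 genotypes = genotypes, clusters = clusters,
                 gene_names = gene_names, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Simulate a clustered two-genotype count matrix with planted ground truth
#'
#' Draws counts per gene per cell from a negative binomial whose mean is
#' `baseline_mean` times a per-gene factor times a per-(gene, cluster)
#' multiplier; mitochondrial genes get a fixed elevated factor and no cluster
#' structure so the background mitochondrial fraction stays well below the
#' default QC cutoff. QC offender cells are then constructed so each violates
#' exactly one rule: low-gene offenders express exactly 50 genes, high-gene
#' offenders express `min(total genes, 3000)` genes (an error if that cannot
#' exceed 2,500), and high-mito offenders get a mitochondrial count share
#' drawn uniformly in (0.10, 0.30) at an ordinary expressed-gene count.
#' Finally, each planted expressing-fraction record Bernoulli-gates the gene
#' in the non-offender cells of its (genotype, cluster): gated-on cells draw
#' from the zero-truncated NB, gated-off cells are set to zero, so the
#' expected positivity fraction equals the target exactly.
#'
#' The output is byte-reproducible from `spec$seed`; the four sampling stages
#' (means, base counts, offenders, planting) use sub-seeds split from it.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `counts` (sparse genes-by-cells `dgCMatrix`),
#'   `annotation` (`data.frame(barcode, cluster, genotype)`), and `truth`
#'   (list with `expressing_fraction`, a data.frame of target and realized
#'   fractions, and `offender_barcodes`, lists of planted offender cells per
#'   rule).
#' @export
simulate_adventitia <- function(spec) {
  if (!inherits(spec, "synthetic_spec"))
    stop_advcomm("'spec' must come from synthetic_spec()",
                 class = "advcomm_validation_error")
  G <- spec$n_genes + spec$n_mito_genes
  n_types <- spec$n_clusters * length(spec$genotypes)
  N <- n_types * spec$cells_per_cluster
  n_high <- floor(spec$qc_high_fraction * N)
  if (n_high > 0L && min(G, 3000L) <= 2500L)
    stop_advcomm(paste0("high-gene offenders need > 2500 expressible genes; ",
                        "increase n_genes or set qc_high_fraction = 0"),
                 class = "advcomm_validation_error")
  set.seed(spec$seed)
  stage_seed <- sample.int(.Machine$integer.max - 1L, 4L)
  mito_idx <- spec$n_genes + seq_len(spec$n_mito_genes)

  # stage 1: per-gene factors and per-(gene, cluster) multipliers
  set.seed(stage_seed[[1L]])
  gene_factor <- exp(rnorm(G, 0, 1))
  gene_factor[mito_idx] <- 4        # elevated, fixed: stable mito background
  mult <- matrix(exp(rnorm(G * spec$n_clusters, 0, 0.5)), nrow = G)
  mult[mito_idx, ] <- 1
  mu <- spec$baseline_mean * gene_factor * mult   # recycled column-wise
  nb_size <- 1 / spec$nb_dispersion

  # stage 2: base counts, genotype-major then cluster-major column blocks
  set.seed(stage_seed[[2L]])
  counts <- matrix(0, nrow = G, ncol = N)
  annotation <- data.frame(barcode = character(N), cluster = character(N),
                           genotype = character(N), stringsAsFactors = FALSE)
  col <- 0L
  for (gt in spec$genotypes) {
    for (cl in seq_len(spec$n_clusters)) {
      idx <- col + seq_len(spec$cells_per_cluster)
      counts[, idx] <- rnbinom(G * spec$cells_per_cluster,
                               mu = mu[, cl], size = nb_size)
      annotation$barcode[idx] <- sprintf("%s_%s_%04d", gt, spec$clusters[[cl]],
                                         seq_len(spec$cells_per_cluster))
      annotation$cluster[idx] <- spec$clusters[[cl]]
      annotation$genotype[idx] <- gt
      col <- col + spec$cells_per_cluster
    }
  }

  # stage 3: QC offenders, each violating exactly one rule by construction
  set.seed(stage_seed[[3L]])
  n_low <- floor(spec$qc_low_fraction * N)
  n_mo <- floor(spec$qc_mito_fraction * N)
  off <- sample.int(N, n_low + n_high + n_mo)
  low_idx <- off[seq_len(n_low)]
  high_idx <- off[n_low + seq_len(n_high)]
  mito_off_idx <- off[n_low + n_high + seq_len(n_mo)]
  nonmito <- seq_len(spec$n_genes)
  for (i in low_idx) {
    counts[, i] <- 0
    counts[sample(nonmito, 50L), i] <- 1
  }
  k_high <- min(G, 3000L)
  for (i in high_idx) {
    counts[, i] <- 0
    counts[sample.int(G, k_high), i] <- 1
  }
  if (n_mo > 0L) {
    if (spec$n_mito_genes < 1L)
      stop_advcomm("high-mito offenders need n_mito_genes >= 1",
                   class = "advcomm_validation_error")
    k_nm <- min(spec$n_genes, 400L)
    if (k_nm < 200L)
      stop_advcomm("high-mito offenders need n_genes >= 200",
                   class = "advcomm_validation_error")
    for (i in mito_off_idx) {
      counts[, i] <- 0
      counts[sample(nonmito, k_nm), i] <- 1
      share <- runif(1, 0.10, 0.30)
      mito_total <- max(1L, round(k_nm * share / (1 - share)))
      counts[mito_idx, i] <- rmultinom(1L, mito_total,
                                       rep(1, spec$n_mito_genes))[, 1L]
    }
  }
  offender <- logical(N); offender[off] <- TRUE

  # stage 4: Bernoulli-gated planting of expressing fractions
  set.seed(stage_seed[[4L]])
  truth_frac <- data.frame(genotype = character(), cluster = character(),
                           gene = character(), target = numeric(),
                           realized = numeric(), stringsAsFactors = FALSE)
  if (!is.null(spec$planted_fractions)) {
    pf <- spec$planted_fractions
    for (r in seq_len(nrow(pf))) {
      g <- match(pf$gene[[r]], spec$gene_names)
      cl <- match(pf$cluster[[r]], spec$clusters)
      cells <- which(annotation$genotype == pf$genotype[[r]] &
                       annotation$cluster == pf$cluster[[r]] & !offender)
      if (!length(cells))
        stop_advcomm("no non-offender cells left in (%s, %s) to plant on",
                     pf$genotype[[r]], pf$cluster[[r]],
                     class = "advcomm_validation_error")
      gate <- rbinom(length(cells), 1L, pf$fraction[[r]]) == 1L
      counts[g, cells] <- 0
      if (any(gate)) {
        mu_g <- spec$baseline_mean * gene_factor[[g]] * mult[g, cl]
        p0 <- dnbinom(0L, mu = mu_g, size = nb_size)
        u <- runif(sum(gate), p0, 1)
        counts[g, cells[gate]] <- pmax(1, qnbinom(u, mu = mu_g, size = nb_size))
      }
      truth_frac <- rbind(truth_frac, data.frame(
        genotype = pf$genotype[[r]], cluster = pf$cluster[[r]],
        gene = pf$gene[[r]], target = pf$fraction[[r]],
        realized = mean(gate), stringsAsFactors = FALSE))
    }
  }

  dimnames(counts) <- list(spec$gene_names, annotation$barcode)
  truth <- list(
    expressing_fraction = truth_frac,
    offender_barcodes = list(
      low_gene = annotation$barcode[low_idx],
      high_gene = annotation$barcode[high_idx],
      high_mito = annotation$barcode[mito_off_idx]))
  list(counts = as_count_matrix(counts), annotation = annotation,
       truth = truth)
}

#' Analytic expected mean interaction number from planted fractions
#'
#' For a ligand cell type A and receptor cell type B, the expected mean
#' interaction number over a pair list is the sum over pairs of
#' `f_A(ligand) * f_B(receptor)` evaluated on the planted fractions — the
#' closed-form expectation of the score the cross-talk module estimates.
#'
#' @param truth The `truth` component returned by [simulate_adventitia()].
#' @param pairs A ligand-receptor pair `data.frame` (see [read_lr_pairs()]).
#' @param ligand_type,receptor_type Cluster labels.
#' @param genotype Genotype label.
#' @param use `"target"` (the specified fractions; the analytic expectation)
#'   or `"realized"` (the fractions actually materialized by the gating).
#' @return A single number, the expected mean interaction number.
#' @export
planted_expected_score <- function(truth, pairs, ligand_type, receptor_type,
                                   genotype, use = c("target", "realized")) {
  use <- match.arg(use)
  tf <- truth$expressing_fraction
  lookup <- function(cluster, gene) {
    hit <- which(tf$genotype == genotype & tf$cluster == cluster &
                   tf$gene == gene)
    if (!length(hit))
      stop_advcomm("no planted fraction for (%s, %s, %s)", genotype, cluster,
                   gene, class = "advcomm_validation_error")
    tf[[use]][[hit[[1L]]]]
  }
  sum(vapply(seq_len(nrow(pairs)), function(r)
    lookup(ligand_type, pairs$ligand[[r]]) *
      lookup(receptor_type, pairs$receptor[[r]]), numeric(1)))
}
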