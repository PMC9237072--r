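test_that("cell QC applies the UMI, mito and relative-detection rules", {
  # 1000 genes; cells engineered to sit exactly on the thresholds
  G <- 1010
  m <- matrix(0L, G, 5)
  rownames(m) <- c(sprintf("mt-%02d", 1:10), sprintf("g%04d", 1:(G - 10)))
  colnames(m) <- paste0("c", 1:5)
  m[1:G, 1] <- 6L                       # c1: 1000 genes detected (incl. mito)
  m[1001:1010, 1] <- 0L                 #     6060 - 60 = 6000 UMI, 1% mito
  m[11:(10 + 400), 2] <- 15L            # c2: 400 genes = 40% of 1000 -> kept
  m[11:(10 + 399), 3] <- 16L            # c3: 399 genes -> relative detection fail
  m[11:(10 + 500), 4] <- 10L            # c4: 5000 UMI -> kept (>= floor)
  m[11:(10 + 500), 5] <- 9L             # c5: 4500 UMI -> removed
  x <- count_matrix(m)
  ann <- data.frame(unit_id = colnames(m),
                    phase = c("G1", "G2M", "G1", "G2M", "G1"))
  res <- qc_filter_cells(x, ann, pipeline_config(min_rel_detection = 0.40))
  expect_setequal(res$annotations$unit_id, c("c1", "c2", "c4"))
  expect_setequal(res$removed$unit_id[res$removed$rule == "min_umi"], "c5")
  expect_setequal(res$removed$unit_id[res$removed$rule == "min_rel_detection"],
                  "c3")

  # mito rule: cell at 6% mitochondrial removed, at 4% kept
  m2 <- matrix(50L, 100, 2,
               dimnames = list(c(sprintf("mt-%d", 1:6), sprintf("g%d", 1:94)),
                               c("hi", "lo")))
  m2[1:6, "hi"] <- 64L   # 384 / (384 + 4700) = 7.6% -> removed
  m2[1:6, "lo"] <- 30L   # 180 / (180 + 4700) = 3.7% -> kept
  m2[7:100, ] <- 50L
  ann2 <- data.frame(unit_id = c("hi", "lo"), phase = c("G1", "G2M"))
  res2 <- qc_filter_cells(count_matrix(m2), ann2,
                          pipeline_config(min_umi = 1000,
                                          min_rel_detection = 0.05))
  expect_equal(res2$removed$unit_id, "hi")
  expect_equal(res2$removed$rule, "max_mito_fraction")
})

test_that("gene filter keeps genes detected in at least 20% of cells", {
  set.seed(41)
  m <- matrix(0L, 200, 100,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("c%03d", 1:100)))
  m[1, 1:19] <- 5L   # 19% -> removed
  m[2, 1:20] <- 5L   # 20% -> kept
  m[3, ] <- 2L       # all cells -> kept
  m[4:200, ] <- matrix(rbinom(197 * 100, 1, 0.4) * 3L, 197, 100)
  x <- count_matrix(m)
  kept <- filter_genes_sc(x, 0.20)$gene_ids
  expect_false("g001" %in% kept)
  expect_true(all(c("g002", "g003") %in% kept))
  want <- rownames(m)[rowMeans(m > 0) >= 0.2]
  expect_setequal(kept, want)
})

test_that("pseudobulk blocks conserve counts exactly", {
  set.seed(42)
  x <- random_counts(genes = 60, units = 25, seed = 42)
  ann <- phase_annotations(25, phases = c(rep("G1", 25)))
  pb <- make_pseudobulk(x, ann, size = 10, seed = 7)
  expect_equal(ncol(pb$counts), 2)
  expect_equal(length(pb$dropped), 5)
  expect_equal(
    rowSums(pb$counts) + rowSums(x$counts[, pb$dropped, drop = FALSE]),
    rowSums(x$counts)
  )
  for (s in colnames(pb$counts)) {
    expect_equal(pb$counts[, s],
                 rowSums(x$counts[, pb$members[[s]], drop = FALSE]))
  }

  # exactly one group of exactly `size` cells: the single sample is the sum
  x10 <- subset_counts(x, units = 1:10)
  pb10 <- make_pseudobulk(x10, ann[1:10, ], size = 10, seed = 1)
  expect_equal(ncol(pb10$counts), 1)
  expect_equal(pb10$counts[, 1], rowSums(x10$counts))
  expect_equal(length(pb10$dropped), 0)
})

test_that("pseudobulk construction is deterministic under a seed", {
  sim <- simulate_sc(sim_params(n_genes = 100, n_cells_per_phase = 40, seed = 2))
  pb1 <- make_pseudobulk(sim$counts, sim$annotations, size = 10, seed = 9)
  pb2 <- make_pseudobulk(sim$counts, sim$annotations, size = 10, seed = 9)
  expect_identical(pb1$counts, pb2$counts)
  expect_identical(pb1$members, pb2$members)
})

test_that("scrambled pseudobulk matches the matched sample layout", {
  sim <- simulate_sc(sim_params(n_genes = 80, n_cells_per_phase = 60,
                                lineages = c("A", "B"), seed = 3))
  matched <- make_pseudobulk(sim$counts, sim$annotations, size = 10, seed = 1)
  scram <- scramble_lineage_pseudobulk(sim$counts, sim$annotations,
                                       size = 10, seed = 1)
  tab_m <- table(matched$annotations$phase, matched$annotations$lineage)
  tab_s <- table(scram$annotations$phase, scram$annotations$lineage)
  expect_equal(tab_m, tab_s)
  # every scrambled sample is phase-pure
  ann <- sim$annotations
  for (s in names(scram$members)) {
    cells <- scram$members[[s]]
    ph <- ann$phase[match(cells, ann$unit_id)]
    expect_equal(length(unique(ph)), 1L)
  }
  # conservation holds per draw
  expect_equal(
    rowSums(scram$counts) +
      rowSums(sim$counts$counts[, scram$dropped, drop = FALSE]),
    rowSums(sim$counts$counts)
  )
})

test_that("equal-phase down-sampling balances each lineage", {
  ann <- data.frame(
    unit_id = sprintf("c%04d", 1:230),
    phase = c(rep("G1", 120), rep("G2M", 80), rep("G1", 30)),
    lineage = c(rep("A", 200), rep("B", 30)),
    stringsAsFactors = FALSE
  )
  expect_warning(keep <- downsample_equal_phase(ann, seed = 4), "lacks one phase")
  kept <- ann[ann$unit_id %in% keep, ]
  expect_equal(sum(kept$lineage == "B"), 0)
  expect_equal(sum(kept$phase == "G1"), 80)
  expect_equal(sum(kept$phase == "G2M"), 80)

  bal <- ann[1:160, ]
  bal$phase <- rep(c("G1", "G2M"), 80)
  keep2 <- downsample_equal_phase(bal, seed = 4)
  expect_setequal(keep2, bal$unit_id)
})

test_that("an exact expression null produces no permuted phasic calls", {
  set.seed(43)
  G <- 300
  g1 <- matrix(rnbinom(G * 100, mu = 4, size = 5), G, 100)
  m <- cbind(g1, g1) # G2M cells are exact copies of G1 cells
  dimnames(m) <- list(sprintf("g%03d", 1:G), sprintf("u%03d", 1:200))
  ann <- phase_annotations(200, phases = rep(c("G1", "G2M"), each = 100))
  x <- filter_genes_sc(count_matrix(m))
  res <- permuted_phasic_test(x, ann, alpha = 0.05, n_permutations = 10,
                              seed = 1)
  expect_equal(sum(res$phasic_call, na.rm = TRUE), 0)
  expect_true(all(res$n_permutations_used <= 10))
})

test_that("a single permutation reduces to one hurdle pass", {
  sim <- simulate_sc(sim_params(n_genes = 150, n_cells_per_phase = 60,
                                frac_phasic = 0.1, seed = 5))
  x <- filter_genes_sc(sim$counts)
  res <- permuted_phasic_test(x, sim$annotations, n_permutations = 1,
                              seed = 11, keep_raw = TRUE)
  adj <- attr(res, "adj_p")
  expect_equal(ncol(adj), 1)
  expect_equal(res$median_adj_p, unname(adj[, 1]))
  expect_equal(res$phasic_call,
               res$median_adj_p < 0.05 & res$passes_fc)
})

test_that("the fold-change gate only ever removes calls", {
  sim <- simulate_sc(sim_params(n_genes = 300, n_cells_per_phase = 80,
                                frac_phasic = 0.15, effect_log2fc = 0.5,
                                seed = 6))
  x <- filter_genes_sc(sim$counts)
  res <- permuted_phasic_test(x, sim$annotations, n_permutations = 10, seed = 2)
  ungated <- !is.na(res$median_adj_p) & res$median_adj_p < 0.05
  gated <- which(res$phasic_call)
  expect_true(all(gated %in% which(ungated)))
  expect_false(any(res$phasic_call & !res$passes_fc))
})

test_that("permuted calls are bit-identical under the same seed", {
  sim <- simulate_sc(sim_params(n_genes = 120, n_cells_per_phase = 50,
                                frac_phasic = 0.1, seed = 7))
  x <- filter_genes_sc(sim$counts)
  r1 <- permuted_phasic_test(x, sim$annotations, n_permutations = 5, seed = 3)
  r2 <- permuted_phasic_test(x, sim$annotations, n_permutations = 5, seed = 3)
  expect_identical(r1, r2)
})

test_that("interaction testing needs two lineages and respects a null", {
  sim <- simulate_sc(sim_params(n_genes = 100, n_cells_per_phase = 50, seed = 8))
  expect_error(
    interaction_phasic_test(sim$counts, sim$annotations, "L1",
                            n_permutations = 2),
    ">= 2 lineages"
  )
  sim2 <- simulate_sc(sim_params(n_genes = 200, n_cells_per_phase = 60,
                                 lineages = c("A", "B"), frac_phasic = 0,
                                 seed = 9))
  x <- filter_genes_sc(sim2$counts)
  res <- interaction_phasic_test(x, sim2$annotations, "A",
                                 n_permutations = 10, seed = 1)
  expect_equal(sum(res$phasic_call, na.rm = TRUE), 0)
  expect_error(
    interaction_phasic_test(x, sim2$annotations, "missing",
                            n_permutations = 2),
    "absent"
  )
})

test_that("identical genotypes give identical call counts", {
  sim <- simulate_sc(sim_params(n_genes = 150, n_cells_per_phase = 60,
                                frac_phasic = 0.1, seed = 10))
  x <- filter_genes_sc(sim$counts)
  set1 <- list(counts = x, annotations = sim$annotations)
  cmp <- compare_genotype_phasic(set1, set1, n_resamples = 3, seed = 5)
  expect_equal(cmp$n_control_calls, cmp$n_mutant_calls)
  expect_equal(cmp$control$median_adj_p, cmp$mutant$median_adj_p)
  cmp1 <- compare_genotype_phasic(set1, set1, n_resamples = 1, seed = 5)
  expect_equal(unique(cmp1$control$n_permutations_used[
    !is.na(cmp1$control$median_adj_p)]), 1)
})

test_that("panel clustering separates phases when effects are large", {
  sim <- simulate_sc(sim_params(n_genes = 200, n_cells_per_phase = 60,
                                frac_phasic = 0.2, effect_log2fc = 4,
                                seed = 11))
  panel <- sim$truth$gene_id[sim$truth$is_phasic]
  agree <- panel_phase_clustering_check(sim$counts, sim$annotations, panel)
  expect_gte(agree, 0.95)
  shuf <- sim$annotations
  set.seed(12)
  shuf$phase <- sample(shuf$phase)
  agree0 <- panel_phase_clustering_check(sim$counts, shuf, panel)
  expect_lt(agree0, 0.65)
  expect_error(panel_phase_clustering_check(sim$counts, sim$annotations,
                                            "no_such_gene"), "panel gene")
})

test_that("2-means agreement matches the exhaustive best 2-partition", {
  sim <- simulate_sc(sim_params(n_genes = 60, n_cells_per_phase = 6,
                                frac_phasic = 0.3, effect_log2fc = 1.5,
                                seed = 13))
  panel <- sim$truth$gene_id[sim$truth$is_phasic]
  x <- subset_counts(sim$counts,
                     genes = match(intersect(panel, sim$counts$gene_ids),
                                   sim$counts$gene_ids))
  expr <- t(log2_cpm(x))
  n <- nrow(expr)
  best <- -Inf
  best_assign <- NULL
  for (code in 1:(2^(n - 1) - 1)) { # all 2-partitions up to label swap
    assign <- as.integer(intToBits(code))[1:n]
    if (all(assign == 0) || all(assign == 1)) next
    ss <- sum(scale(expr[assign == 0, , drop = FALSE], scale = FALSE)^2) +
      sum(scale(expr[assign == 1, , drop = FALSE], scale = FALSE)^2)
    if (-ss > best) {
      best <- -ss
      best_assign <- assign
    }
  }
  phase <- normalize_phase(sim$annotations$phase)
  oracle_agree <- max(mean((best_assign == 0) == (phase == "G1")),
                      mean((best_assign == 1) == (phase == "G1")))
  got <- panel_phase_clustering_check(x, sim$annotations, x$gene_ids)
  expect_equal(got, oracle_agree, tolerance = 1e-9)
})
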