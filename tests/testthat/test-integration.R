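test_that("cross-strain concordance separates identical from mirrored results", {
  de <- toy_de(paste0("f", 1:10), logFC = c(rep(1, 5), rep(-1, 5)),
               P = rep(0.001, 10))
  same <- cross_strain_concordance(de, de)
  expect_equal(same$n_same, 10)
  expect_equal(same$n_opposite, 0)
  mirrored <- de
  mirrored$logFC <- -mirrored$logFC
  opp <- cross_strain_concordance(de, mirrored)
  expect_equal(opp$n_opposite, 10)
  expect_equal(opp$fraction_opposite, 1)
  none <- cross_strain_concordance(de, toy_de("zz", 1, 0.001))
  expect_true(is.na(none$p_binomial))
})

test_that("concordance binomial P equals exact enumeration up to 20 genes", {
  set.seed(18)
  for (i in 1:15) {
    n <- sample(3:20, 1)
    k <- sample(0:n, 1)
    dir_a <- rep(1, n)
    dir_b <- c(rep(1, k), rep(-1, n - k))
    de_a <- toy_de(paste0("f", 1:n), logFC = dir_a, P = rep(0.001, n))
    de_b <- toy_de(paste0("f", 1:n), logFC = dir_b, P = rep(0.001, n))
    res <- cross_strain_concordance(de_a, de_b)
    expect_equal(res$n_same, k)
    expect_equal(res$p_binomial, brute_force_binom_two_sided(k, n),
                 tolerance = 1e-9)
  }
})

test_that("pathway convergence applies the 2-of-12 FDR and 4-of-12 nominal rule", {
  comparisons <- sprintf("c%02d", 1:12)
  grid <- rbind(
    # exactly at the boundary: 2 FDR-significant, 4 nominal -> selected
    data.frame(pathway = "boundary", comparison = comparisons[1:4],
               p = 0.01, pfdr = c(0.01, 0.01, 0.5, 0.5)),
    # 1 FDR-significant but nominal everywhere -> excluded
    data.frame(pathway = "nominal_only", comparison = comparisons,
               p = 0.01, pfdr = c(0.01, rep(0.5, 11)))
  )
  res <- pathway_convergence(grid)
  expect_true(res$selected[res$pathway == "boundary"])
  expect_false(res$selected[res$pathway == "nominal_only"])
  expect_error(pathway_convergence(grid[0, ]), "empty")
})

test_that("pathway convergence matches per-pathway enumeration and is monotone", {
  set.seed(19)
  grid <- expand.grid(pathway = sprintf("p%02d", 1:15),
                      comparison = sprintf("c%02d", 1:12),
                      stringsAsFactors = FALSE)
  grid$p <- runif(nrow(grid), 0, 0.2)
  grid$pfdr <- pmin(1, grid$p * runif(nrow(grid), 1, 6))
  res <- pathway_convergence(grid)
  for (pw in unique(grid$pathway)) {
    g <- grid[grid$pathway == pw, ]
    expect_equal(res$selected[res$pathway == pw],
                 sum(g$pfdr < 0.05) >= 2 && sum(g$p < 0.05) >= 4)
  }
  # making any P smaller never de-selects
  grid2 <- grid
  grid2$p <- grid2$p / 10
  grid2$pfdr <- grid2$pfdr / 10
  res2 <- pathway_convergence(grid2)
  expect_true(all(res2$selected[res$selected]))
})

test_that("regulator selection requires the ceiling of 25% of comparisons", {
  grid <- expand.grid(regulator = c("three_hits", "two_hits"),
                      comparison = sprintf("c%02d", 1:12),
                      stringsAsFactors = FALSE)
  grid$pfdr <- 1
  grid$pfdr[grid$regulator == "three_hits"][1:3] <- 0.01
  grid$pfdr[grid$regulator == "two_hits"][1:2] <- 0.01
  res <- regulator_selection(grid)
  expect_equal(res$required[1], 3)
  expect_true(res$selected[res$regulator == "three_hits"])
  expect_false(res$selected[res$regulator == "two_hits"])
  set.seed(20)
  grid$pfdr <- runif(nrow(grid))
  res <- regulator_selection(grid)
  for (rg in unique(grid$regulator)) {
    expect_equal(res$selected[res$regulator == rg],
                 sum(grid$pfdr[grid$regulator == rg] < 0.05) >= 3)
  }
})

test_that("cross-omics overlap demands the same comparison in two data sets", {
  base <- expand.grid(dataset = c("mrna", "protein"),
                      strain = "B6", contrast = "susceptible_vs_control",
                      stringsAsFactors = FALSE)
  both <- cbind(feature_id = "Cycs", base, logFC = 1, P = 0.001)
  res <- cross_omics_overlap(both)
  expect_equal(res$molecule, "CYCS")
  expect_equal(res$n_datasets, 2)
  # same molecule DE in two different contrasts only -> excluded
  split_contrast <- both
  split_contrast$contrast <- c("susceptible_vs_control",
                               "resilient_vs_control")
  expect_equal(nrow(cross_omics_overlap(split_contrast)), 0)
  # category annotation and display filter
  res2 <- cross_omics_overlap(both,
                              categories = list("mitochondria-related" = "CYCS"))
  expect_equal(res2$category, "mitochondria-related")
  expect_true(res2$passes_display)
})

test_that("cross-omics overlap matches brute-force enumeration on a random grid", {
  set.seed(22)
  grid <- expand.grid(feature_id = sprintf("m%02d", 1:30),
                      dataset = c("mrna", "protein"),
                      strain = c("B6", "D2"),
                      contrast = c("susceptible_vs_control",
                                   "resilient_vs_control"),
                      stringsAsFactors = FALSE)
  grid$logFC <- rnorm(nrow(grid))
  grid$P <- runif(nrow(grid), 0, 0.2)
  res <- cross_omics_overlap(grid)
  flag <- grid$P < 0.05 & abs(grid$logFC) >= log2(1.2)
  oracle <- 0L
  for (f in unique(grid$feature_id)) for (st in c("B6", "D2")) {
    for (cn in unique(grid$contrast)) {
      rows <- grid$feature_id == f & grid$strain == st & grid$contrast == cn
      if (length(unique(grid$dataset[rows & flag])) >= 2) oracle <- oracle + 1L
    }
  }
  expect_equal(nrow(res), oracle)
})

test_that("miRNA-target pairs need 3+ sources, joint DE, and matching direction", {
  de_mir <- toy_de(c("miR-99b", "miR-15b", "miR-34c"),
                   logFC = c(-0.6, 0.4, -1.5), P = c(0.001, 0.002, 0.004))
  de_mrna <- toy_de(c("Igf1r", "Dmtf1", "Jag1"),
                    logFC = c(-0.4, 0.4, 1.2), P = c(0.01, 0.01, 0.01))
  interactions <- data.frame(
    mirna = c("miR-99b", "miR-99b", "miR-15b", "miR-34c"),
    target = c("Igf1r", "Dmtf1", "Dmtf1", "Jag1"),
    n_sources = c(3, 3, 2, 3), stringsAsFactors = FALSE)
  pairs <- mirna_target_pairs(de_mir, de_mrna, interactions)
  # miR-99b/Igf1r: 3 sources, both down -> retained
  expect_true(any(pairs$mirna == "miR-99b" & pairs$target == "Igf1r"))
  # miR-99b/Dmtf1: opposite directions -> removed
  expect_false(any(pairs$mirna == "miR-99b" & pairs$target == "Dmtf1"))
  # miR-15b/Dmtf1: only 2 sources -> removed
  expect_false(any(pairs$mirna == "miR-15b"))
  # miR-34c down / Jag1 up -> removed
  expect_false(any(pairs$mirna == "miR-34c"))
  # invariant to interaction row order
  pairs2 <- mirna_target_pairs(de_mir, de_mrna,
                               interactions[rev(seq_len(nrow(interactions))), ])
  expect_identical(pairs, pairs2)
  expect_error(mirna_target_pairs(de_mir, de_mrna, interactions[0, ]),
               "empty interaction")
})

test_that("cross-tissue correlation behaves on exact and planted cases", {
  x <- stats::setNames(rnorm(50), paste0("g", 1:50))
  expect_equal(cross_tissue_correlation(x, x)$r, 1)
  expect_equal(cross_tissue_correlation(x, -x)$r, -1)
  expect_error(cross_tissue_correlation(x[1:2], x[1:2]), "insufficient")
  set.seed(23)
  n <- 500
  shared <- rnorm(n)
  de1 <- toy_de(sprintf("g%03d", 1:n), logFC = shared + rnorm(n, 0, 1.1),
                P = runif(n, 0, 0.04))
  de2 <- toy_de(sprintf("g%03d", 1:n), logFC = shared + rnorm(n, 0, 1.1),
                P = runif(n))
  res <- cross_tissue_correlation(de1, de2)
  expect_gt(res$r, 0.2)
  expect_lt(res$p, 1e-4)
  expect_equal(res$n, n)
})

test_that("the GSEA summary filter keeps sets significant in half the comparisons", {
  comparisons <- paste0("c", 1:6)
  enr <- rbind(
    data.frame(set = "kept", comparison = comparisons,
               nes = 2, pfdr = c(0.1, 0.2, 0.24, 0.5, 0.5, 0.5)),
    data.frame(set = "dropped", comparison = comparisons,
               nes = 2, pfdr = c(0.1, 0.2, rep(0.5, 4)))
  )
  res <- gsea_summary_filter(enr)
  expect_equal(res$selected, "kept")
  expect_equal(sum(!is.na(res$nes["kept", ])), 3)
  set.seed(24)
  enr$pfdr <- runif(nrow(enr))
  res <- gsea_summary_filter(enr)
  for (s in c("kept", "dropped")) {
    in_sel <- s %in% res$selected
    expect_equal(in_sel, sum(enr$pfdr[enr$set == s] < 0.25) >= 3)
  }
  expect_error(gsea_summary_filter(enr[0, ]), "empty")
})

test_that("union heatmap rows are ordered by the chosen contrast with stable ties", {
  de <- rbind(
    toy_de(c("a", "b", "c"), logFC = c(1, -2, 1), P = c(0.01, 0.01, 0.01),
           contrast = "susceptible_vs_control"),
    toy_de(c("a", "b", "d"), logFC = c(0.5, 0.5, 2), P = c(0.2, 0.01, 0.01),
           contrast = "resilient_vs_control")
  )
  tab <- union_heatmap_table(de, order_by = "susceptible_vs_control")
  expect_setequal(tab$feature_id, c("a", "b", "c", "d"))
  # a and c tie on FC = 2 in the ordering contrast -> alphabetical; d has no
  # FC there -> last
  expect_equal(tab$feature_id, c("a", "c", "b", "d"))
  expect_error(union_heatmap_table(de, order_by = "missing"), "not present")
  # random-order oracle
  set.seed(25)
  de2 <- toy_de(sprintf("f%02d", 1:20), logFC = rnorm(20),
                P = runif(20, 0, 0.04))
  tab2 <- union_heatmap_table(de2)
  flagged <- de2[abs(de2$logFC) >= log2(1.2), ]
  expect_equal(tab2$feature_id,
               flagged$feature_id[order(-flagged$FC, flagged$feature_id)])
})
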