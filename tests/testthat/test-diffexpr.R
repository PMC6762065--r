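test_that("CPM filter keeps features at the inclusive boundary and drops the silent", {
  # 2 features, library sizes exactly 1e6: CPM of the all-ones feature is 1
  v <- rbind(ones = rep(1, 6), filler = rep(999999, 6))
  colnames(v) <- sprintf("s%d", 1:6)
  samples <- make_sample_sheet(2, "B6")
  samples$sample_id <- colnames(v)
  m <- omics_matrix(v, samples, "mrna")
  kept <- cpm_filter(m, min_cpm = 1, min_samples = 6)
  expect_true("ones" %in% rownames(kept$values))
  v2 <- rbind(v, silent = rep(0, 6))
  m2 <- omics_matrix(v2, samples, "mrna")
  expect_false("silent" %in% rownames(cpm_filter(m2, 1, 1)$values))
})

test_that("CPM filter agrees with exhaustive per-cell evaluation on a toy matrix", {
  set.seed(4)
  v <- matrix(rpois(30, 10), 5, 6,
              dimnames = list(paste0("f", 1:5), paste0("s", 1:6)))
  samples <- make_sample_sheet(2, "B6")
  samples$sample_id <- colnames(v)
  m <- omics_matrix(v, samples, "mrna")
  for (ms in 1:4) {
    kept <- as.character(rownames(cpm_filter(m, min_cpm = 2e5,
                                             min_samples = ms)$values))
    cpm <- sweep(v, 2, colSums(v), "/") * 1e6
    oracle <- rownames(v)[rowSums(cpm >= 2e5) >= ms]
    expect_identical(kept, oracle)
  }
})

test_that("log-CPM matches hand arithmetic and is depth-invariant", {
  v <- matrix(c(0, 999999, 10, 999990), 2, 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  samples <- make_sample_sheet(1, "B6", groups = c("control", "susceptible"))
  samples$sample_id <- colnames(v)
  lc <- log_cpm(omics_matrix(v, samples, "mrna"))
  expect_equal(lc$values["a", "s1"], log2(0.5 / 1e6 * 1e6), tolerance = 1e-6)
  expect_equal(lc$values["a", "s2"], log2(10.5 / 1000001 * 1e6))
  # doubling counts and depth leaves values essentially unchanged for
  # expressed features (the pseudo-count makes zeros only approximately so)
  lc2 <- log_cpm(omics_matrix(v * 2, samples, "mrna"))
  expect_equal(lc2$values[v > 0], lc$values[v > 0], tolerance = 1e-3)
})

test_that("batch centering removes location shifts and preserves grand means", {
  tl <- toy_log_matrix(20, 4, seed = 2)
  batch <- rep(c("b1", "b2"), each = 4)
  shifted <- tl$values
  shifted[, batch == "b2"] <- shifted[, batch == "b2"] + 3
  fixed <- batch_center(shifted, batch)
  expect_equal(rowMeans(fixed[, batch == "b1"]),
               rowMeans(fixed[, batch == "b2"]))
  expect_equal(rowMeans(fixed), rowMeans(shifted))
  expect_equal(batch_center(tl$values, rep("b1", 8)), tl$values)
})

test_that("planted batch effects are flattened after centering", {
  samples <- make_sample_sheet(6, "B6", n_batches = 2)
  m <- simulate_counts(400, samples, signal_spec(batch_sd = 0.8, seed = 13))
  lc <- log_cpm(m)
  fstat <- function(vals) {
    b <- factor(samples$batch)
    mean(apply(vals, 1, function(x) summary(stats::aov(x ~ b))[[1]]$`F value`[1]))
  }
  expect_gt(fstat(lc$values), 2)
  expect_lt(fstat(batch_center(lc)$values), 1.3)
})

test_that("moderated t is zero for equal group means and needs replication", {
  v <- rbind(f1 = c(4, 6, 4, 6), f2 = c(1, 3, 1, 3))
  colnames(v) <- paste0("s", 1:4)
  groups <- c("control", "control", "susceptible", "susceptible")
  de <- fit_moderated_t(v, groups, contrast = c("susceptible", "control"))
  expect_equal(de$logFC, c(0, 0))
  expect_equal(de$t, c(0, 0))
  expect_equal(de$P, c(1, 1))
  expect_error(fit_moderated_t(v, c("a", "a", "a", "susceptible"),
                               contrast = c("susceptible", "a")),
               "insufficient replication")
  expect_error(fit_moderated_t(rbind(c(1, 1, 2, 2)), groups,
                               contrast = c("susceptible", "control")),
               "degenerate")
})

test_that("identical gene variances make the moderated t ordinary (full-shrinkage fixed point)", {
  # every feature has the same residual sum of squares by construction
  n <- 30
  v <- t(vapply(seq_len(n), function(i) {
    c(10 + i + c(-1, 1, -0.5, 0.5), 12 + i + c(-1, 1, -0.5, 0.5))
  }, numeric(8)))
  dimnames(v) <- list(sprintf("f%02d", 1:n), sprintf("s%d", 1:8))
  groups <- rep(c("control", "susceptible"), each = 4)
  de <- fit_moderated_t(v, groups, contrast = c("susceptible", "control"))
  hp <- attr(de, "hyperparams")
  expect_identical(hp$d0, Inf)
  s2 <- hp$s02
  ordinary_t <- de$logFC / sqrt(s2 * (1 / 4 + 1 / 4))
  expect_equal(de$t, ordinary_t)
})

test_that("moderated t and hyperparameters agree with the reference empirical-Bayes fit", {
  skip_if_not_installed("limma")
  tl <- toy_log_matrix(300, 5, seed = 7, effect = 1, n_effect = 30)
  de <- fit_moderated_t(tl$values, tl$groups,
                        contrast = c("susceptible", "control"))
  design <- stats::model.matrix(~factor(tl$groups, c("control", "susceptible")))
  fit <- limma::eBayes(limma::lmFit(tl$values, design))
  expect_equal(attr(de, "hyperparams")$d0, fit$df.prior, tolerance = 1e-6)
  expect_equal(attr(de, "hyperparams")$s02, fit$s2.prior, tolerance = 1e-6)
  expect_equal(de$t, unname(fit$t[de$feature_id, 2]), tolerance = 1e-8)
  expect_equal(de$P, unname(fit$p.value[de$feature_id, 2]), tolerance = 1e-8)
})

test_that("BH adjustment matches the definitional step-up on random vectors", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(10)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- bh_adjust(p)
    expect_equal(q, brute_force_bh(p))
    expect_true(all(q >= p & q <= 1))
    ord <- order(p)
    expect_true(all(diff(q[ord]) >= -1e-12))  # monotone in the P ranks
  }
})

test_that("DE flag uses strict P and inclusive fold-change boundaries", {
  de <- toy_de(paste0("f", 1:6),
               logFC = c(log2(1.2), log2(1.2) - 1e-9, -2, 0.5, -0.1, 1),
               P = c(0.01, 0.01, 0.05, 0.049, 0.001, 0.2))
  flagged <- de_flag(de)
  expect_true("f1" %in% flagged$feature_id)   # |FC| exactly 1.2, P small
  expect_false("f2" %in% flagged$feature_id)  # just under the FC bound
  expect_false("f3" %in% flagged$feature_id)  # P exactly 0.05
  expect_false("f5" %in% flagged$feature_id)  # tiny FC
  # brute-force row rule
  oracle <- de$feature_id[de$P < 0.05 & abs(de$logFC) >= log2(1.2)]
  expect_setequal(flagged$feature_id, oracle)
  expect_equal(flagged$direction, sign(flagged$logFC))
})

test_that("protein inclusion filter enforces peptide and variability rules", {
  reps <- expand.grid(replicate = 1:3, sample_id = "s1",
                      protein_id = c("good", "onepep", "noisy"),
                      stringsAsFactors = FALSE)
  reps$n_unique_peptides <- ifelse(reps$protein_id == "onepep", 1L, 3L)
  reps$hl_ratio <- 1
  reps$hl_ratio[reps$protein_id == "good"] <- 2       # CV 0
  reps$hl_ratio[reps$protein_id == "noisy"] <- c(1, 2, 4)  # CV ~ 65%
  out <- filter_proteins(reps)
  expect_identical(rownames(out), "good")
  expect_equal(out["good", "s1"], log2(2))
  dropped <- attr(out, "dropped")
  expect_equal(dropped$reason[dropped$protein_id == "onepep"],
               "unique_peptides")
  expect_equal(dropped$reason[dropped$protein_id == "noisy"],
               "hl_variability")
  expect_error(filter_proteins(reps[, 1:3]), "lacks columns")
})

test_that("protein filter agrees with per-protein rule evaluation on a random table", {
  set.seed(21)
  prot <- sprintf("q%02d", 1:25)
  reps <- expand.grid(replicate = 1:3, sample_id = c("s1", "s2"),
                      protein_id = prot, stringsAsFactors = FALSE)
  reps$n_unique_peptides <- sample(1:4, nrow(reps), replace = TRUE)
  reps$hl_ratio <- exp(rnorm(nrow(reps), 0, 0.2))
  out <- filter_proteins(reps)
  oracle_pass <- vapply(prot, function(p) {
    all(vapply(c("s1", "s2"), function(s) {
      r <- reps[reps$protein_id == p & reps$sample_id == s, ]
      q <- r[r$n_unique_peptides >= 2, ]
      nrow(q) >= 2 && sd(q$hl_ratio) / mean(q$hl_ratio) < 0.30
    }, logical(1)))
  }, logical(1))
  expect_setequal(rownames(out), prot[oracle_pass])
})

test_that("power: most planted features are flagged at n = 10 per group", {
  samples <- make_sample_sheet(10, "B6")
  planted <- sprintf("g%04d", 1:30)
  sig <- signal_spec(sets = list(S = planted), effect_size = 1,
                     strain_sign = c(B6 = 1), dispersion = 0.1, seed = 31)
  de <- fit_moderated_t(log_cpm(cpm_filter(
    simulate_counts(1000, samples, sig), 1, 6)),
    contrast = c("susceptible", "control"))
  flagged <- de_flag(de)
  expect_gte(mean(planted %in% flagged$feature_id), 0.8)
})

test_that("filtering and log transform commute with sample reordering", {
  samples <- make_sample_sheet(4, "B6")
  m <- simulate_counts(100, samples, signal_spec(seed = 17))
  perm <- sample(ncol(m$values))
  m2 <- m
  m2$values <- m2$values[, perm]
  m2$samples <- m2$samples[perm, ]
  a <- log_cpm(cpm_filter(m, 1, 3))$values
  b <- log_cpm(cpm_filter(m2, 1, 3))$values
  expect_equal(a, b[, colnames(a)])
})
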