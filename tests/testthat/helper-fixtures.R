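# Shared fixtures and independent oracles used across the test files.

# Toy DE table with known content.
toy_de <- function(feature_id, logFC, P, contrast = "susceptible_vs_control",
                   dataset = "toy") {
  data.frame(feature_id = feature_id, logFC = logFC,
             FC = ifelse(logFC >= 0, 2^logFC, -2^(-logFC)),
             t = logFC, P = P, Padj = p.adjust(P, "BH"),
             contrast = contrast, dataset = dataset,
             stringsAsFactors = FALSE)
}

# Definitional step-up BH: q_(i) = min_{j >= i} (m / j) p_(j), capped at 1.
brute_force_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q <- numeric(m)
  for (i in seq_len(m)) {
    q[ord[i]] <- min(1, min(vapply(i:m, function(j) m / j * p[ord[j]],
                                   numeric(1))))
  }
  q
}

# Exhaustive hypergeometric upper tail: probability that a uniformly random
# n-subset of the universe overlaps the set in at least k elements.
brute_force_hyper <- function(universe, set, n_draw, k) {
  draws <- utils::combn(length(universe), n_draw)
  in_set <- universe %in% set
  hits <- apply(draws, 2, function(ix) sum(in_set[ix]))
  mean(hits >= k)
}

# Exact two-sided binomial P at p = 0.5 by enumeration: total probability of
# outcomes no more likely than the observed one.
brute_force_binom_two_sided <- function(k, n) {
  d <- dbinom(0:n, n, 0.5)
  sum(d[d <= d[k + 1] * (1 + 1e-7)])
}

# Running-sum GSEA enrichment score computed step by step (weight p = 1).
brute_force_es <- function(metric, hit) {
  n <- length(metric)
  tot <- sum(abs(metric[hit]))
  run <- 0
  best <- 0
  for (i in seq_len(n)) {
    run <- run + if (hit[i]) abs(metric[i]) / tot else -1 / (n - sum(hit))
    if (abs(run) > abs(best)) best <- run
  }
  best
}

# Small deterministic log-scale matrix with group structure.
toy_log_matrix <- function(n_features = 50, n_per_group = 4, seed = 1,
                           effect = 0, n_effect = 0) {
  set.seed(seed)
  groups <- rep(c("control", "susceptible"), each = n_per_group)
  m <- matrix(rnorm(n_features * length(groups), 5, 1), n_features,
              dimnames = list(sprintf("f%03d", seq_len(n_features)),
                              sprintf("s%02d", seq_along(groups))))
  if (n_effect > 0) {
    m[seq_len(n_effect), groups == "susceptible"] <-
      m[seq_len(n_effect), groups == "susceptible"] + effect
  }
  list(values = m, groups = groups)
}
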