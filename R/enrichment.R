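# Rank-based gene-set enrichment (preranked GSEA with a random-set
# permutation null, NES, pooled-null FDR), hypergeometric
# overrepresentation, and a signed-regulon activation z-score.

#' Build a ranked list from a DE result
#'
#' The ranking metric is `sign(logFC) * -log10(P)`, combining direction and
#' significance. Features are sorted by metric descending, with ties broken
#' by `|logFC|` descending and then by identifier, so the order is a pure
#' function of the table content.
#'
#' @param de DE result table (needs `feature_id`, `logFC`, `P`).
#' @return Data frame of class `"ranked_list"` with columns `feature_id`
#'   and `metric`, in ranked order.
#' @export
rank_metric <- function(de) {
  if (anyDuplicated(de$feature_id)) {
    stop("ranked list requires unique feature identifiers", call. = FALSE)
  }
  metric <- sign(de$logFC) * -log10(de$P)
  if (any(!is.finite(metric))) {
    stop("non-finite ranking metric (P = 0 or missing values?)", call. = FALSE)
  }
  ord <- order(-metric, -abs(de$logFC), de$feature_id)
  structure(data.frame(feature_id = de$feature_id[ord],
                       metric = metric[ord],
                       stringsAsFactors = FALSE, row.names = NULL),
            class = c("ranked_list", "data.frame"))
}

# Enrichment score from hit positions in a ranked list. `aw` is
# |metric|^p for every position. The running sum increases by
# aw / sum(aw[hits]) at hits and decreases by 1/(N - k) at misses; its
# extremes can only occur immediately after a hit or immediately before
# the next hit, so only those 2k candidates are evaluated.
es_from_positions <- function(aw, positions) {
  n <- length(aw)
  k <- length(positions)
  if (k == 0) stop("undefined enrichment score: empty intersection", call. = FALSE)
  if (k >= n) stop("invalid set: as large as the ranked universe", call. = FALSE)
  pos <- sort(positions)
  hw <- aw[pos]
  tot <- sum(hw)
  if (tot == 0) hw <- rep(1, k)  # all-zero hit weights: fall back to unweighted
  cum_hit <- cumsum(hw) / max(tot, sum(hw) * (tot == 0))
  miss <- 1 / (n - k)
  after <- cum_hit - (pos - seq_len(k)) * miss
  before <- c(0, cum_hit[-k]) - (pos - seq_len(k)) * miss  # just before each hit
  cand <- c(after, before)
  cand[which.max(abs(cand))]
}

#' GSEA enrichment score with running-sum profile
#'
#' Weighted Kolmogorov-Smirnov-style enrichment score: walking down the
#' ranked list, the running sum gains `|metric|^p / sum of hit |metric|^p`
#' at set members and loses `1 / (N - N_hits)` elsewhere; the ES is the
#' signed maximum deviation from zero. The running sum starts and ends at
#' zero.
#'
#' @param ranked A [rank_metric()] result (or data frame with `feature_id`,
#'   `metric` in ranked order).
#' @param set Character vector of member identifiers; must intersect the
#'   ranked universe.
#' @param p Weighting exponent (1 = classic weighted; 0 = unweighted).
#' @return List with `es`, `running` (length-N profile), and `positions`
#'   (hit positions in the ranked list).
#' @export
gsea_es <- function(ranked, set, p = 1) {
  ids <- ranked$feature_id
  n <- length(ids)
  hit <- ids %in% set
  k <- sum(hit)
  if (k == 0) stop("undefined enrichment score: empty intersection", call. = FALSE)
  if (k >= n) stop("invalid set: as large as the ranked universe", call. = FALSE)
  aw <- abs(ranked$metric)^p
  tot <- sum(aw[hit])
  incr <- rep(-1 / (n - k), n)
  incr[hit] <- if (tot > 0) aw[hit] / tot else 1 / k
  running <- cumsum(incr)
  es <- running[which.max(abs(running))]
  list(es = es, running = running, positions = which(hit))
}

#' Preranked GSEA over a gene-set collection
#'
#' For each set, the observed ES is compared to a null of `n_perm` ES
#' values from random same-size draws out of the ranked universe. The NES
#' divides the ES by the mean magnitude of same-sign null ES; the nominal P
#' is the fraction of same-sign null ES at least as extreme. The FDR is the
#' pooled-null procedure: all null ES are NES-normalised with their own
#' set's same-sign null mean and pooled, and for each observed NES the FDR
#' is the pooled-null tail fraction over the observed tail fraction (capped
#' at 1), computed separately for positive and negative scores.
#'
#' @param ranked A [rank_metric()] result.
#' @param collection Named list of gene sets (see [gene_set_collection()]);
#'   sets with no member in the ranked universe are dropped with a warning.
#' @param p Weighting exponent.
#' @param n_perm Number of random-set permutations (>= 100).
#' @param seed Integer seed for the permutation draws.
#' @param comparison Comparison identifier carried into the result.
#' @return Data frame: `set`, `size`, `es`, `nes`, `p`, `pfdr`, `method`,
#'   `comparison`. Sets whose same-sign null is empty get `nes = NA` and
#'   `pfdr = 1` with a warning.
#' @export
gsea_preranked <- function(ranked, collection, p = 1, n_perm = 1000,
                           seed = 1L, comparison = "") {
  if (n_perm < 100) stop("n_perm must be >= 100", call. = FALSE)
  ids <- ranked$feature_id
  n <- length(ids)
  aw <- abs(ranked$metric)^p
  sets <- lapply(collection, function(s) which(ids %in% s))
  sizes <- lengths(sets)
  if (any(sizes == 0)) {
    warning("dropping sets with no member in the ranked universe: ",
            paste(names(sets)[sizes == 0], collapse = ", "))
    sets <- sets[sizes > 0]
    sizes <- sizes[sizes > 0]
  }
  if (any(sizes >= n)) {
    stop("invalid set: at least as large as the ranked universe", call. = FALSE)
  }
  if (!length(sets)) {
    return(data.frame(set = character(), size = integer(), es = numeric(),
                      nes = numeric(), p = numeric(), pfdr = numeric(),
                      method = character(), comparison = character(),
                      stringsAsFactors = FALSE))
  }
  set.seed(as.integer(seed))
  es_obs <- vapply(sets, function(pos) es_from_positions(aw, pos), numeric(1))
  null_es <- lapply(sizes, function(k) {
    vapply(seq_len(n_perm),
           function(i) es_from_positions(aw, sample.int(n, k)), numeric(1))
  })
  norm_pos <- vapply(null_es, function(e) mean(e[e > 0]), numeric(1))
  norm_neg <- vapply(null_es, function(e) mean(abs(e[e < 0])), numeric(1))
  nes <- p_nom <- rep(NA_real_, length(sets))
  for (i in seq_along(sets)) {
    e <- es_obs[i]; nul <- null_es[[i]]
    if (e >= 0) {
      same <- nul[nul >= 0]
      if (!length(same) || is.na(norm_pos[i])) next
      nes[i] <- e / norm_pos[i]
      p_nom[i] <- sum(same >= e) / length(same)
    } else {
      same <- nul[nul < 0]
      if (!length(same) || is.na(norm_neg[i])) next
      nes[i] <- e / norm_neg[i]
      p_nom[i] <- sum(same <= e) / length(same)
    }
  }
  # pooled-null FDR on the NES scale
  null_nes <- unlist(lapply(seq_along(sets), function(i) {
    e <- null_es[[i]]
    out <- rep(NA_real_, length(e))
    if (!is.na(norm_pos[i])) out[e >= 0] <- e[e >= 0] / norm_pos[i]
    if (!is.na(norm_neg[i])) out[e < 0] <- e[e < 0] / norm_neg[i]
    out
  }))
  null_nes <- null_nes[!is.na(null_nes)]
  obs <- nes[!is.na(nes)]
  pfdr <- rep(1, length(sets))
  for (i in seq_along(sets)) {
    if (is.na(nes[i])) next
    if (nes[i] >= 0) {
      num_den <- sum(null_nes >= nes[i]) / max(1, sum(null_nes >= 0))
      den <- sum(obs >= nes[i]) / max(1, sum(obs >= 0))
    } else {
      num_den <- sum(null_nes <= nes[i]) / max(1, sum(null_nes < 0))
      den <- sum(obs <= nes[i]) / max(1, sum(obs < 0))
    }
    pfdr[i] <- if (den > 0) min(1, num_den / den) else 1
  }
  if (any(is.na(nes))) {
    warning("sets with an empty same-sign null: NES undefined, PFDR set to 1")
  }
  data.frame(set = names(sets), size = as.integer(sizes), es = es_obs,
             nes = nes, p = p_nom, pfdr = pfdr, method = "gsea",
             comparison = comparison, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Hypergeometric overrepresentation test
#'
#' Upper-tail hypergeometric probability of observing at least the realised
#' overlap between a DE set and a gene set within a finite universe, with
#' the fold enrichment `(k / |de|) / (|set in universe| / |universe|)`.
#'
#' @param de_set DE feature identifiers; must be a subset of `universe`.
#' @param universe All testable feature identifiers.
#' @param set Gene-set members (intersected with the universe).
#' @return List with `p`, `overlap`, `set_size` (in-universe),
#'   `fold_enrichment`.
#' @export
hypergeom_ora <- function(de_set, universe, set) {
  de_set <- unique(de_set); universe <- unique(universe)
  if (!length(universe) || !length(de_set)) {
    stop("invalid input: empty universe or DE set", call. = FALSE)
  }
  if (!all(de_set %in% universe)) {
    stop("DE set must be a subset of the universe", call. = FALSE)
  }
  set_u <- intersect(unique(set), universe)
  k <- length(intersect(de_set, set_u))
  K <- length(set_u); n <- length(de_set); N <- length(universe)
  p <- if (K == 0) 1 else
    stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  fe <- if (K == 0) NA_real_ else (k / n) / (K / N)
  list(p = p, overlap = k, set_size = K, fold_enrichment = fe)
}

#' Report the top overrepresented sets
#'
#' BH-adjusts ORA P-values across sets, keeps sets with adjusted P below
#' `fdr`, and truncates to the `top_n` most significant (ordered by
#' adjusted P, then nominal P, then set name). An empty report is a valid
#' result, not an error.
#'
#' @param results Data frame with columns `set` and `p` (one row per set);
#'   other columns are carried along.
#' @param top_n Maximum number of sets reported.
#' @param fdr Adjusted-P threshold (strict `<`).
#' @return The filtered, ordered data frame with an added `pfdr` column.
#' @export
ora_report <- function(results, top_n = 100, fdr = 0.05) {
  results$pfdr <- bh_adjust(results$p)
  keep <- results[results$pfdr < fdr, , drop = FALSE]
  keep <- keep[order(keep$pfdr, keep$p, keep$set), , drop = FALSE]
  rownames(keep) <- NULL
  utils::head(keep, top_n)
}

#' Signed regulon
#'
#' A regulator with its target features and edge signs (+1 activating,
#' -1 repressing), the input to [activation_zscore()].
#'
#' @param regulator Regulator name.
#' @param targets Named numeric vector: target identifier -> edge sign in
#'   `{+1, -1}`; names must be unique.
#' @return An object of class `"signed_regulon"`.
#' @export
signed_regulon <- function(regulator, targets) {
  if (is.null(names(targets)) || anyDuplicated(names(targets))) {
    stop("targets must be uniquely named", call. = FALSE)
  }
  if (!all(targets %in% c(-1, 1))) {
    stop("edge signs must be +1 or -1", call. = FALSE)
  }
  structure(list(regulator = regulator, targets = targets),
            class = "signed_regulon")
}

#' Activation z-score of a regulator
#'
#' Over the regulon targets found in the DE set, each target contributes
#' `edge sign x DE direction` (+1 when the observed direction is consistent
#' with activation, -1 otherwise); the score is the sum over the square
#' root of the overlap size, approximately standard normal when directions
#' are random.
#'
#' @param regulon A [signed_regulon()].
#' @param directions Named numeric vector of DE directions (+1/-1) by
#'   feature identifier; must overlap the regulon targets.
#' @return List with `z`, `n_overlap`, `regulator`.
#' @export
activation_zscore <- function(regulon, directions) {
  stopifnot(inherits(regulon, "signed_regulon"))
  common <- intersect(names(regulon$targets), names(directions))
  if (!length(common)) {
    stop("undefined activation score: no regulon target in the DE set",
         call. = FALSE)
  }
  consistency <- regulon$targets[common] * directions[common]
  list(z = sum(consistency) / sqrt(length(common)),
       n_overlap = length(common),
       regulator = regulon$regulator)
}
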