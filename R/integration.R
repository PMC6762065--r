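# Convergence layer: cross-strain direction concordance, multi-comparison
# pathway and regulator selection rules, cross-omics molecule overlap,
# same-direction miRNA-target pairing, cross-tissue correlation, the
# multi-data-set GSEA summary filter, and union heatmap ordering.

#' Cross-strain direction concordance of DE features
#'
#' Intersects the DE (flagged) feature sets of two strains and compares
#' fold-change directions. The two-sided binomial P tests the
#' same-direction count against chance (p = 0.5).
#'
#' @param de_a,de_b DE tables for the same contrast in two strains; flagged
#'   internally with [de_flag()] at the supplied thresholds.
#' @param p_thresh,fc_thresh DE thresholds passed to [de_flag()].
#' @return List of class `"concordance_summary"`: `common` (feature ids),
#'   `n_same`, `n_opposite`, `fraction_opposite`, `p_binomial` (NA when the
#'   intersection is empty).
#' @export
cross_strain_concordance <- function(de_a, de_b, p_thresh = 0.05,
                                     fc_thresh = 1.2) {
  fa <- de_flag(de_a, p_thresh, fc_thresh)
  fb <- de_flag(de_b, p_thresh, fc_thresh)
  common <- intersect(fa$feature_id, fb$feature_id)
  if (!length(common)) {
    return(structure(list(common = character(), n_same = 0L, n_opposite = 0L,
                          fraction_opposite = NA_real_,
                          p_binomial = NA_real_),
                     class = "concordance_summary"))
  }
  da <- fa$direction[match(common, fa$feature_id)]
  db <- fb$direction[match(common, fb$feature_id)]
  n_same <- sum(da == db)
  n_opp <- length(common) - n_same
  structure(list(common = common, n_same = n_same, n_opposite = n_opp,
                 fraction_opposite = n_opp / length(common),
                 p_binomial = stats::binom.test(n_same, length(common),
                                                p = 0.5)$p.value),
            class = "concordance_summary")
}

#' @export
print.concordance_summary <- function(x, ...) {
  cat(sprintf("concordance: %d common DE features (%d same / %d opposite",
              length(x$common), x$n_same, x$n_opposite))
  if (!is.na(x$p_binomial)) cat(sprintf(", binomial P = %.3g", x$p_binomial))
  cat(")\n")
  invisible(x)
}

#' Select pathways converging across comparisons
#'
#' A pathway is selected when it is FDR-significant (`pfdr < fdr`) in at
#' least `fdr_hits` comparisons AND nominally significant (`p < nominal`)
#' in at least `nominal_hits` comparisons. Comparisons a pathway is missing
#' from count as non-significant.
#'
#' @param grid Long data frame with columns `pathway`, `comparison`, `p`,
#'   `pfdr` (one row per pathway x comparison where a result exists).
#' @param fdr_hits,nominal_hits Required numbers of significant comparisons.
#' @param fdr,nominal Significance thresholds (strict `<`).
#' @return Data frame per pathway: `pathway`, `n_fdr`, `n_nominal`,
#'   `selected`; ordered by pathway name.
#' @export
pathway_convergence <- function(grid, fdr_hits = 2, nominal_hits = 4,
                                fdr = 0.05, nominal = 0.05) {
  if (!nrow(grid)) stop("invalid input: empty pathway grid", call. = FALSE)
  n_fdr <- tapply(grid$pfdr < fdr, grid$pathway, sum)
  n_nom <- tapply(grid$p < nominal, grid$pathway, sum)
  pathways <- sort(names(n_fdr))
  data.frame(pathway = pathways,
             n_fdr = as.integer(n_fdr[pathways]),
             n_nominal = as.integer(n_nom[pathways]),
             selected = as.integer(n_fdr[pathways]) >= fdr_hits &
                        as.integer(n_nom[pathways]) >= nominal_hits,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Select upstream regulators recurrent across comparisons
#'
#' A regulator is selected when it is FDR-significant in at least
#' `ceiling(fraction * n_comparisons)` comparisons.
#'
#' @param grid Long data frame with columns `regulator`, `comparison`,
#'   `pfdr`.
#' @param fraction Required fraction of all comparisons.
#' @param fdr Significance threshold (strict `<`).
#' @param n_comparisons Total number of comparisons; defaults to the number
#'   of distinct comparisons in the grid.
#' @return Data frame per regulator: `regulator`, `n_significant`,
#'   `required`, `selected`.
#' @export
regulator_selection <- function(grid, fraction = 0.25, fdr = 0.05,
                                n_comparisons = NULL) {
  if (!nrow(grid)) stop("invalid input: empty regulator grid", call. = FALSE)
  if (is.null(n_comparisons)) n_comparisons <- length(unique(grid$comparison))
  required <- ceiling(fraction * n_comparisons)
  n_sig <- tapply(grid$pfdr < fdr, grid$regulator, sum)
  regulators <- sort(names(n_sig))
  data.frame(regulator = regulators,
             n_significant = as.integer(n_sig[regulators]),
             required = required,
             selected = as.integer(n_sig[regulators]) >= required,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Cross-omics molecule overlap
#'
#' Finds molecules differentially expressed in the SAME (strain, contrast)
#' comparison in at least two data sets (e.g. mRNA and protein), with
#' identifiers harmonised case-insensitively. Each overlapping molecule is
#' annotated with the gene-set categories it belongs to and whether it
#' passes the display filter (`P < display_p`) in at least one comparison.
#'
#' @param de_long Long DE table across data sets with columns `feature_id`,
#'   `dataset`, `strain`, `contrast`, `logFC`, `P`.
#' @param display_p Display filter threshold on the nominal P.
#' @param p_thresh,fc_thresh DE thresholds (as in [de_flag()]).
#' @param categories Optional named list: category label -> member
#'   identifiers (matched case-insensitively).
#' @return Data frame: `molecule` (upper-cased key), `strain`, `contrast`,
#'   `datasets` (comma-separated), `n_datasets`, `category`,
#'   `passes_display`.
#' @export
cross_omics_overlap <- function(de_long, display_p = 0.01, p_thresh = 0.05,
                                fc_thresh = 1.2, categories = NULL) {
  needed <- c("feature_id", "dataset", "strain", "contrast", "logFC", "P")
  missing_cols <- setdiff(needed, names(de_long))
  if (length(missing_cols)) {
    stop("DE table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  de_long$key <- toupper(de_long$feature_id)
  if (length(unique(de_long$dataset)) > 1) {
    by_ds <- split(de_long$key, de_long$dataset)
    shared <- Reduce(intersect, by_ds)
    if (!length(shared)) {
      stop("join error: no shared identifiers between data sets ",
           paste(names(by_ds), collapse = ", "), call. = FALSE)
    }
  }
  flagged <- de_long[de_long$P < p_thresh &
                     abs(de_long$logFC) >= log2(fc_thresh), , drop = FALSE]
  if (!nrow(flagged)) {
    return(data.frame(molecule = character(), strain = character(),
                      contrast = character(), datasets = character(),
                      n_datasets = integer(), category = character(),
                      passes_display = logical(), stringsAsFactors = FALSE))
  }
  cells <- split(flagged,
                 list(flagged$key, flagged$strain, flagged$contrast),
                 drop = TRUE)
  rows <- lapply(cells, function(d) {
    ds <- unique(d$dataset)
    if (length(ds) < 2) return(NULL)
    data.frame(molecule = d$key[1], strain = d$strain[1],
               contrast = d$contrast[1],
               datasets = paste(sort(ds), collapse = ","),
               n_datasets = length(ds), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(molecule = character(), strain = character(),
                      contrast = character(), datasets = character(),
                      n_datasets = integer(), category = character(),
                      passes_display = logical(), stringsAsFactors = FALSE))
  }
  cat_of <- function(key) {
    if (is.null(categories)) return(NA_character_)
    hit <- names(categories)[vapply(categories,
                                    function(m) key %in% toupper(m),
                                    logical(1))]
    if (length(hit)) paste(hit, collapse = ",") else NA_character_
  }
  out$category <- vapply(out$molecule, cat_of, character(1))
  min_p <- tapply(de_long$P, de_long$key, min)
  out$passes_display <- min_p[out$molecule] < display_p
  out <- out[order(out$molecule, out$strain, out$contrast), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Same-direction miRNA-target pairs with strong evidence
#'
#' Retains (miRNA, mRNA) pairs that appear in the interaction table with at
#' least `min_sources` evidence sources, whose members are both DE in the
#' queried comparison, and whose fold-change directions match (a repressed
#' target co-precipitating with its repressing miRNA moves with it in
#' these data).
#'
#' @param de_mirna,de_mrna DE tables; flagged internally via [de_flag()].
#' @param interactions Data frame with columns `mirna`, `target`,
#'   `n_sources`.
#' @param min_sources Evidence-source threshold (inclusive; the default 3
#'   encodes "more than two sources").
#' @param p_thresh,fc_thresh DE thresholds.
#' @return Data frame: `mirna`, `target`, `n_sources`, `mirna_logFC`,
#'   `target_logFC`, `direction`; ordered by miRNA then target, invariant
#'   to the row order of `interactions`.
#' @export
mirna_target_pairs <- function(de_mirna, de_mrna, interactions,
                               min_sources = 3, p_thresh = 0.05,
                               fc_thresh = 1.2) {
  if (is.null(interactions) || !nrow(interactions)) {
    stop("invalid input: empty interaction table", call. = FALSE)
  }
  fm <- de_flag(de_mirna, p_thresh, fc_thresh)
  fg <- de_flag(de_mrna, p_thresh, fc_thresh)
  tab <- interactions[interactions$n_sources >= min_sources &
                      interactions$mirna %in% fm$feature_id &
                      interactions$target %in% fg$feature_id, , drop = FALSE]
  if (!nrow(tab)) {
    return(data.frame(mirna = character(), target = character(),
                      n_sources = integer(), mirna_logFC = numeric(),
                      target_logFC = numeric(), direction = numeric(),
                      stringsAsFactors = FALSE))
  }
  dm <- fm$direction[match(tab$mirna, fm$feature_id)]
  dg <- fg$direction[match(tab$target, fg$feature_id)]
  tab <- tab[dm == dg, , drop = FALSE]
  out <- data.frame(mirna = tab$mirna, target = tab$target,
                    n_sources = tab$n_sources,
                    mirna_logFC = fm$logFC[match(tab$mirna, fm$feature_id)],
                    target_logFC = fg$logFC[match(tab$target, fg$feature_id)],
                    stringsAsFactors = FALSE)
  out$direction <- sign(out$mirna_logFC)
  out <- out[order(out$mirna, out$target), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Correlation of expression responses between two tissues
#'
#' Pearson correlation of per-feature values (log2 fold changes from DE
#' tables, or any named numeric vectors such as mean log expression)
#' between two tissues, over a feature subset. When `features` is not
#' given, it defaults to the features nominally DE (`P < select_p`) in the
#' first table and present in the second -- the "DE in tissue 1, expressed
#' in tissue 2" selection.
#'
#' @param x1,x2 DE tables (with `feature_id`, `logFC`, `P`) or named
#'   numeric vectors.
#' @param features Optional feature subset.
#' @param select_p Nominal-P selection threshold used when `features` is
#'   missing and `x1` is a DE table.
#' @return List with `r`, `p` (t-transform, n - 2 df), `n`.
#' @export
cross_tissue_correlation <- function(x1, x2, features = NULL,
                                     select_p = 0.05) {
  as_vec <- function(x) {
    if (is.data.frame(x)) stats::setNames(x$logFC, x$feature_id) else x
  }
  v1 <- as_vec(x1); v2 <- as_vec(x2)
  if (is.null(features)) {
    features <- names(v1)
    if (is.data.frame(x1)) features <- x1$feature_id[x1$P < select_p]
    features <- intersect(features, names(v2))
  }
  features <- intersect(intersect(features, names(v1)), names(v2))
  if (length(features) < 3) {
    stop("insufficient data: need >= 3 shared features", call. = FALSE)
  }
  ct <- stats::cor.test(v1[features], v2[features], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(features))
}

#' Multi-data-set GSEA summary filter
#'
#' Keeps gene sets FDR-significant (`pfdr < fdr`) in at least
#' `ceiling(fraction * n_comparisons)` comparisons and returns the NES
#' matrix for the kept sets, with cells that are missing or not significant
#' marked `NA` (unavailable).
#'
#' @param enrichment Long enrichment table with columns `set`,
#'   `comparison`, `nes`, `pfdr`.
#' @param fdr FDR threshold (strict `<`; 0.25 is the conventional
#'   exploratory level for GSEA).
#' @param fraction Required fraction of comparisons.
#' @param n_comparisons Total comparisons; defaults to the distinct
#'   comparisons present.
#' @return List with `selected` (set names, alphabetical) and `nes`
#'   (matrix selected sets x comparisons, `NA` where unavailable).
#' @export
gsea_summary_filter <- function(enrichment, fdr = 0.25, fraction = 0.5,
                                n_comparisons = NULL) {
  if (!nrow(enrichment)) stop("invalid input: empty enrichment table",
                              call. = FALSE)
  comparisons <- sort(unique(enrichment$comparison))
  if (is.null(n_comparisons)) n_comparisons <- length(comparisons)
  required <- ceiling(fraction * n_comparisons)
  sig <- !is.na(enrichment$pfdr) & enrichment$pfdr < fdr
  n_sig <- tapply(sig, enrichment$set, sum)
  selected <- sort(names(n_sig)[n_sig >= required])
  nes <- matrix(NA_real_, length(selected), length(comparisons),
                dimnames = list(selected, comparisons))
  keep <- enrichment$set %in% selected & sig
  if (any(keep)) {
    nes[cbind(match(enrichment$set[keep], selected),
              match(enrichment$comparison[keep], comparisons))] <-
      enrichment$nes[keep]
  }
  list(selected = selected, nes = nes)
}

#' Fold-change table for a union heatmap
#'
#' Builds the plotting-ready fold-change matrix for the union of flagged
#' features across the contrasts of one data set, with rows ordered by the
#' fold change in the named contrast (descending; features absent from it
#' sort last) and ties broken by feature identifier.
#'
#' @param de Stacked DE table for one data set covering one or more
#'   contrasts (columns `feature_id`, `logFC`, `FC`, `P`, `contrast`).
#' @param order_by Contrast whose FC orders the rows.
#' @param p_thresh,fc_thresh DE thresholds defining the union.
#' @return Data frame: `feature_id` plus one FC column per contrast
#'   (`NA` where the feature was not measured), ordered for plotting.
#' @export
union_heatmap_table <- function(de, order_by = "susceptible_vs_control",
                                p_thresh = 0.05, fc_thresh = 1.2) {
  flagged <- de_flag(de, p_thresh, fc_thresh)
  features <- sort(unique(flagged$feature_id))
  contrasts <- unique(de$contrast)
  if (!order_by %in% contrasts) {
    stop("`order_by` contrast not present in the DE table", call. = FALSE)
  }
  fc <- matrix(NA_real_, length(features), length(contrasts),
               dimnames = list(features, contrasts))
  keep <- de$feature_id %in% features
  fc[cbind(match(de$feature_id[keep], features),
           match(de$contrast[keep], contrasts))] <- de$FC[keep]
  ord <- order(-fc[, order_by], features, na.last = TRUE)
  out <- data.frame(feature_id = features[ord], fc[ord, , drop = FALSE],
                    stringsAsFactors = FALSE, check.names = FALSE,
                    row.names = NULL)
  out
}
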