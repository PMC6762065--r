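# Differential expression: CPM filtering, log-CPM transform, batch
# mean-centering, empirical-Bayes moderated t with log-F moment-matched
# hyperparameters, BH adjustment, DE flagging, and the proteomics
# inclusion filter.

#' Filter features by counts-per-million abundance
#'
#' Keeps features with CPM at or above `min_cpm` in at least `min_samples`
#' samples, where `CPM = 1e6 * count / library size` and the library size
#' is the column sum.
#'
#' @param x An [omics_matrix()] of counts with positive library sizes.
#' @param min_cpm CPM threshold (inclusive).
#' @param min_samples Minimum number of samples meeting the threshold.
#' @return The filtered [omics_matrix()].
#' @export
cpm_filter <- function(x, min_cpm = 1, min_samples) {
  stopifnot(inherits(x, "omics_matrix"))
  if (x$modality == "protein") {
    stop("cpm_filter applies to count modalities only", call. = FALSE)
  }
  lib <- colSums(x$values)
  if (any(lib == 0)) stop("invalid matrix: zero library size", call. = FALSE)
  cpm <- sweep(x$values, 2, lib, `/`) * 1e6
  keep <- rowSums(cpm >= min_cpm) >= min_samples
  x$values <- x$values[keep, , drop = FALSE]
  x
}

#' log2 counts-per-million
#'
#' `log2((count + 0.5) / (library size + 1) * 1e6)`; the 0.5/1 offsets keep
#' zero counts finite while leaving abundant features essentially on the
#' log-CPM scale.
#'
#' @param x An [omics_matrix()] of counts.
#' @return The same object with `values` replaced by log2-CPM (modality
#'   unchanged, but values are no longer counts; downstream functions treat
#'   them as log-scale).
#' @export
log_cpm <- function(x) {
  stopifnot(inherits(x, "omics_matrix"))
  lib <- colSums(x$values)
  x$values <- log2(sweep(x$values + 0.5, 2, lib + 1, `/`) * 1e6)
  attr(x, "log_scale") <- TRUE
  x
}

#' Remove additive batch effects by per-batch mean-centering
#'
#' For each feature, subtracts the batch mean and adds back the feature's
#' grand mean, removing location-shift batch effects exactly while
#' preserving feature-wise grand means. A single batch is the identity.
#'
#' @param x An [omics_matrix()] on the log scale, or a numeric matrix.
#' @param batch Batch labels, one per sample; taken from the metadata if
#'   `x` is an `omics_matrix` and `batch` is missing.
#' @return Object of the same kind with adjusted values.
#' @export
batch_center <- function(x, batch = NULL) {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  if (is.null(batch) && inherits(x, "omics_matrix")) batch <- x$samples$batch
  if (length(batch) != ncol(m)) {
    stop("`batch` must give one label per sample", call. = FALSE)
  }
  grand <- rowMeans(m)
  for (b in unique(batch)) {
    j <- batch == b
    m[, j] <- m[, j, drop = FALSE] - rowMeans(m[, j, drop = FALSE]) + grand
  }
  if (inherits(x, "omics_matrix")) { x$values <- m; x } else m
}

#' Median-center log-ratio columns
#'
#' Per-sample median-centering of a log-ratio matrix, the location-only
#' normalization used for the proteomics layer.
#'
#' @param x An [omics_matrix()] (protein modality) or numeric matrix.
#' @return Object of the same kind, each column shifted to median zero.
#' @export
median_center <- function(x) {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  m <- sweep(m, 2, apply(m, 2, stats::median))
  if (inherits(x, "omics_matrix")) { x$values <- m; x } else m
}

# Invert the trigamma function by Newton iteration (monotone decreasing on
# (0, Inf)); returns NA on non-convergence so the caller can fall back.
trigamma_inverse <- function(y, tol = 1e-8, max_iter = 100L) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in seq_len(max_iter)) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, deriv = 2)
    x <- x + dif
    if (-dif / x < tol) return(x)
  }
  NA_real_
}

# Moment-match log residual variances to a scaled log-F distribution:
# s_g^2 ~ s0^2 F(df, d0). Returns the prior df d0 and prior variance s0^2.
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) stop("degenerate variances: no positive residual variances",
                     call. = FALSE)
  z <- log(s2[ok])
  e <- z - digamma(df / 2) + log(df / 2)
  emean <- mean(e)
  evar <- stats::var(e) - trigamma(df / 2)
  if (is.na(evar) || evar <= 0) {
    # no excess spread in the log variances: infinite prior df, and the
    # prior variance is the plain mean so full shrinkage keeps t ordinary
    # when all gene variances agree
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  }
  half_d0 <- trigamma_inverse(evar)
  if (is.na(half_d0)) {
    warning("prior df estimation did not converge; using d0 = Inf")
    return(list(d0 = Inf, s02 = mean(s2[ok])))
  }
  d0 <- 2 * half_d0
  list(d0 = d0, s02 = exp(emean + digamma(half_d0) - log(half_d0)))
}

#' Empirical-Bayes moderated t-test for one two-group contrast
#'
#' Per feature, ordinary least squares on the two contrasted groups gives
#' the log2 fold change and a residual variance `s_g^2` on `n1 + n2 - 2`
#' degrees of freedom. The gene-wise variances are shrunk towards a prior:
#' `(d0, s0^2)` are estimated by matching the first two moments of
#' `log s_g^2` to a scaled log-F distribution (trigamma inversion by Newton
#' iteration; non-convergence falls back to `d0 = Inf` with a warning), the
#' posterior variance is `(d0 s0^2 + df s_g^2) / (d0 + df)`, and the
#' moderated t is the mean difference over its posterior standard error,
#' referred to a t distribution on `d0 + df` degrees of freedom (capped at
#' the pooled residual df).
#'
#' @param x An [omics_matrix()] on the log scale, or a numeric log-scale
#'   matrix.
#' @param groups Group label per sample; taken from metadata if `x` is an
#'   `omics_matrix` and `groups` is missing.
#' @param contrast Length-2 character: the contrast `groups[1] - groups[2]`
#'   (e.g. `c("susceptible", "control")`). Each side needs >= 2 samples.
#' @param dataset Data-set identifier carried into the result.
#' @return Data frame (one row per feature): `feature_id`, `logFC`, `FC`
#'   (signed linear fold change: `2^logFC` when positive, `-2^|logFC|` when
#'   negative), `t`, `P`, `Padj` (BH), `contrast`, `dataset`; with
#'   attribute `"hyperparams"` holding `d0` and `s02`.
#' @export
fit_moderated_t <- function(x, groups = NULL,
                            contrast = c("susceptible", "control"),
                            dataset = "") {
  m <- if (inherits(x, "omics_matrix")) x$values else x
  if (is.null(groups) && inherits(x, "omics_matrix")) groups <- x$samples$group
  if (length(groups) != ncol(m)) {
    stop("`groups` must give one label per sample", call. = FALSE)
  }
  if (length(contrast) != 2) stop("`contrast` must name two groups", call. = FALSE)
  j1 <- which(groups == contrast[1]); j2 <- which(groups == contrast[2])
  if (length(j1) < 2 || length(j2) < 2) {
    stop("insufficient replication: both contrasted groups need >= 2 samples",
         call. = FALSE)
  }
  n1 <- length(j1); n2 <- length(j2)
  m1 <- rowMeans(m[, j1, drop = FALSE]); m2 <- rowMeans(m[, j2, drop = FALSE])
  rss <- rowSums((m[, j1, drop = FALSE] - m1)^2) +
         rowSums((m[, j2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  s2 <- rss / df
  if (all(s2 == 0)) {
    stop("degenerate variances: all residual variances are zero", call. = FALSE)
  }
  prior <- fit_variance_prior(s2, df)
  s2_post <- if (is.infinite(prior$d0)) {
    rep(prior$s02, length(s2))
  } else {
    (prior$d0 * prior$s02 + df * s2) / (prior$d0 + df)
  }
  logfc <- m1 - m2
  tstat <- logfc / sqrt(s2_post * (1 / n1 + 1 / n2))
  df_total <- min(prior$d0 + df, length(s2) * df)
  p <- 2 * stats::pt(-abs(tstat), df = df_total)
  res <- data.frame(
    feature_id = rownames(m),
    logFC = logfc,
    FC = ifelse(logfc >= 0, 2^logfc, -2^(-logfc)),
    t = tstat,
    P = p,
    Padj = bh_adjust(p),
    contrast = paste0(contrast[1], "_vs_", contrast[2]),
    dataset = dataset,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  attr(res, "hyperparams") <- list(d0 = prior$d0, s02 = prior$s02, df = df)
  res
}

#' Benjamini-Hochberg adjusted P-values
#'
#' Step-up BH false-discovery-rate adjustment: sort ascending, take
#' `q_(i) = min over j >= i of (m / j) p_(j)` capped at 1, and return in the
#' input order.
#'
#' @param p Vector of P-values.
#' @return Adjusted P-values, same order as the input.
#' @export
bh_adjust <- function(p) {
  stats::p.adjust(p, method = "BH")
}

#' Flag differentially expressed features
#'
#' A feature is DE when `P < p_thresh` (strict) and the linear fold change
#' magnitude is at least `fc_thresh` (inclusive), i.e.
#' `|logFC| >= log2(fc_thresh)`.
#'
#' @param de A DE result table from [fit_moderated_t()] (needs `feature_id`,
#'   `logFC`, `P`).
#' @param p_thresh Nominal P threshold (strict `<`).
#' @param fc_thresh Linear fold-change threshold (inclusive `>=`).
#' @return The flagged subset of `de` with an added `direction` column
#'   (`sign(logFC)`).
#' @export
de_flag <- function(de, p_thresh = 0.05, fc_thresh = 1.2) {
  keep <- de$P < p_thresh & abs(de$logFC) >= log2(fc_thresh)
  out <- de[keep, , drop = FALSE]
  out$direction <- sign(out$logFC)
  rownames(out) <- NULL
  out
}

#' Proteomics inclusion filter
#'
#' Retains proteins identified by at least `min_peptides` unique peptides in
#' at least `min_replicates` of the technical replicates and whose
#' replicate-to-replicate H/L ratio coefficient of variation is below
#' `max_cv`, in every sample. The retained value per protein and sample is
#' the log2 of the mean H/L ratio across the qualifying replicates (those
#' meeting the peptide rule).
#'
#' @param replicates Long replicate table with columns `protein_id`,
#'   `sample_id`, `replicate`, `n_unique_peptides`, `hl_ratio` (linear
#'   scale), as produced by [simulate_proteomics()].
#' @param samples Optional sample metadata sheet; when supplied the result
#'   is an [omics_matrix()] with `modality = "protein"`, otherwise a plain
#'   matrix.
#' @param min_peptides Unique-peptide threshold per replicate (inclusive).
#' @param min_replicates Number of replicates that must meet it (inclusive).
#' @param max_cv Strict upper bound on the replicate CV (0.30 = 30%).
#' @return Protein-by-sample log2 H/L matrix restricted to retained
#'   proteins, with attribute `"dropped"` (data frame of protein and
#'   reason); an `omics_matrix` when `samples` is given.
#' @export
filter_proteins <- function(replicates, samples = NULL,
                            min_peptides = 2, min_replicates = 2,
                            max_cv = 0.30) {
  needed <- c("protein_id", "sample_id", "replicate", "n_unique_peptides",
              "hl_ratio")
  missing_cols <- setdiff(needed, names(replicates))
  if (length(missing_cols)) {
    stop("invalid replicate table: lacks columns ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n_rep <- length(unique(replicates$replicate))
  if (n_rep < 2) {
    stop("invalid replicate table: need >= 2 technical replicates", call. = FALSE)
  }
  prot <- unique(replicates$protein_id)
  samp <- unique(replicates$sample_id)
  value <- matrix(NA_real_, length(prot), length(samp),
                  dimnames = list(prot, samp))
  pass <- matrix(FALSE, length(prot), length(samp),
                 dimnames = list(prot, samp))
  reason <- matrix(NA_character_, length(prot), length(samp))
  key <- split(seq_len(nrow(replicates)),
               list(replicates$protein_id, replicates$sample_id), drop = TRUE)
  for (cell in names(key)) {
    idx <- key[[cell]]
    pid <- replicates$protein_id[idx[1]]
    sid <- replicates$sample_id[idx[1]]
    qual <- idx[replicates$n_unique_peptides[idx] >= min_peptides]
    if (length(qual) < min_replicates) {
      reason[match(pid, prot), match(sid, samp)] <- "unique_peptides"
      next
    }
    r <- replicates$hl_ratio[qual]
    cv <- stats::sd(r) / mean(r)
    if (!is.finite(cv) || cv >= max_cv) {
      reason[match(pid, prot), match(sid, samp)] <- "hl_variability"
      next
    }
    pass[match(pid, prot), match(sid, samp)] <- TRUE
    value[match(pid, prot), match(sid, samp)] <- log2(mean(r))
  }
  keep <- rowSums(pass) == ncol(pass)
  dropped <- data.frame(
    protein_id = prot[!keep],
    reason = apply(reason[!keep, , drop = FALSE], 1, function(r) {
      r <- r[!is.na(r)]
      if (length(r)) r[1] else "unknown"
    }),
    stringsAsFactors = FALSE, row.names = NULL
  )
  out <- value[keep, , drop = FALSE]
  if (!is.null(samples)) {
    out <- omics_matrix(out, samples, "protein")
    attr(out, "dropped") <- dropped
  } else {
    attr(out, "dropped") <- dropped
  }
  out
}
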