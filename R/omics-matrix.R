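#' Omics expression container
#'
#' Bundles a feature-by-sample value matrix with its sample metadata and a
#' modality tag. Sequencing modalities (`"mrna"`, `"mirna"`) hold
#' non-negative integer counts; the `"protein"` modality holds log2
#' heavy/light (H/L) isotope-label ratios.
#'
#' @param values Numeric matrix, features in rows (unique rownames required),
#'   samples in columns (colnames required).
#' @param samples Data frame of sample metadata with at least the columns
#'   `sample_id`, `strain`, `tissue`, `group`, `batch`. Every column of
#'   `values` must appear in `samples$sample_id`.
#' @param modality One of `"mrna"`, `"mirna"`, `"protein"`.
#'
#' @return An object of class `"omics_matrix"`: a list with elements
#'   `values`, `samples` (reordered to match the columns) and `modality`.
#' @export
#' @examples
#' meta <- make_sample_sheet(n_per_group = 2, strain = "B6")
#' m <- matrix(rpois(12, 50), nrow = 2,
#'             dimnames = list(c("g1", "g2"), meta$sample_id))
#' omics_matrix(m, meta, "mrna")
omics_matrix <- function(values, samples, modality = c("mrna", "mirna", "protein")) {
  modality <- match.arg(modality)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate feature identifiers in `values`", call. = FALSE)
  }
  required <- c("sample_id", "strain", "tissue", "group", "batch")
  missing_cols <- setdiff(required, names(samples))
  if (length(missing_cols)) {
    stop("sample metadata lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  absent <- setdiff(colnames(values), samples$sample_id)
  if (length(absent)) {
    stop("samples missing from metadata: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (modality != "protein") {
    if (any(values < 0) || any(values != round(values))) {
      stop("count modalities require non-negative integer values", call. = FALSE)
    }
  }
  samples <- samples[match(colnames(values), samples$sample_id), , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(values = values, samples = samples, modality = modality),
            class = "omics_matrix")
}

#' @export
print.omics_matrix <- function(x, ...) {
  cat(sprintf("omics_matrix [%s]: %d features x %d samples\n",
              x$modality, nrow(x$values), ncol(x$values)))
  cat("groups: ", paste(sprintf("%s=%d", names(table(x$samples$group)),
                                table(x$samples$group)), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.omics_matrix <- function(x) dim(x$values)

#' Build a sample metadata sheet
#'
#' Convenience constructor for the per-sample metadata used throughout the
#' package: `n_per_group` samples in each of the phenotype groups, assigned
#' round-robin to `n_batches` library-preparation batches.
#'
#' @param n_per_group Samples per phenotype group.
#' @param strain Strain label (e.g. `"B6"`, `"D2"`).
#' @param tissue Tissue label.
#' @param groups Phenotype group labels.
#' @param n_batches Number of batches samples are cycled through.
#' @return Data frame with columns `sample_id`, `strain`, `tissue`, `group`,
#'   `batch`.
#' @export
make_sample_sheet <- function(n_per_group, strain = "B6", tissue = "BNST",
                              groups = c("control", "susceptible", "resilient"),
                              n_batches = 1) {
  stopifnot(n_per_group >= 1, n_batches >= 1)
  group <- rep(groups, each = n_per_group)
  n <- length(group)
  data.frame(
    sample_id = sprintf("%s_%s_%02d", strain, substr(group, 1, 3),
                        unlist(lapply(rep(n_per_group, length(groups)), seq_len))),
    strain = strain,
    tissue = tissue,
    group = group,
    batch = rep_len(paste0("b", seq_len(n_batches)), n),
    stringsAsFactors = FALSE
  )
}
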