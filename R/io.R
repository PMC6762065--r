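# Readers and writers: GMT gene-set collections and tab-separated matrix,
# metadata, and result tables. Everything is plain text with "NA" as the
# missing-value token.

#' Gene-set collection
#'
#' A named list of feature-identifier vectors with optional descriptions
#' and category labels (e.g. `"mitochondria-related"`).
#'
#' @param sets Named list of non-empty character vectors.
#' @param descriptions Optional character vector, one per set.
#' @param categories Optional character vector of category labels, one per
#'   set.
#' @return Object of class `"gene_set_collection"` (a named list with
#'   `description` and `category` attributes).
#' @export
gene_set_collection <- function(sets, descriptions = NULL, categories = NULL) {
  if (!length(sets) || is.null(names(sets)) || any(names(sets) == "")) {
    stop("sets must be a non-empty named list", call. = FALSE)
  }
  if (any(lengths(sets) == 0)) stop("sets must be non-empty", call. = FALSE)
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  attr(sets, "description") <- stats::setNames(descriptions, names(sets))
  if (!is.null(categories)) {
    attr(sets, "category") <- stats::setNames(categories, names(sets))
  }
  class(sets) <- "gene_set_collection"
  sets
}

#' Read a GMT gene-set file
#'
#' Standard GMT dialect: one set per line, tab-separated fields `name`,
#' `description`, then members. Duplicate members within a line are
#' deduplicated with a warning; a line with fewer than three fields is a
#' parse error naming the line.
#'
#' @param path Path to the GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list(); desc <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("GMT parse error at line ", i, ": fewer than 3 fields", call. = FALSE)
    }
    members <- fields[-(1:2)]
    if (anyDuplicated(members)) {
      warning("duplicate members in set '", fields[1], "' deduplicated")
      members <- unique(members)
    }
    sets[[fields[1]]] <- members
    desc[fields[1]] <- fields[2]
  }
  gene_set_collection(sets, descriptions = desc)
}

#' Write a gene-set collection as GMT
#'
#' @param collection A [gene_set_collection()] or named list of sets.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  desc <- attr(collection, "description")
  lines <- vapply(names(collection), function(nm) {
    d <- if (!is.null(desc) && nzchar(desc[[nm]])) desc[[nm]] else "na"
    paste(c(nm, d, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read an omics matrix and its sample metadata
#'
#' The matrix file is tab-separated with a header row: first column
#' `feature_id`, remaining columns one per sample. The metadata file is
#' tab-separated with columns `sample_id`, `strain`, `tissue`, `group`,
#' `batch`. Validation (metadata coverage, unique identifiers, integer
#' non-negative counts for count modalities) is delegated to
#' [omics_matrix()].
#'
#' @param path Matrix file path.
#' @param meta_path Metadata file path.
#' @param modality Modality tag.
#' @return An [omics_matrix()].
#' @export
read_omics_matrix <- function(path, meta_path,
                              modality = c("mrna", "mirna", "protein")) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "feature_id") {
    stop("matrix file must start with a 'feature_id' column", call. = FALSE)
  }
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab$feature_id
  meta <- utils::read.delim(meta_path, stringsAsFactors = FALSE)
  omics_matrix(values, meta, match.arg(modality))
}

#' Write an omics matrix and its sample metadata
#'
#' @param x An [omics_matrix()].
#' @param path Matrix output path.
#' @param meta_path Metadata output path (skipped when `NULL`).
#' @return `path`, invisibly.
#' @export
write_omics_matrix <- function(x, path, meta_path = NULL) {
  stopifnot(inherits(x, "omics_matrix"))
  tab <- data.frame(feature_id = rownames(x$values), x$values,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(meta_path)) {
    utils::write.table(x$samples, meta_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(path)
}

#' Write a result table as tab-separated text
#'
#' @param x Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a tab-separated result table
#'
#' @param path Input path.
#' @return Data frame.
#' @export
read_result_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
}
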