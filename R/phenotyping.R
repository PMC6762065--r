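# Behavioural phenotyping: SI ratios, log-scale outlier removal,
# susceptible/resilient classification against a control-derived border,
# strain-level susceptibility summaries, and body-weight utilities.

#' Social interaction ratio
#'
#' `100 * time in the interaction zone with the social target / time in the
#' interaction zone without it`. The no-target time must be positive.
#'
#' @param t_no_target,t_target Times in seconds (scalars or vectors); each
#'   must lie within the 150 s trial.
#' @return SI ratio on the percent scale.
#' @export
#' @examples
#' compute_si_ratio(60, 30)  # 50
compute_si_ratio <- function(t_no_target, t_target) {
  if (any(t_no_target < 0) || any(t_target < 0) ||
      any(t_no_target > 150) || any(t_target > 150)) {
    stop("interaction-zone times must lie in [0, 150] seconds", call. = FALSE)
  }
  if (any(t_no_target == 0)) {
    stop("undefined SI ratio: no-target time is zero", call. = FALSE)
  }
  100 * t_target / t_no_target
}

#' Flag SI-ratio outliers on the log scale
#'
#' Ratios are natural-log-transformed (to approximate normality) and values
#' more than 3 interquartile ranges from the median of the log ratios are
#' flagged. A zero IQR flags only values that differ from the median (so a
#' constant vector yields no outliers).
#'
#' @param ratios SI ratios (percent), all positive; at least 4 values so
#'   quartiles are definable.
#' @param k IQR multiplier (default 3).
#' @return Logical outlier mask, same length as `ratios`.
#' @export
remove_si_outliers <- function(ratios, k = 3) {
  if (length(ratios) < 4) {
    stop("insufficient data: need >= 4 ratios to define quartiles", call. = FALSE)
  }
  if (any(ratios <= 0)) stop("SI ratios must be positive", call. = FALSE)
  lr <- log(ratios)
  abs(lr - stats::median(lr)) > k * stats::IQR(lr)
}

#' Classify defeated mice as susceptible or resilient
#'
#' The border is the control group's mean log SI ratio minus one log SD,
#' back-transformed to the percent scale. Defeated mice strictly below the
#' border are susceptible; mice at or above it (i.e. resembling controls)
#' are resilient. Both inputs should already be outlier-filtered.
#'
#' @param control_ratios,defeated_ratios SI ratios (percent); at least two
#'   controls are required.
#' @return List with `labels` (character, one per defeated mouse) and
#'   `border` (percent scale).
#' @export
classify_defeated <- function(control_ratios, defeated_ratios) {
  if (length(control_ratios) < 2) {
    stop("insufficient data: need >= 2 control ratios", call. = FALSE)
  }
  if (any(c(control_ratios, defeated_ratios) <= 0)) {
    stop("SI ratios must be positive", call. = FALSE)
  }
  lc <- log(control_ratios)
  border <- exp(mean(lc) - stats::sd(lc))
  labels <- ifelse(defeated_ratios < border, "susceptible", "resilient")
  list(labels = labels, border = border)
}

#' Strain-level susceptibility percentage
#'
#' `round(100 * n_susceptible / (n_susceptible + n_resilient))`, reported as
#' an integer percent.
#'
#' @param n_susceptible,n_resilient Non-negative counts, not both zero.
#' @return Integer percent.
#' @export
#' @examples
#' susceptibility_percentage(62, 8)   # 89
#' susceptibility_percentage(34, 78)  # 30
susceptibility_percentage <- function(n_susceptible, n_resilient) {
  if (n_susceptible < 0 || n_resilient < 0) {
    stop("counts must be non-negative", call. = FALSE)
  }
  if (n_susceptible + n_resilient == 0) {
    stop("empty group: no defeated mice to summarise", call. = FALSE)
  }
  round(100 * n_susceptible / (n_susceptible + n_resilient))
}

#' Pearson chi-square for a 2x2 strain-by-phenotype table
#'
#' Standard Pearson chi-square without continuity correction, 1 degree of
#' freedom, upper-tail P.
#'
#' @param table 2x2 matrix of counts with positive row and column margins.
#' @return List with `statistic`, `p_value`, `df`.
#' @export
strain_phenotype_chi2 <- function(table) {
  table <- as.matrix(table)
  if (!all(dim(table) == c(2, 2)) || any(table < 0)) {
    stop("need a 2x2 table of non-negative counts", call. = FALSE)
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("degenerate table: a margin is zero", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), p_value = ct$p.value, df = 1L)
}

#' Modified Z-score outlier mask
#'
#' Flags values with `|0.6745 * (x - median) / MAD| > threshold`, the
#' median-based robust outlier rule. When the MAD is zero (more than half
#' the values equal the median) the score falls back to the mean absolute
#' deviation form `|x - median| / (1.253314 * meanAD)`; if that too is zero
#' (constant data) nothing is flagged and a warning is issued.
#'
#' @param values Numeric vector, length >= 3.
#' @param threshold Modified Z-score cut-off (default 3.5).
#' @return Logical outlier mask.
#' @export
modified_zscore_outliers <- function(values, threshold = 3.5) {
  if (length(values) < 3) {
    stop("insufficient data: need >= 3 values", call. = FALSE)
  }
  med <- stats::median(values)
  dev <- abs(values - med)
  mad <- stats::median(dev)
  if (mad > 0) {
    z <- 0.6745 * dev / mad
  } else if (mean(dev) > 0) {
    z <- dev / (1.253314 * mean(dev))
  } else {
    warning("MAD and mean absolute deviation are zero; no outliers flagged")
    return(rep(FALSE, length(values)))
  }
  z > threshold
}

#' Percent-of-baseline body-weight trajectory
#'
#' For each day after the first, `100 * (weight - baseline) / baseline`,
#' with the day-1 weight as baseline.
#'
#' @param weights Numeric vector of weights (grams), day 1 first; at least
#'   two records and a positive baseline.
#' @return Numeric vector of percent change from baseline, one per
#'   subsequent day.
#' @export
weight_trajectory <- function(weights) {
  if (length(weights) < 2) {
    stop("insufficient data: need >= 2 weight records", call. = FALSE)
  }
  if (is.na(weights[1]) || weights[1] <= 0) {
    stop("insufficient data: missing or non-positive baseline weight", call. = FALSE)
  }
  100 * (weights[-1] - weights[1]) / weights[1]
}

#' Phenotype a simulated or recorded cohort
#'
#' Runs the full classification procedure per strain: SI ratios from the
#' trial times, log-scale 3-IQR outlier removal across the strain's mice,
#' and susceptible/resilient calls for the defeated, non-outlier mice
#' against the control-derived border.
#'
#' @param records Behavioural table as produced by [simulate_cohort()]
#'   (columns `mouse_id`, `strain`, `group`, `t_iz_no_target`,
#'   `t_iz_target`).
#' @return List with `calls` (data frame: `mouse_id`, `strain`, `si_ratio`,
#'   `outlier`, `label` in control/susceptible/resilient/excluded) and
#'   `borders` (named per-strain border, percent scale).
#' @export
phenotype_cohort <- function(records) {
  needed <- c("mouse_id", "strain", "group", "t_iz_no_target", "t_iz_target")
  missing_cols <- setdiff(needed, names(records))
  if (length(missing_cols)) {
    stop("behavioural table lacks columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  records$si_ratio <- compute_si_ratio(records$t_iz_no_target,
                                       records$t_iz_target)
  strains <- unique(records$strain)
  borders <- stats::setNames(numeric(length(strains)), strains)
  calls <- vector("list", length(strains))
  for (i in seq_along(strains)) {
    r <- records[records$strain == strains[i], , drop = FALSE]
    out <- remove_si_outliers(r$si_ratio)
    ctl <- r$group == "control"
    cls <- classify_defeated(r$si_ratio[ctl & !out], r$si_ratio[!ctl & !out])
    borders[i] <- cls$border
    label <- rep("excluded", nrow(r))
    label[ctl & !out] <- "control"
    label[!ctl & !out] <- cls$labels
    calls[[i]] <- data.frame(mouse_id = r$mouse_id, strain = r$strain,
                             si_ratio = r$si_ratio, outlier = out,
                             label = label, stringsAsFactors = FALSE)
  }
  list(calls = do.call(rbind, calls), borders = borders)
}
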