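# Synthetic-data generators: behavioural cohorts, negative-binomial count
# matrices, log-normal proteomics ratios, and miRNA-target interaction tables
# with planted, optionally strain-opposite, gene-set effects.

#' Cohort specification for the behavioural simulator
#'
#' Defines the study conditions for [simulate_cohort()]: per-strain sample
#' sizes for the control and defeated arms, the planted susceptible fraction
#' among defeated mice, and the social-interaction (SI) ratio distributions
#' on the natural-log scale. Defaults encode the canonical two-strain CSDS
#' design: a largely resilient strain (30% susceptible, 112 defeated) and a
#' largely susceptible strain (89% susceptible, 70 defeated), 56 controls
#' each, with control SI distributions placed so that the classification
#' border (control log-mean minus one log-SD, back-transformed) falls near
#' 76 and 106 percent respectively.
#'
#' @param strains Strain labels.
#' @param n_control,n_defeated Per-strain sample sizes (non-negative).
#' @param susceptible_fraction Per-strain probability that a defeated mouse
#'   is drawn from the susceptible SI distribution; in `[0, 1]`.
#' @param control_log_mean,control_log_sd Mean and SD of log SI ratio
#'   (percent scale inside the log) for control mice; SD must be positive.
#' @param susceptible_offset,resilient_offset Log-scale shifts applied to the
#'   control mean for defeated mice drawn as susceptible or resilient.
#' @param seed Integer seed; all randomness in [simulate_cohort()] derives
#'   from it.
#' @return An object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(strains = c("B6", "D2"),
                        n_control = c(56, 56),
                        n_defeated = c(112, 70),
                        susceptible_fraction = c(0.30, 0.89),
                        control_log_mean = log(c(103, 143)),
                        control_log_sd = c(0.30, 0.30),
                        susceptible_offset = -1.2,
                        resilient_offset = 0.4,
                        seed = 1L) {
  k <- length(strains)
  rec <- function(x) rep_len(x, k)
  n_control <- rec(n_control); n_defeated <- rec(n_defeated)
  susceptible_fraction <- rec(susceptible_fraction)
  control_log_mean <- rec(control_log_mean)
  control_log_sd <- rec(control_log_sd)
  if (any(susceptible_fraction < 0 | susceptible_fraction > 1)) {
    stop("invalid cohort spec: susceptible_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (any(n_control < 0) || any(n_defeated < 0)) {
    stop("invalid cohort spec: sample sizes must be >= 0", call. = FALSE)
  }
  if (any(n_defeated == 0 & susceptible_fraction > 0)) {
    stop("invalid cohort spec: positive susceptible_fraction requires defeated mice",
         call. = FALSE)
  }
  if (any(control_log_sd <= 0)) {
    stop("invalid cohort spec: control_log_sd must be > 0", call. = FALSE)
  }
  structure(list(strains = strains, n_control = n_control,
                 n_defeated = n_defeated,
                 susceptible_fraction = susceptible_fraction,
                 control_log_mean = control_log_mean,
                 control_log_sd = control_log_sd,
                 susceptible_offset = susceptible_offset,
                 resilient_offset = resilient_offset,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Simulate a behavioural CSDS cohort
#'
#' Draws SI ratios for control and defeated mice per strain. Defeated mice
#' are a mixture: with probability `susceptible_fraction` the log SI ratio
#' comes from the susceptible distribution (control mean plus
#' `susceptible_offset`), otherwise from the resilient one. Interaction-zone
#' times are back-computed so that [compute_si_ratio()] reproduces the drawn
#' ratio exactly: the no-target trial time is fixed at 30 s and the target
#' trial time is `ratio / 100 * 30` s (capped at the 150 s trial length).
#'
#' @param spec A [cohort_spec()].
#' @return Data frame of behavioural records: `mouse_id`, `strain`, `group`
#'   (`control`/`defeated`), `t_iz_no_target`, `t_iz_target` (seconds), and
#'   `planted_label` recording the generating mixture component (the ground
#'   truth a classifier should recover).
#' @export
simulate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  out <- vector("list", length(spec$strains))
  for (i in seq_along(spec$strains)) {
    st <- spec$strains[i]
    mu <- spec$control_log_mean[i]; sd <- spec$control_log_sd[i]
    nc <- spec$n_control[i]; nd <- spec$n_defeated[i]
    ctl <- rnorm(nc, mu, sd)
    sus <- rbinom(nd, 1, spec$susceptible_fraction[i]) == 1
    def <- ifelse(sus,
                  rnorm(nd, mu + spec$susceptible_offset, sd),
                  rnorm(nd, mu + spec$resilient_offset, sd))
    ratio <- exp(c(ctl, def))
    no_target <- rep(30, nc + nd)
    target <- pmin(ratio / 100 * no_target, 150)
    out[[i]] <- data.frame(
      mouse_id = sprintf("%s_m%03d", st, seq_len(nc + nd)),
      strain = st,
      group = rep(c("control", "defeated"), c(nc, nd)),
      t_iz_no_target = no_target,
      t_iz_target = target,
      planted_label = c(rep("control", nc),
                        ifelse(sus, "susceptible", "resilient")),
      stringsAsFactors = FALSE
    )
  }
  do.call(rbind, out)
}

#' Signal specification for the omics simulators
#'
#' Describes what the count and proteomics simulators plant: named gene
#' sets, a log2 effect size per set, a per-strain effect sign (the
#' strain-opposite structure is obtained with signs `+1` and `-1`), and the
#' contrasts whose non-control group carries the shift. Also holds the
#' negative-binomial dispersion, library-size range, and batch-effect
#' magnitude for the count model.
#'
#' @param sets Named list of character vectors: planted set name ->
#'   member feature identifiers. Empty list plants nothing.
#' @param effect_size log2 effect magnitude, a scalar or one value per set.
#' @param strain_sign Named numeric vector of `+1`/`-1` per strain.
#' @param affected_contrasts Which contrasts carry the effect; subset of
#'   `c("susceptible_vs_control", "resilient_vs_control")`. The named
#'   non-control group's mean is shifted relative to control.
#' @param dispersion Negative-binomial dispersion (must be > 0); counts are
#'   NB with variance `mu + dispersion * mu^2`.
#' @param lib_size_range Range library sizes are drawn from (uniform).
#' @param batch_sd SD (log2 scale) of per-feature, per-batch additive
#'   shifts; 0 disables batch effects.
#' @param base_log2_mean,base_log2_sd Location/spread of the log2 baseline
#'   abundance from which gene-wise means are drawn (log-normal means).
#' @param seed Integer seed; simulator sub-streams derive from it.
#' @return An object of class `"signal_spec"`.
#' @export
signal_spec <- function(sets = list(),
                        effect_size = 1,
                        strain_sign = c(B6 = 1, D2 = -1),
                        affected_contrasts = "susceptible_vs_control",
                        dispersion = 0.1,
                        lib_size_range = c(1e6, 2e6),
                        batch_sd = 0,
                        base_log2_mean = 4,
                        base_log2_sd = 1.5,
                        seed = 1L) {
  if (dispersion <= 0) {
    stop("invalid signal spec: dispersion must be > 0", call. = FALSE)
  }
  ok <- c("susceptible_vs_control", "resilient_vs_control")
  if (length(affected_contrasts) && !all(affected_contrasts %in% ok)) {
    stop("affected_contrasts must be a subset of ",
         paste(ok, collapse = ", "), call. = FALSE)
  }
  if (length(sets)) {
    if (is.null(names(sets)) || any(names(sets) == "")) {
      stop("planted sets must be named", call. = FALSE)
    }
    effect_size <- rep_len(effect_size, length(sets))
    names(effect_size) <- names(sets)
  }
  structure(list(sets = sets, effect_size = effect_size,
                 strain_sign = strain_sign,
                 affected_contrasts = affected_contrasts,
                 dispersion = dispersion,
                 lib_size_range = lib_size_range,
                 batch_sd = batch_sd,
                 base_log2_mean = base_log2_mean,
                 base_log2_sd = base_log2_sd,
                 seed = as.integer(seed)),
            class = "signal_spec")
}

# log2 shift matrix (features x samples) implied by a signal spec
planted_delta <- function(feature_ids, samples, signal) {
  delta <- matrix(0, length(feature_ids), nrow(samples),
                  dimnames = list(feature_ids, samples$sample_id))
  if (!length(signal$sets)) return(delta)
  groups <- sub("_vs_control$", "", signal$affected_contrasts)
  for (s in names(signal$sets)) {
    members <- signal$sets[[s]]
    bad <- setdiff(members, feature_ids)
    if (length(bad)) {
      stop("planted set '", s, "' has members outside the feature universe: ",
           paste(utils::head(bad, 5), collapse = ", "), call. = FALSE)
    }
    for (j in seq_len(nrow(samples))) {
      if (samples$group[j] %in% groups) {
        sgn <- signal$strain_sign[[samples$strain[j]]]
        if (is.null(sgn) || is.na(sgn)) sgn <- 1
        delta[members, j] <- delta[members, j] + signal$effect_size[[s]] * sgn
      }
    }
  }
  delta
}

#' Simulate a negative-binomial count matrix with planted effects
#'
#' Gene-wise baseline abundances are drawn log-normally; planted features
#' receive a group-mean log2 shift of the specified effect size with the
#' strain-specific sign in the affected groups; per-feature batch shifts
#' (additive on the log2 scale, mean-centred across batches) and drawn
#' library sizes complete the expected counts, from which negative-binomial
#' counts are sampled.
#'
#' @param n_features Number of features.
#' @param samples Sample metadata sheet (see [make_sample_sheet()]).
#' @param signal A [signal_spec()]; planted set members must be contained in
#'   `feature_ids`.
#' @param feature_ids Feature identifiers (default `g0001`, `g0002`, ...).
#' @param modality Count modality tag for the result.
#' @return An [omics_matrix()] of counts.
#' @export
simulate_counts <- function(n_features, samples, signal,
                            feature_ids = sprintf("g%04d", seq_len(n_features)),
                            modality = c("mrna", "mirna")) {
  stopifnot(inherits(signal, "signal_spec"))
  modality <- match.arg(modality)
  if (length(feature_ids) != n_features || anyDuplicated(feature_ids)) {
    stop("feature_ids must be ", n_features, " unique identifiers", call. = FALSE)
  }
  set.seed(signal$seed + 101L)
  n_samp <- nrow(samples)
  base <- rnorm(n_features, signal$base_log2_mean, signal$base_log2_sd)
  delta <- planted_delta(feature_ids, samples, signal)
  if (signal$batch_sd > 0) {
    batches <- unique(samples$batch)
    if (length(batches) > 1) {
      shift <- matrix(rnorm(n_features * length(batches), 0, signal$batch_sd),
                      n_features, length(batches))
      shift <- shift - rowMeans(shift)
      delta <- delta + shift[, match(samples$batch, batches), drop = FALSE]
    }
  }
  lib <- runif(n_samp, signal$lib_size_range[1], signal$lib_size_range[2])
  w <- 2^(base + delta)                      # relative abundance per cell
  mu <- sweep(w, 2, lib / colSums(w), `*`)   # expected counts at drawn depth
  counts <- matrix(rnbinom(n_features * n_samp, mu = mu,
                           size = 1 / signal$dispersion),
                   n_features, n_samp,
                   dimnames = list(feature_ids, samples$sample_id))
  omics_matrix(counts, samples, modality)
}

#' Simulate isotope-label proteomics with technical replicates
#'
#' Each protein's true per-sample log2 H/L ratio is a protein baseline plus
#' the planted effect (as in [simulate_counts()], without library or batch
#' terms). Per protein, a replicate coefficient of variation (CV, the "H/L
#' variability") is drawn uniformly from `cv_range`, and replicate-level
#' linear H/L ratios are log-normal around the true ratio with exactly that
#' CV, so the downstream inclusion filter ([filter_proteins()]) has genuine
#' work to do. A fraction of proteins is assigned a single unique peptide
#' per replicate and should be removed by the peptide rule.
#'
#' @param n_proteins Number of proteins.
#' @param samples Sample metadata sheet.
#' @param signal A [signal_spec()].
#' @param feature_ids Protein identifiers (default `p0001`, ...).
#' @param n_replicates Technical replicates per sample (>= 2).
#' @param baseline_sd SD (log2) of the protein baseline ratio.
#' @param cv_range Range the per-protein replicate CV is drawn from.
#' @param low_peptide_fraction Fraction of proteins planted with only one
#'   unique peptide per replicate.
#' @return A list of class `"proteomics_sim"`: `replicates` (long table with
#'   `protein_id`, `sample_id`, `replicate`, `n_unique_peptides`,
#'   `hl_ratio`), `samples`, `feature_ids`, `truth` (true log2 ratio matrix)
#'   and `cv` (planted per-protein CV).
#' @export
simulate_proteomics <- function(n_proteins, samples, signal,
                                feature_ids = sprintf("p%04d", seq_len(n_proteins)),
                                n_replicates = 3,
                                baseline_sd = 0.1,
                                cv_range = c(0.05, 0.45),
                                low_peptide_fraction = 0.1) {
  stopifnot(inherits(signal, "signal_spec"))
  if (n_replicates < 2) {
    stop("invalid spec: proteomics requires >= 2 technical replicates", call. = FALSE)
  }
  if (length(feature_ids) != n_proteins || anyDuplicated(feature_ids)) {
    stop("feature_ids must be ", n_proteins, " unique identifiers", call. = FALSE)
  }
  set.seed(signal$seed + 202L)
  n_samp <- nrow(samples)
  baseline <- rnorm(n_proteins, 0, baseline_sd)
  truth <- planted_delta(feature_ids, samples, signal) + baseline
  cv <- runif(n_proteins, cv_range[1], cv_range[2])
  sdlog <- sqrt(log(1 + cv^2))               # log-normal sdlog giving CV exactly
  low_pep <- runif(n_proteins) < low_peptide_fraction
  n_pep <- ifelse(low_pep, 1L, 2L + rpois(n_proteins, 2))
  rows <- expand.grid(replicate = seq_len(n_replicates),
                      sample_id = samples$sample_id,
                      protein_id = feature_ids,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- rows[, c("protein_id", "sample_id", "replicate")]
  i <- match(rows$protein_id, feature_ids)
  j <- match(rows$sample_id, samples$sample_id)
  noise <- exp(rnorm(nrow(rows), -sdlog[i]^2 / 2, sdlog[i]))  # mean-1 multiplier
  rows$n_unique_peptides <- n_pep[i]
  rows$hl_ratio <- 2^truth[cbind(i, j)] * noise
  rownames(rows) <- NULL
  structure(list(replicates = rows, samples = samples,
                 feature_ids = feature_ids, truth = truth, cv = cv),
            class = "proteomics_sim")
}

#' Simulate a miRNA-target interaction table
#'
#' Produces the full cross of miRNAs and targets, each pair annotated with
#' an evidence-source count drawn from `{1, 2, 3}` with the supplied
#' probabilities -- emulating interaction catalogues that report how many
#' independent sources (experimental databases, predictions) support a
#' pair.
#'
#' @param mirnas,targets Identifier vectors.
#' @param source_probs Probabilities over source counts 1, 2, 3 (must be
#'   non-negative and sum to 1).
#' @param seed Integer seed.
#' @return Data frame with columns `mirna`, `target`, `n_sources`.
#' @export
simulate_interactions <- function(mirnas, targets,
                                  source_probs = c(0.5, 0.3, 0.2),
                                  seed = 1L) {
  if (length(source_probs) != 3 || any(source_probs < 0) ||
      abs(sum(source_probs) - 1) > 1e-8) {
    stop("source_probs must be 3 non-negative probabilities summing to 1",
         call. = FALSE)
  }
  set.seed(as.integer(seed) + 303L)
  tab <- expand.grid(mirna = mirnas, target = targets,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  tab$n_sources <- sample.int(3L, nrow(tab), replace = TRUE, prob = source_probs)
  tab
}
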