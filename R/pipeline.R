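# End-to-end synthetic pipeline: simulate -> phenotype -> differential
# expression -> enrichment -> integration -> report.

#' Configuration for [run_pipeline()]
#'
#' Collects every threshold, sample size and seed the pipeline uses. The
#' defaults describe a two-strain study with one planted
#' "mitochondria-like" gene set of opposite effect sign between the
#' strains, decoy sets with no effect, an mRNA layer (20 mice per
#' phenotype group), a proteomics layer (4 mice per group, triplicate
#' runs), and a miRNA layer whose planted miRNAs move with their planted
#' target genes.
#'
#' @param seed Global integer seed; every stochastic stage derives its
#'   sub-seed from it.
#' @param out_dir Output directory for tables and the run log; `NULL`
#'   keeps everything in memory.
#' @param stages Stages to execute, in order, a subset of
#'   `c("simulate", "phenotype", "de", "enrichment", "integrate",
#'   "report")`. Later stages require the earlier ones.
#' @param strains Strain labels (effect signs alternate `+1, -1, ...`).
#' @param n_features,n_per_group_rna mRNA layer size.
#' @param n_proteins,n_per_group_protein Proteomics layer size.
#' @param n_mirnas,n_per_group_mirna miRNA layer size.
#' @param planted_set_size,n_decoy_sets,effect_size Planted-signal shape:
#'   one planted set of this size and log2 effect, plus unaffected decoy
#'   sets of the same size.
#' @param mirna_set_size Number of planted miRNAs.
#' @param p_thresh,fc_thresh DE definition thresholds.
#' @param fdr FDR threshold for convergence counting.
#' @param min_cpm,min_samples Abundance-filter settings.
#' @param min_sources miRNA-target evidence-source threshold.
#' @param fdr_hits,nominal_hits Pathway-convergence rule counts.
#' @param summary_fdr,summary_fraction GSEA summary-filter settings.
#' @param n_perm GSEA permutations per set.
#' @return List of class `"pipeline_config"`.
#' @export
pipeline_config <- function(seed = 1L,
                            out_dir = NULL,
                            stages = c("simulate", "phenotype", "de",
                                       "enrichment", "integrate", "report"),
                            strains = c("B6", "D2"),
                            n_features = 2000, n_per_group_rna = 20,
                            n_proteins = 800, n_per_group_protein = 4,
                            n_mirnas = 300, n_per_group_mirna = 10,
                            planted_set_size = 80, n_decoy_sets = 4,
                            effect_size = 1.0, mirna_set_size = 12,
                            p_thresh = 0.05, fc_thresh = 1.2, fdr = 0.05,
                            min_cpm = 1, min_samples = 6, min_sources = 3,
                            fdr_hits = 2, nominal_hits = 4,
                            summary_fdr = 0.25, summary_fraction = 0.5,
                            n_perm = 500) {
  all_stages <- c("simulate", "phenotype", "de", "enrichment", "integrate",
                  "report")
  if (length(stages)) {
    stages <- match.arg(stages, all_stages, several.ok = TRUE)
  } else {
    stages <- character()
  }
  cfg <- as.list(environment())
  cfg$all_stages <- NULL
  cfg$seed <- as.integer(seed)
  structure(cfg, class = "pipeline_config")
}

pipeline_contrasts <- list(
  susceptible_vs_control = c("susceptible", "control"),
  resilient_vs_control = c("resilient", "control"),
  susceptible_vs_resilient = c("susceptible", "resilient")
)

#' Run the synthetic multi-omics pipeline
#'
#' Executes the enabled stages in order on fully synthetic data:
#' behavioural cohort simulation and phenotyping; mRNA, proteomics and
#' miRNA simulation with the planted strain-opposite gene-set signal;
#' abundance filtering, normalization and moderated-t differential
#' expression for every strain, layer and contrast (the comparison grid);
#' preranked GSEA per comparison; and the convergence layer (pathway
#' convergence over the grid, GSEA summary filter, cross-strain
#' concordance, miRNA-target pairing). The report stage writes every
#' intermediate table plus a run log to `config$out_dir`.
#'
#' @param config A [pipeline_config()].
#' @return List with (depending on enabled stages): `cohort`, `phenotype`
#'   (calls, borders, susceptibility percentages, chi-square), `de`
#'   (named list of DE tables, one per comparison), `enrichment` (long
#'   table over comparisons), `integration` (convergence table, summary
#'   filter, concordance, miRNA pairs, planted-set NES by strain), and
#'   `files` (paths written). An empty `stages` yields an empty bundle.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  state <- list(config = config, files = character())
  run_stage <- function(name, fun, state) {
    tryCatch(fun(state), error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  stage_funs <- list(simulate = stage_simulate, phenotype = stage_phenotype,
                     de = stage_de, enrichment = stage_enrichment,
                     integrate = stage_integrate, report = stage_report)
  for (s in intersect(names(stage_funs), config$stages)) {
    state <- run_stage(s, stage_funs[[s]], state)
  }
  state$config <- NULL
  state
}

stage_simulate <- function(state) {
  cfg <- state$config
  set.seed(cfg$seed + 7L)
  gene_ids <- sprintf("g%04d", seq_len(cfg$n_features))
  mirna_ids <- sprintf("mir%03d", seq_len(cfg$n_mirnas))
  planted <- sample(gene_ids, cfg$planted_set_size)
  decoys <- lapply(seq_len(cfg$n_decoy_sets),
                   function(i) sample(gene_ids, cfg$planted_set_size))
  names(decoys) <- sprintf("RANDOM_SET_%d", seq_len(cfg$n_decoy_sets))
  sets <- c(list(MITOCHONDRIAL_OXPHOS = planted), decoys)
  collection <- gene_set_collection(
    sets, categories = c("mitochondria-related",
                         rep("mitochondria-unrelated", cfg$n_decoy_sets)))
  planted_mirnas <- sample(mirna_ids, cfg$mirna_set_size)
  signs <- stats::setNames(rep_len(c(1, -1), length(cfg$strains)), cfg$strains)
  protein_ids <- unique(c(planted, sample(gene_ids, cfg$n_proteins)))
  protein_ids <- protein_ids[seq_len(min(length(protein_ids), cfg$n_proteins))]
  protein_ids <- unique(c(planted, protein_ids))

  state$cohort <- simulate_cohort(cohort_spec(strains = cfg$strains,
                                              seed = cfg$seed))
  state$collection <- collection
  state$planted_set <- "MITOCHONDRIAL_OXPHOS"
  state$planted_mirnas <- planted_mirnas
  state$matrices <- list()
  for (i in seq_along(cfg$strains)) {
    st <- cfg$strains[i]
    sgn <- signs
    rna_signal <- signal_spec(
      sets = list(MITOCHONDRIAL_OXPHOS = planted),
      effect_size = cfg$effect_size, strain_sign = sgn,
      affected_contrasts = "susceptible_vs_control",
      batch_sd = 0.25, seed = cfg$seed + 10L * i)
    rna_samples <- make_sample_sheet(cfg$n_per_group_rna, strain = st,
                                     n_batches = 2)
    state$matrices[[paste0(st, "_mrna")]] <-
      simulate_counts(cfg$n_features, rna_samples, rna_signal,
                      feature_ids = gene_ids, modality = "mrna")

    prot_signal <- signal_spec(
      sets = list(MITOCHONDRIAL_OXPHOS = planted),
      effect_size = cfg$effect_size, strain_sign = sgn,
      affected_contrasts = "susceptible_vs_control",
      seed = cfg$seed + 10L * i + 5L)
    prot_samples <- make_sample_sheet(cfg$n_per_group_protein, strain = st)
    state$matrices[[paste0(st, "_protein")]] <-
      simulate_proteomics(length(protein_ids), prot_samples, prot_signal,
                          feature_ids = protein_ids,
                          cv_range = c(0.02, 0.45))

    mirna_signal <- signal_spec(
      sets = list(PLANTED_MIRNAS = planted_mirnas),
      effect_size = cfg$effect_size, strain_sign = sgn,
      affected_contrasts = "susceptible_vs_control",
      seed = cfg$seed + 10L * i + 7L)
    mirna_samples <- make_sample_sheet(cfg$n_per_group_mirna, strain = st)
    state$matrices[[paste0(st, "_mirna")]] <-
      simulate_counts(cfg$n_mirnas, mirna_samples, mirna_signal,
                      feature_ids = mirna_ids, modality = "mirna")
  }
  state$interactions <- simulate_interactions(
    mirna_ids[seq_len(min(60, cfg$n_mirnas))],
    c(planted, sample(gene_ids, 60)),
    source_probs = c(0.2, 0.3, 0.5), seed = cfg$seed + 11L)
  state
}

stage_phenotype <- function(state) {
  if (is.null(state$cohort)) stop("requires the simulate stage")
  cfg <- state$config
  ph <- phenotype_cohort(state$cohort)
  counts <- table(factor(ph$calls$label,
                         levels = c("susceptible", "resilient")),
                  ph$calls$strain)
  pct <- vapply(colnames(counts), function(st) {
    susceptibility_percentage(counts["susceptible", st],
                              counts["resilient", st])
  }, numeric(1))
  chi2 <- if (ncol(counts) == 2) strain_phenotype_chi2(t(counts)) else NULL
  state$phenotype <- list(calls = ph$calls, borders = ph$borders,
                          counts = counts, susceptibility_pct = pct,
                          chi2 = chi2)
  state
}

stage_de <- function(state) {
  if (is.null(state$matrices)) stop("requires the simulate stage")
  cfg <- state$config
  de <- list()
  for (st in cfg$strains) {
    rna <- state$matrices[[paste0(st, "_mrna")]]
    rna <- log_cpm(cpm_filter(rna, cfg$min_cpm, cfg$min_samples))
    rna <- batch_center(rna)
    prot <- filter_proteins(state$matrices[[paste0(st, "_protein")]]$replicates,
                            samples = state$matrices[[paste0(st, "_protein")]]$samples)
    prot <- median_center(prot)
    mirna <- state$matrices[[paste0(st, "_mirna")]]
    mirna <- log_cpm(cpm_filter(mirna, cfg$min_cpm, cfg$min_samples))
    layers <- list(mrna = rna, protein = prot, mirna = mirna)
    for (layer in names(layers)) {
      for (cn in names(pipeline_contrasts)) {
        key <- paste(st, layer, cn, sep = "|")
        de[[key]] <- fit_moderated_t(layers[[layer]],
                                     contrast = pipeline_contrasts[[cn]],
                                     dataset = paste0(st, "_", layer))
      }
    }
  }
  state$de <- de
  state
}

stage_enrichment <- function(state) {
  if (is.null(state$de)) stop("requires the de stage")
  cfg <- state$config
  # the canonical comparison grid: 2 strains x 3 contrasts x {mRNA, protein}
  keys <- names(state$de)
  keys <- keys[!grepl("\\|mirna\\|", keys)]
  enr <- vector("list", length(keys))
  for (i in seq_along(keys)) {
    ranked <- rank_metric(state$de[[keys[i]]])
    enr[[i]] <- gsea_preranked(ranked, state$collection,
                               n_perm = cfg$n_perm,
                               seed = cfg$seed + 1000L + i,
                               comparison = keys[i])
  }
  state$enrichment <- do.call(rbind, enr)
  state
}

stage_integrate <- function(state) {
  if (is.null(state$enrichment)) stop("requires the enrichment stage")
  cfg <- state$config
  enr <- state$enrichment
  convergence <- pathway_convergence(
    data.frame(pathway = enr$set, comparison = enr$comparison,
               p = enr$p, pfdr = enr$pfdr, stringsAsFactors = FALSE),
    fdr_hits = cfg$fdr_hits, nominal_hits = cfg$nominal_hits,
    fdr = cfg$fdr, nominal = cfg$p_thresh)
  summary_filter <- gsea_summary_filter(enr, fdr = cfg$summary_fdr,
                                        fraction = cfg$summary_fraction)
  sus_key <- function(st, layer) paste(st, layer,
                                       "susceptible_vs_control", sep = "|")
  concordance <- cross_strain_concordance(
    state$de[[sus_key(cfg$strains[1], "mrna")]],
    state$de[[sus_key(cfg$strains[2], "mrna")]],
    p_thresh = cfg$p_thresh, fc_thresh = cfg$fc_thresh)
  pairs <- mirna_target_pairs(
    state$de[[sus_key(cfg$strains[1], "mirna")]],
    state$de[[sus_key(cfg$strains[1], "mrna")]],
    state$interactions, min_sources = cfg$min_sources,
    p_thresh = cfg$p_thresh, fc_thresh = cfg$fc_thresh)
  planted_nes <- vapply(cfg$strains, function(st) {
    row <- enr$set == state$planted_set &
      enr$comparison == sus_key(st, "mrna")
    if (any(row)) enr$nes[row][1] else NA_real_
  }, numeric(1))
  state$integration <- list(convergence = convergence,
                            summary_filter = summary_filter,
                            concordance = concordance,
                            mirna_pairs = pairs,
                            planted_nes = planted_nes)
  state
}

stage_report <- function(state) {
  cfg <- state$config
  if (is.null(cfg$out_dir)) return(state)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(name) file.path(cfg$out_dir, name)
  files <- character()
  if (!is.null(state$cohort)) {
    write_result_table(state$cohort, out("cohort.tsv"))
    files <- c(files, out("cohort.tsv"))
  }
  if (!is.null(state$phenotype)) {
    write_result_table(state$phenotype$calls, out("phenotype_calls.tsv"))
    files <- c(files, out("phenotype_calls.tsv"))
  }
  if (!is.null(state$matrices)) {
    for (nm in names(state$matrices)) {
      m <- state$matrices[[nm]]
      if (inherits(m, "omics_matrix")) {
        write_omics_matrix(m, out(paste0(nm, ".tsv")),
                           out(paste0(nm, "_samples.tsv")))
        files <- c(files, out(paste0(nm, ".tsv")))
      }
    }
    write_gmt(state$collection, out("gene_sets.gmt"))
    write_result_table(state$interactions, out("interactions.tsv"))
    files <- c(files, out("gene_sets.gmt"), out("interactions.tsv"))
  }
  if (!is.null(state$de)) {
    de_all <- do.call(rbind, state$de)
    rownames(de_all) <- NULL
    write_result_table(de_all, out("de_results.tsv"))
    files <- c(files, out("de_results.tsv"))
  }
  if (!is.null(state$enrichment)) {
    write_result_table(state$enrichment, out("enrichment.tsv"))
    files <- c(files, out("enrichment.tsv"))
  }
  if (!is.null(state$integration)) {
    write_result_table(state$integration$convergence, out("convergence.tsv"))
    nes <- state$integration$summary_filter$nes
    nes_tab <- data.frame(set = rownames(nes), nes, check.names = FALSE,
                          stringsAsFactors = FALSE)
    write_result_table(nes_tab, out("summary_nes.tsv"))
    write_result_table(state$integration$mirna_pairs, out("mirna_pairs.tsv"))
    files <- c(files, out("convergence.tsv"), out("summary_nes.tsv"),
               out("mirna_pairs.tsv"))
  }
  log_lines <- c(
    sprintf("run_pipeline log"),
    sprintf("timestampless deterministic run; seed = %d", cfg$seed),
    sprintf("R version: %s", R.version.string),
    sprintf("package: csdsomics %s",
            as.character(utils::packageVersion("csdsomics"))),
    sprintf("stages: %s", paste(cfg$stages, collapse = ", ")),
    sprintf("thresholds: p=%g fc=%g fdr=%g min_cpm=%g min_samples=%d min_sources=%d",
            cfg$p_thresh, cfg$fc_thresh, cfg$fdr, cfg$min_cpm,
            cfg$min_samples, cfg$min_sources),
    sprintf("convergence rule: >=%d/12 PFDR<%g and >=%d/12 P<%g",
            cfg$fdr_hits, cfg$fdr, cfg$nominal_hits, cfg$p_thresh),
    sprintf("summary filter: PFDR<%g in >=%g of comparisons",
            cfg$summary_fdr, cfg$summary_fraction),
    sprintf("gsea: n_perm=%d weight p=1", cfg$n_perm),
    sprintf("sizes: n_features=%d n_proteins=%d n_mirnas=%d per-group rna=%d protein=%d mirna=%d",
            cfg$n_features, cfg$n_proteins, cfg$n_mirnas,
            cfg$n_per_group_rna, cfg$n_per_group_protein,
            cfg$n_per_group_mirna)
  )
  writeLines(log_lines, out("run_log.txt"))
  state$files <- c(files, out("run_log.txt"))
  state
}
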