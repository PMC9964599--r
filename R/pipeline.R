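#' @title End-to-end pipeline and configuration
#'
#' @description One structured configuration object controls every
#' threshold of the workflow; [runAll()] executes the full chain
#' (simulate, curate, 2D cascade, 3D cascade, target correlation,
#' integration, report) deterministically from a master seed.
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All thresholds default to the workflow's standard values: MACCS Tc
#' >= 0.8 and ECFP4 Tc >= 0.3 for the 2D cascade, TanimotoCombo >= 1.5
#' for the 3D cascade, 1000 nM potency cutoff and 180-850 Da window for
#' active selection, at least 10 annotations per target, and rho >= 0.40
#' with p <= 0.05 plus the CI-lower criterion for target selection.
#'
#' @param seed master seed.
#' @param ... overrides for any top-level entry.
#' @return a nested configuration list.
#' @export
defaultConfig <- function(seed = 42L, ...) {
  cfg <- list(
    seed = as.integer(seed),
    t_maccs = 0.8,
    t_ecfp4 = 0.3,
    t_combo = 1.5,
    ecfp4_nbits = 2048L,
    potency_cutoff_nm = 1000,
    mw_range = c(180, 850),
    min_annotations = 10L,
    rho_min = 0.40,
    p_max = 0.05,
    require_ci = TRUE,
    ci_method = "bonett",
    ci_level = 0.95,
    n_conformers = 10L,
    ovality = "ratio",
    cell_line_aliases = list(),
    sim = simulationConfig(seed = seed))
  over <- list(...)
  if (length(over)) cfg <- utils::modifyList(cfg, over)
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Entries present in the file override the defaults; everything else
#' keeps its default value.
#'
#' @param path YAML file.
#' @param seed fallback master seed when the file does not set one.
#' @return a configuration list.
#' @export
readPipelineConfig <- function(path, seed = 42L) {
  user <- yaml::read_yaml(path)
  cfg <- defaultConfig(seed = if (!is.null(user$seed)) user$seed else seed)
  simOver <- user$sim
  user$sim <- NULL
  cfg <- utils::modifyList(cfg, user)
  if (!is.null(simOver))
    cfg$sim <- do.call(simulationConfig,
                       utils::modifyList(
                         c(list(seed = cfg$seed), simOver), list()))
  cfg
}

#' Apply cell-line alias pooling
#'
#' Renames `scope_id` values according to a named alias list (e.g.
#' `list("LNCaP clone FGC" = "LNCaP")`). The default configuration pools
#' nothing.
#'
#' @param records cell-scope bioactivity rows.
#' @param aliases named list/character: old name -> new name.
#' @return the records with aliased scope ids.
#' @export
applyCellLineAliases <- function(records, aliases) {
  if (!length(aliases)) return(records)
  m <- match(records$scope_id, names(aliases))
  records$scope_id[!is.na(m)] <- unlist(aliases)[m[!is.na(m)]]
  records
}

#' Run the complete workflow
#'
#' Simulates (or consumes) the input data, curates compounds and
#' bioactivities, runs the 2D then 3D similarity cascade of the drug
#' library against the selected actives, mines correlated targets, and
#' writes the ranked candidate report. Identical configurations produce
#' byte-identical report files.
#'
#' @param config configuration list from [defaultConfig()] /
#'   [readPipelineConfig()].
#' @param out_dir directory for report files (optional; when NULL nothing
#'   is written).
#' @param sim pre-built simulation (from [simulateAll()] or
#'   [readFixtures()]); by default generated from `config$sim`.
#' @return list with every intermediate: curated records, actives, 2D
#'   pairs and survivors, overlay scores and survivors, correlation
#'   results, selected targets, the ranked report, and the configuration.
#' @export
runAll <- function(config = defaultConfig(), out_dir = NULL, sim = NULL) {
  if (is.null(sim)) sim <- simulateAll(config$sim)

  # curation
  cell <- filterCellBioactivities(
    applyCellLineAliases(sim$cell_records, config$cell_line_aliases))
  cell <- dedupBest(cell)
  targ <- filterTargetBioactivities(sim$target_records)
  activeIds <- selectActives(cell, sim$library,
                             potency_cutoff_nm = config$potency_cutoff_nm,
                             mw_range = config$mw_range)
  actives <- sim$library[activeIds]
  drugs <- removeOverlap(sim$drugs, actives)

  # 2D cascade
  pairs2d <- allAgainstAll2D(drugs, actives,
                             nbits_ecfp4 = config$ecfp4_nbits)
  surv2d <- cascadeFilter2D(pairs2d, config$t_maccs, config$t_ecfp4)

  # 3D cascade on the 2D survivors
  scores3d <- overlayScores(surv2d, drugs, actives,
                            n_conformers = config$n_conformers,
                            seed = config$seed)
  surv3d <- cascadeFilter3D(scores3d, config$t_combo)
  hits <- merge(surv3d,
                surv2d[, c("drug_id", "active_id", "tc_maccs",
                           "tc_ecfp4")],
                by = c("drug_id", "active_id"), sort = TRUE)
  hits <- hits[order(hits$drug_id, hits$active_id), , drop = FALSE]
  rownames(hits) <- NULL

  # target correlation mining
  corr <- correlateTargets(targ, cell,
                           min_annotations = config$min_annotations,
                           rho_min = config$rho_min,
                           p_max = config$p_max,
                           require_ci = config$require_ci,
                           level = config$ci_level,
                           ci_method = config$ci_method,
                           seed = config$seed)
  selTargets <- unique(corr$target_id[corr$selected])

  # integration + report
  report <- if (nrow(hits)) {
    rankCandidates(annotateCandidates(
      hits, sim$drug_meta, sim$drug_bioactivities, selTargets,
      sim$clinical_table))
  } else NULL

  paths <- NULL
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir))
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    .writeTsv(corr, file.path(out_dir, "target_correlations.tsv"))
    .writeTsv(scores3d, file.path(out_dir, "overlay_scores.tsv"))
    s2 <- pairs2d
    s2$cascade_pass <- s2$tc_maccs >= config$t_maccs &
      s2$tc_ecfp4 >= config$t_ecfp4
    .writeTsv(s2, file.path(out_dir, "similarity_2d.tsv"))
    if (!is.null(report))
      paths <- writeCandidateReport(report,
                                    file.path(out_dir, "candidates"))
  }

  list(sim = sim, cell_records = cell, target_records = targ,
       active_ids = activeIds, actives = actives, drugs = drugs,
       pairs_2d = pairs2d, survivors_2d = surv2d,
       scores_3d = scores3d, survivors_3d = surv3d, hits = hits,
       correlations = corr, selected_targets = selTargets,
       report = report, report_paths = paths, config = config)
}
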