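#' @title Evidence integration and the ranked candidate report
#'
#' @description Joins the similarity-cascade survivors with drug metadata,
#' potency-classified target annotations and clinical-trial evidence, sets
#' the four objective selection flags, and emits a deterministic ranked
#' report. Final triage (novelty, toxicity) is deliberately left to the
#' user.
#'
#' @name integration_report
NULL

.ACTIVITY_LABELS <- c("highly_active", "scarcely_active", "inactive")

#' Classify a potency value into activity classes
#'
#' `<= 1000` nM is highly active, `(1000, 10000)` nM scarcely active and
#' `>= 10000` nM inactive. The two class definitions meet at exactly 10 uM;
#' that boundary is resolved as inactive.
#'
#' @param value_nm positive potency value(s) in nM.
#' @return character vector of class labels.
#' @export
classifyActivity <- function(value_nm) {
  if (any(!is.finite(value_nm) | value_nm <= 0))
    domainError("potency values must be positive")
  ifelse(value_nm <= 1000, "highly_active",
         ifelse(value_nm < 10000, "scarcely_active", "inactive"))
}

#' Annotate cascade survivors into candidate reports
#'
#' One report per distinct drug among the 3D-cascade survivors. The four
#' evidence flags are: `in_vitro_pc` (the drug has its own cell-based
#' potency record), `in_vivo_pc` (metadata annotation), `pc_trial` (a
#' clinical row on prostate cancer or a solid-tumor trial), and `pc_target`
#' (a highly-active record on a target that passed correlation selection).
#'
#' @param hits data.frame of surviving pairs with columns drug_id,
#'   active_id, tc_maccs, tc_ecfp4, tanimoto_combo.
#' @param drug_meta data.frame(drug_id, name, max_phase) and optionally
#'   `invivo_pc` (logical).
#' @param drug_bioactivities bioactivity rows whose compound_id is a drug
#'   id (cell- and target-scope evidence for the drugs themselves); may be
#'   empty.
#' @param correlated_targets character vector of selected target ids.
#' @param clinical_table data.frame(drug_id, trial_id, disease, phase); may
#'   be empty or NULL.
#' @return data.frame with one row per drug, a list-column
#'   `target_annotations`, the flag columns and the best-hit summary.
#' @export
annotateCandidates <- function(hits, drug_meta, drug_bioactivities = NULL,
                               correlated_targets = character(),
                               clinical_table = NULL) {
  stopifnot(all(c("drug_id", "active_id", "tanimoto_combo") %in%
                  names(hits)))
  drugs <- unique(hits$drug_id)
  if (is.null(drug_bioactivities))
    drug_bioactivities <- .emptyBioactivityTable()
  rows <- vector("list", length(drugs))
  for (k in seq_along(drugs)) {
    d <- drugs[k]
    h <- hits[hits$drug_id == d, , drop = FALSE]
    h <- h[order(-h$tanimoto_combo, h$active_id), , drop = FALSE]
    best <- h[1, ]

    mi <- match(d, drug_meta$drug_id)
    if (is.na(mi))
      warning(sprintf("no metadata for drug '%s'; emitting nulls", d),
              call. = FALSE)
    name <- if (is.na(mi)) NA_character_ else drug_meta$name[mi]
    phase <- if (is.na(mi)) NA_integer_ else drug_meta$max_phase[mi]
    invivo <- if (!is.na(mi) && "invivo_pc" %in% names(drug_meta))
      isTRUE(drug_meta$invivo_pc[mi]) else FALSE

    db <- drug_bioactivities[drug_bioactivities$compound_id == d, ,
                             drop = FALSE]
    cellRows <- db[db$activity_scope == "cell", , drop = FALSE]
    targRows <- db[db$activity_scope == "target", , drop = FALSE]
    tann <- if (nrow(targRows))
      data.frame(target_id = targRows$scope_id,
                 value_nm = targRows$standard_value,
                 class = classifyActivity(targRows$standard_value),
                 is_correlated_target =
                   targRows$scope_id %in% correlated_targets)
    else data.frame(target_id = character(), value_nm = numeric(),
                    class = character(), is_correlated_target = logical())

    clin <- if (!is.null(clinical_table) && nrow(clinical_table))
      clinical_table[clinical_table$drug_id == d, , drop = FALSE]
    else NULL
    pcTrial <- !is.null(clin) && nrow(clin) > 0 &&
      any(grepl("prostate|solid tumor", clin$disease, ignore.case = TRUE))

    rows[[k]] <- data.frame(
      drug_id = d, name = name, max_phase = phase,
      best_active_id = best$active_id,
      best_tc_maccs = if ("tc_maccs" %in% names(best)) best$tc_maccs
      else NA_real_,
      best_tc_ecfp4 = if ("tc_ecfp4" %in% names(best)) best$tc_ecfp4
      else NA_real_,
      best_tanimoto_combo = best$tanimoto_combo,
      in_vitro_pc = nrow(cellRows) > 0,
      in_vivo_pc = invivo,
      pc_trial = pcTrial,
      pc_target = any(tann$is_correlated_target &
                        tann$class == "highly_active"),
      stringsAsFactors = FALSE)
    rows[[k]]$target_annotations <- I(list(tann))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @keywords internal
.emptyBioactivityTable <- function() {
  data.frame(compound_id = character(), activity_scope = character(),
             scope_id = character(), standard_type = character(),
             standard_relation = character(), standard_value = numeric(),
             standard_units = character(), assay_type = character(),
             target_type = character(), target_organism = character())
}

#' Rank annotated candidates deterministically
#'
#' Order: number of true evidence flags (descending), best TanimotoCombo
#' (descending), max clinical phase (descending), then drug id
#' (lexicographic ascending) as the final tie-break, giving a total order.
#'
#' @param reports data.frame from [annotateCandidates()].
#' @return the reports sorted, with a `rank` column (1 = best).
#' @export
rankCandidates <- function(reports) {
  flags <- reports$in_vitro_pc + reports$in_vivo_pc + reports$pc_trial +
    reports$pc_target
  phase <- ifelse(is.na(reports$max_phase), -1L, reports$max_phase)
  ord <- order(-flags, -reports$best_tanimoto_combo, -phase,
               reports$drug_id)
  out <- reports[ord, , drop = FALSE]
  out$n_flags <- flags[ord]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Write the candidate report as delimited text and JSON
#'
#' Output is byte-reproducible: fixed column order, fixed numeric
#' formatting, no timestamps. The delimited file flattens the per-target
#' annotations into a `target_annotations` summary column; the JSON keeps
#' them nested. A footer note records that p-values are reported without
#' multiple-testing correction.
#'
#' @param reports ranked report data.frame from [rankCandidates()].
#' @param path_prefix output prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return invisibly, the two file paths.
#' @export
writeCandidateReport <- function(reports, path_prefix) {
  flat <- reports
  flat$target_annotations <- vapply(reports$target_annotations,
    function(t) {
      if (!nrow(t)) return("")
      paste(sprintf("%s:%.6g:%s:%s", t$target_id, t$value_nm, t$class,
                    ifelse(t$is_correlated_target, "corr", "uncorr")),
            collapse = ";")
    }, "")
  num <- vapply(flat, is.numeric, TRUE)
  for (cn in names(flat)[num])
    flat[[cn]] <- ifelse(is.na(flat[[cn]]), "NA",
                         formatC(flat[[cn]], format = "g", digits = 10))
  tsv <- paste0(path_prefix, ".tsv")
  jsn <- paste0(path_prefix, ".json")
  con <- file(tsv, open = "wb")
  write.table(flat, con, sep = "\t", quote = FALSE, row.names = FALSE,
              eol = "\n")
  writeLines("# note: p-values are reported without multiple-testing correction",
             con)
  close(con)

  lst <- lapply(seq_len(nrow(reports)), function(i) {
    r <- as.list(reports[i, setdiff(names(reports), "target_annotations")])
    r$target_annotations <- reports$target_annotations[[i]]
    r
  })
  jsonlite::write_json(lst, jsn, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", pretty = TRUE)
  invisible(c(tsv = tsv, json = jsn))
}
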