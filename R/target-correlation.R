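#' @title Target-phenotype correlation mining
#'
#' @description Pairs per-target potencies with per-cell-line
#' antiproliferative potencies compound-by-compound and selects targets
#' whose tie-aware Spearman correlation passes the selection rule
#' (rho >= 0.40, p <= 0.05, and - per the confidence-interval criterion -
#' the lower bound of the Bonett-Wright interval also >= 0.40). Each
#' (target, cell line) pair is tested separately. Because Spearman's rho is
#' rank-based, raw nM values and -log10 potencies give identical results.
#'
#' @name target_correlation
NULL

#' Keep targets with enough distinct compound annotations
#'
#' @param records deduplicated target-scope bioactivity rows.
#' @param min_n minimum number of distinct annotated compounds (default
#'   10).
#' @return character vector of retained target ids.
#' @export
minAnnotationFilter <- function(records, min_n = 10L) {
  .checkBioactivityCols(records)
  if (!nrow(records)) return(character())
  cnt <- tapply(records$compound_id, records$scope_id,
                function(x) length(unique(x)))
  out <- names(cnt)[cnt >= min_n]
  logInfo("minAnnotationFilter: %d targets in, %d retained (>= %d)",
          length(cnt), length(out), min_n)
  out
}

#' Pair target and cell potencies per compound
#'
#' Inner join on compound id between one target's records and one cell
#' line's records. Both inputs must already be deduplicated (one record per
#' compound); duplicates raise `duplicateKeyError`.
#'
#' @param target_records deduplicated rows for one target
#'   (`scope_id == target_id`).
#' @param cell_records deduplicated cell-scope rows.
#' @param cell_line the cell line to pair against.
#' @return list with `target_id`, `cell_line`, `pairs`
#'   (data.frame compound_id, target_value_nm, cell_value_nm) and `n`.
#' @export
buildPairs <- function(target_records, cell_records, cell_line) {
  .checkBioactivityCols(target_records)
  .checkBioactivityCols(cell_records)
  tid <- unique(target_records$scope_id)
  stopifnot(length(tid) <= 1L)
  cell <- cell_records[cell_records$scope_id == cell_line, , drop = FALSE]
  if (anyDuplicated(target_records$compound_id))
    duplicateKeyError(
      target_records$compound_id[duplicated(target_records$compound_id)][1],
      "target records")
  if (anyDuplicated(cell$compound_id))
    duplicateKeyError(cell$compound_id[duplicated(cell$compound_id)][1],
                      "cell records")
  common <- intersect(target_records$compound_id, cell$compound_id)
  pairs <- data.frame(
    compound_id = common,
    target_value_nm =
      target_records$standard_value[match(common,
                                          target_records$compound_id)],
    cell_value_nm = cell$standard_value[match(common, cell$compound_id)])
  list(target_id = if (length(tid)) tid else NA_character_,
       cell_line = cell_line, pairs = pairs, n = nrow(pairs))
}

#' Tie-aware Spearman correlation with t-approximation p-value
#'
#' Average ranks are correlated with Pearson's formula; the p-value comes
#' from the t distribution with n - 2 degrees of freedom. Invariant under
#' any strictly monotone transform of either variable.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return list(rho, p_value, n).
#' @export
spearmanRho <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) insufficientDataError(n, 3L)
  if (stats::var(x) == 0) undefinedCorrelationError("x")
  if (stats::var(y) == 0) undefinedCorrelationError("y")
  rx <- rank(x); ry <- rank(y)
  rho <- stats::cor(rx, ry, method = "pearson")
  # exact rank agreement (or reversal) is rho = +/-1 by definition; avoid
  # the epsilon-level error of the generic correlation routine there
  if (identical(rx, ry)) rho <- 1
  else if (identical(rx, n + 1 - ry)) rho <- -1
  rho <- max(-1, min(1, rho))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n)
}

#' Bonett-Wright confidence interval for Spearman's rho
#'
#' Fisher z-transform interval with standard error
#' `sqrt((1 + rho^2/2) / (n - 3))`, back-transformed with tanh.
#'
#' @param rho point estimate, |rho| < 1.
#' @param n number of pairs, n >= 4.
#' @param level confidence level (default 0.95).
#' @return c(ci_low, ci_high).
#' @export
rhoConfidenceInterval <- function(rho, n, level = 0.95) {
  if (n < 4L) insufficientDataError(n, 4L)
  stopifnot(abs(rho) < 1)
  z <- atanh(rho)
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  crit <- stats::qnorm(1 - (1 - level) / 2)
  c(ci_low = tanh(z - crit * se), ci_high = tanh(z + crit * se))
}

#' Bootstrap confidence interval for Spearman's rho (alternative)
#'
#' Seeded percentile bootstrap over compound pairs; provided as the
#' config-swappable alternative to the Bonett-Wright interval.
#'
#' @param x,y paired potency vectors.
#' @param level confidence level.
#' @param n_boot resamples (default 2000).
#' @param seed integer seed.
#' @return c(ci_low, ci_high).
#' @export
rhoBootstrapInterval <- function(x, y, level = 0.95, n_boot = 2000L,
                                 seed = 1L) {
  n <- length(x)
  if (n < 4L) insufficientDataError(n, 4L)
  .withSeed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      idx <- sample.int(n, n, replace = TRUE)
      if (stats::var(x[idx]) == 0 || stats::var(y[idx]) == 0) NA_real_
      else stats::cor(rank(x[idx]), rank(y[idx]))
    }, 0)
    stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2),
                    na.rm = TRUE, names = FALSE)
  })
}

#' Correlate every (target, cell line) combination
#'
#' Runs the full mining stage: the six-clause target filter (unless the
#' input is already filtered), the minimum-annotation filter, per-cell-line
#' pairing, Spearman correlation, confidence intervals and the selection
#' rule. Pairs with fewer than `min_pairs` compounds, or with zero rank
#' variance, are reported as not selected with an NA correlation rather
#' than raising.
#'
#' @param target_records target-scope bioactivity rows (deduplicated).
#' @param cell_records deduplicated cell-scope rows.
#' @param cell_lines cell lines to test (default: all present).
#' @param min_annotations minimum annotations per target (default 10).
#' @param min_pairs minimum joined pairs to attempt a correlation.
#' @param rho_min,p_max,require_ci,level selection rule parameters, see
#'   [selectTargets()].
#' @param ci_method `"bonett"` (closed form) or `"bootstrap"`.
#' @param seed seed for the bootstrap interval.
#' @return data.frame(target_id, cell_line, n, rho, p_value, ci_low,
#'   ci_high, selected).
#' @export
correlateTargets <- function(target_records, cell_records,
                             cell_lines = NULL, min_annotations = 10L,
                             min_pairs = 4L, rho_min = 0.40, p_max = 0.05,
                             require_ci = TRUE, level = 0.95,
                             ci_method = c("bonett", "bootstrap"),
                             seed = 1L) {
  ci_method <- match.arg(ci_method)
  if (is.null(cell_lines))
    cell_lines <- sort(unique(cell_records$scope_id))
  targets <- minAnnotationFilter(target_records, min_annotations)
  rows <- list()
  for (tid in targets) {
    trec <- target_records[target_records$scope_id == tid, , drop = FALSE]
    for (cl in cell_lines) {
      pv <- buildPairs(trec, cell_records, cl)
      row <- data.frame(target_id = tid, cell_line = cl, n = pv$n,
                        rho = NA_real_, p_value = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_,
                        selected = FALSE)
      if (pv$n >= max(min_pairs, 4L)) {
        res <- tryCatch(
          spearmanRho(pv$pairs$target_value_nm, pv$pairs$cell_value_nm),
          undefinedCorrelationError = function(e) NULL)
        if (!is.null(res)) {
          ci <- if (abs(res$rho) < 1) {
            if (ci_method == "bonett")
              rhoConfidenceInterval(res$rho, pv$n, level)
            else rhoBootstrapInterval(pv$pairs$target_value_nm,
                                      pv$pairs$cell_value_nm, level,
                                      seed = seed)
          } else c(res$rho, res$rho)
          row$rho <- res$rho; row$p_value <- res$p_value
          row$ci_low <- ci[1]; row$ci_high <- ci[2]
        }
      }
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(target_id = character(), cell_line = character(),
                  n = integer(), rho = numeric(), p_value = numeric(),
                  ci_low = numeric(), ci_high = numeric(),
                  selected = logical())
  rownames(out) <- NULL
  selectTargets(out, rho_min, p_max, require_ci, keep_all = TRUE)
}

#' Apply the target selection rule
#'
#' A result is selected when rho >= `rho_min`, p <= `p_max`, and (when
#' `require_ci`) the lower confidence bound is also >= `rho_min`.
#'
#' @param results data.frame with columns rho, p_value, ci_low.
#' @param rho_min minimum correlation (default 0.40).
#' @param p_max maximum p-value (default 0.05).
#' @param require_ci also require `ci_low >= rho_min` (default TRUE).
#' @param keep_all return all rows with the `selected` flag updated
#'   (TRUE), or only the selected rows (FALSE, default).
#' @return data.frame.
#' @export
selectTargets <- function(results, rho_min = 0.40, p_max = 0.05,
                          require_ci = TRUE, keep_all = FALSE) {
  stopifnot(all(c("rho", "p_value", "ci_low") %in% names(results)))
  sel <- !is.na(results$rho) & results$rho >= rho_min &
    !is.na(results$p_value) & results$p_value <= p_max
  if (require_ci) sel <- sel & !is.na(results$ci_low) &
      results$ci_low >= rho_min
  results$selected <- sel
  if (keep_all) results else results[sel, , drop = FALSE]
}
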