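#' @title Structured error conditions
#' @description Internal helpers that raise classed conditions so callers can
#'   `tryCatch()` on a specific failure mode rather than matching message
#'   strings. Each condition class carries its offending data in the
#'   condition object.
#' @name conditions
#' @keywords internal
NULL

stopCondition <- function(class, message, call = sys.call(-1), ...) {
  cond <- structure(
    class = c(class, "SimCascadeError", "error", "condition"),
    list(message = message, call = call, ...)
  )
  stop(cond)
}

parseError <- function(smiles, reason = "SMILES could not be parsed") {
  stopCondition("parseError",
                sprintf("%s: %s", reason, deparse1(smiles)),
                smiles = smiles)
}

embedError <- function(compoundId, reason) {
  stopCondition("embedError",
                sprintf("conformer embedding failed for '%s': %s",
                        compoundId, reason),
                compound_id = compoundId)
}

keyMissingError <- function(key, where) {
  stopCondition("keyMissingError",
                sprintf("key '%s' not found in %s", key, where), key = key)
}

duplicateKeyError <- function(key, where) {
  stopCondition("duplicateKeyError",
                sprintf("duplicate key '%s' in %s (deduplicate first)",
                        key, where), key = key)
}

incompatibleFingerprintError <- function(msg) {
  stopCondition("incompatibleFingerprintError", msg)
}

insufficientDataError <- function(n, needed) {
  stopCondition("insufficientDataError",
                sprintf("need at least %d observations, got %d", needed, n),
                n = n)
}

undefinedCorrelationError <- function(which) {
  stopCondition("undefinedCorrelationError",
                sprintf("correlation undefined: zero variance in %s", which))
}

domainError <- function(msg) {
  stopCondition("domainError", msg)
}

#' @keywords internal
logInfo <- function(fmt, ...) {
  message(sprintf(paste0("[SimCascade] ", fmt), ...))
}
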