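#' @title 2D fingerprints and the Tanimoto cascade
#'
#' @description MACCS (166 structural keys) and ECFP4 (circular, radius 2)
#' bit fingerprints, Tanimoto similarity, the all-against-all 2D scoring of
#' a drug library versus a cell-active reference set, and the dual-threshold
#' cascade filter (MACCS Tc >= 0.8 AND ECFP4 Tc >= 0.3 by default).
#'
#' @name similarity_2d
NULL

#' Compute fingerprints for a compound collection
#'
#' Fingerprints are computed on the canonical parent structures, so they are
#' invariant to the atom ordering of the input SMILES. ECFP4 is folded from
#' OpenBabel's base vector down to `nbits` by OR-folding; MACCS always has
#' 166 bits.
#'
#' @param compounds a [CompoundSet-class] (or character vector of SMILES
#'   with names as ids).
#' @param kind `"MACCS"` or `"ECFP4"`.
#' @param nbits folded length for ECFP4 (power of two, <= 4096; default
#'   2048). Ignored for MACCS.
#' @return a [FingerprintSet-class].
#' @export
fingerprints <- function(compounds, kind = c("MACCS", "ECFP4"),
                         nbits = 2048L) {
  kind <- match.arg(kind)
  if (is(compounds, "CompoundSet")) {
    smi <- compounds@structureKey
    ids <- compounds@ids
  } else {
    smi <- unname(compounds)
    ids <- names(compounds)
    if (is.null(ids)) ids <- paste0("cpd", seq_along(smi))
  }
  if (!length(smi))
    return(new("FingerprintSet", kind = kind,
               nbits = if (kind == "MACCS") 166L else as.integer(nbits),
               bits = matrix(logical(), 0,
                             if (kind == "MACCS") 166L else as.integer(nbits),
                             dimnames = list(character(), NULL))))

  mols <- ChemmineOB::forEachMol(
    "SMILES", paste(paste(smi, seq_along(smi)), collapse = "\n"), identity)
  raw <- ChemmineOB::fingerprint_OB(mols, kind)
  if (is.null(dim(raw))) raw <- matrix(raw, nrow = 1L)
  if (kind == "MACCS") {
    bits <- raw[, seq_len(166L), drop = FALSE] > 0
    nbits <- 166L
  } else {
    nbits <- as.integer(nbits)
    if (nbits < 1L || bitwAnd(nbits, nbits - 1L) != 0L)
      stop("nbits must be a power of two")
    if (nbits > ncol(raw)) nbits <- ncol(raw)
    bits <- matrix(FALSE, nrow(raw), nbits)
    for (block in seq_len(ncol(raw) / nbits)) {
      cols <- ((block - 1L) * nbits + 1L):(block * nbits)
      bits <- bits | (raw[, cols, drop = FALSE] > 0)
    }
  }
  rownames(bits) <- ids
  new("FingerprintSet", kind = kind, nbits = as.integer(nbits), bits = bits)
}

#' Tanimoto coefficient between two fingerprints
#'
#' |A intersect B| / |A union B|. Two empty bit sets are defined as
#' identical (Tc = 1); empty versus non-empty gives 0. Symmetric in its
#' arguments.
#'
#' @param a,b [Fingerprint-class] objects of the same kind and length.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  stopifnot(is(a, "Fingerprint"), is(b, "Fingerprint"))
  if (a@kind != b@kind || a@length != b@length)
    incompatibleFingerprintError(sprintf(
      "cannot compare %s(%d) with %s(%d)", a@kind, a@length, b@kind,
      b@length))
  ni <- length(intersect(a@bits, b@bits))
  nu <- length(a@bits) + length(b@bits) - ni
  if (nu == 0L) return(1.0)
  ni / nu
}

#' Pairwise Tanimoto matrix between two fingerprint sets
#'
#' @param fpsA,fpsB [FingerprintSet-class] objects of identical kind and
#'   length.
#' @return numeric matrix, rows = compounds of `fpsA`, columns = `fpsB`.
#' @export
tanimotoMatrix <- function(fpsA, fpsB) {
  stopifnot(is(fpsA, "FingerprintSet"), is(fpsB, "FingerprintSet"))
  if (fpsA@kind != fpsB@kind || fpsA@nbits != fpsB@nbits)
    incompatibleFingerprintError("fingerprint kind/length mismatch")
  A <- fpsA@bits * 1; B <- fpsB@bits * 1
  inter <- A %*% t(B)
  un <- outer(rowSums(A), rowSums(B), `+`) - inter
  tc <- ifelse(un == 0, 1, inter / un)
  dimnames(tc) <- list(rownames(fpsA@bits), rownames(fpsB@bits))
  tc
}

#' All-against-all 2D similarity of drugs versus actives
#'
#' Scores every (drug, active) pair with both MACCS and ECFP4 Tanimoto
#' coefficients. The output has exactly `length(drugs) * length(actives)`
#' rows, drugs in the outer order.
#'
#' @param drugs,actives [CompoundSet-class] objects (standardized).
#' @param nbits_ecfp4 ECFP4 folded length (default 2048).
#' @return data.frame(drug_id, active_id, tc_maccs, tc_ecfp4).
#' @export
allAgainstAll2D <- function(drugs, actives, nbits_ecfp4 = 2048L) {
  fm <- tanimotoMatrix(fingerprints(drugs, "MACCS"),
                       fingerprints(actives, "MACCS"))
  fe <- tanimotoMatrix(fingerprints(drugs, "ECFP4", nbits_ecfp4),
                       fingerprints(actives, "ECFP4", nbits_ecfp4))
  grid <- expand.grid(active_id = compoundIds(actives),
                      drug_id = compoundIds(drugs),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(drug_id = grid$drug_id, active_id = grid$active_id,
                    tc_maccs = fm[cbind(grid$drug_id, grid$active_id)],
                    tc_ecfp4 = fe[cbind(grid$drug_id, grid$active_id)])
  rownames(out) <- NULL
  out
}

#' Dual-threshold 2D cascade filter
#'
#' Retains pairs whose MACCS and ECFP4 Tanimoto coefficients are both at or
#' above their thresholds (conjunction; boundaries inclusive).
#'
#' @param pairs data.frame with columns `tc_maccs`, `tc_ecfp4` (as produced
#'   by [allAgainstAll2D()]).
#' @param t_maccs MACCS threshold (default 0.8).
#' @param t_ecfp4 ECFP4 threshold (default 0.3).
#' @return the retained subset, order preserved.
#' @export
cascadeFilter2D <- function(pairs, t_maccs = 0.8, t_ecfp4 = 0.3) {
  stopifnot(all(c("tc_maccs", "tc_ecfp4") %in% names(pairs)))
  keep <- pairs$tc_maccs >= t_maccs & pairs$tc_ecfp4 >= t_ecfp4
  logInfo("cascadeFilter2D: %d pairs in, %d retained", nrow(pairs),
          sum(keep))
  pairs[keep, , drop = FALSE]
}
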