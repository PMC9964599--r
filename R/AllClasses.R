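#' @import methods
NULL

# ---------------------------------------------------------------------------
# CompoundSet
# ---------------------------------------------------------------------------

#' CompoundSet: a standardized compound collection
#'
#' Container for standardized chemical structures. Each record keeps the raw
#' input SMILES, the canonical SMILES of the desalted parent structure (the
#' identity key used for deduplication and overlap removal), and the
#' molecular weight of the parent. `source` labels the collection the
#' records came from (the cell-active reference set or the drug library).
#'
#' @slot ids character, unique compound identifiers.
#' @slot smiles character, raw input SMILES (as supplied).
#' @slot structureKey character, canonical SMILES of the largest covalent
#'   fragment after salt stripping; identical for any two encodings of the
#'   same molecule.
#' @slot mw numeric, molecular weight of the parent structure in daltons.
#' @slot source character scalar, one of `"cell_active_set"`, `"drug_set"`
#'   or `""` when unlabelled.
#' @exportClass CompoundSet
setClass("CompoundSet",
  representation(ids = "character", smiles = "character",
                 structureKey = "character", mw = "numeric",
                 source = "character"),
  prototype(ids = character(), smiles = character(),
            structureKey = character(), mw = numeric(), source = "")
)

setValidity("CompoundSet", function(object) {
  n <- length(object@ids)
  msgs <- character()
  if (length(object@smiles) != n || length(object@structureKey) != n ||
      length(object@mw) != n)
    msgs <- c(msgs, "slot lengths differ")
  if (anyDuplicated(object@ids))
    msgs <- c(msgs, "compound ids must be unique")
  if (length(object@source) != 1L ||
      !object@source %in% c("cell_active_set", "drug_set", ""))
    msgs <- c(msgs, "source must be 'cell_active_set', 'drug_set' or ''")
  if (n > 0 && any(!is.na(object@mw) & object@mw <= 0))
    msgs <- c(msgs, "mw must be positive")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn CompoundSet number of compounds
#' @param x,object a `CompoundSet`
#' @export
setMethod("length", "CompoundSet", function(x) length(x@ids))

#' Accessors for CompoundSet
#'
#' @param x a `CompoundSet`
#' @return `compoundIds()` the identifier vector; `structureKey()` the
#'   canonical identity strings; `compoundMw()` molecular weights (Da);
#'   `compoundSmiles()` the raw input SMILES.
#' @export
compoundIds <- function(x) x@ids

#' @rdname compoundIds
#' @export
structureKey <- function(x) stats::setNames(x@structureKey, x@ids)

#' @rdname compoundIds
#' @export
compoundMw <- function(x) stats::setNames(x@mw, x@ids)

#' @rdname compoundIds
#' @export
compoundSmiles <- function(x) stats::setNames(x@smiles, x@ids)

#' @describeIn CompoundSet subset by index, logical mask or id
#' @param i index vector
#' @param j,drop,... unused
#' @export
setMethod("[", "CompoundSet", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) {
    miss <- setdiff(i, x@ids)
    if (length(miss)) keyMissingError(miss[1], "CompoundSet")
    i <- match(i, x@ids)
  }
  initialize(x, ids = x@ids[i], smiles = x@smiles[i],
             structureKey = x@structureKey[i], mw = x@mw[i])
})

setMethod("show", "CompoundSet", function(object) {
  cat(sprintf("CompoundSet of %d compounds (source: %s)\n",
              length(object), if (nzchar(object@source)) object@source
              else "unlabelled"))
  if (length(object)) {
    k <- min(3L, length(object))
    for (i in seq_len(k))
      cat(sprintf("  %s  %s  (%.1f Da)\n", object@ids[i],
                  object@structureKey[i], object@mw[i]))
    if (length(object) > k) cat(sprintf("  ... and %d more\n",
                                        length(object) - k))
  }
})

# ---------------------------------------------------------------------------
# Fingerprint / FingerprintSet
# ---------------------------------------------------------------------------

#' Fingerprint: a single binary structural fingerprint
#'
#' Sparse representation of one molecule's bit fingerprint: the sorted
#' indices of the set bits (0-based) plus the total bit length.
#'
#' @slot kind `"MACCS"` (166 structural keys) or `"ECFP4"` (circular,
#'   radius 2, folded).
#' @slot bits integer, 0-based indices of set bits, strictly increasing.
#' @slot length integer scalar, total bit count (166 for MACCS, a power of
#'   two for ECFP4).
#' @exportClass Fingerprint
setClass("Fingerprint",
  representation(kind = "character", bits = "integer", length = "integer"))

setValidity("Fingerprint", function(object) {
  msgs <- character()
  if (!object@kind %in% c("MACCS", "ECFP4"))
    msgs <- c(msgs, "kind must be 'MACCS' or 'ECFP4'")
  if (length(object@bits) &&
      (min(object@bits) < 0L || max(object@bits) >= object@length))
    msgs <- c(msgs, "bit indices out of range")
  if (is.unsorted(object@bits, strictly = TRUE) && length(object@bits) > 1)
    msgs <- c(msgs, "bit indices must be strictly increasing")
  if (length(msgs)) msgs else TRUE
})

setMethod("show", "Fingerprint", function(object) {
  cat(sprintf("%s fingerprint: %d/%d bits set\n", object@kind,
              length(object@bits), object@length))
})

#' FingerprintSet: fingerprints for a compound collection
#'
#' @slot kind `"MACCS"` or `"ECFP4"`.
#' @slot nbits integer scalar, bit length.
#' @slot bits logical matrix, compounds in rows (rownames are compound ids),
#'   bit positions in columns.
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  representation(kind = "character", nbits = "integer", bits = "matrix"))

setValidity("FingerprintSet", function(object) {
  msgs <- character()
  if (!object@kind %in% c("MACCS", "ECFP4"))
    msgs <- c(msgs, "kind must be 'MACCS' or 'ECFP4'")
  if (!is.logical(object@bits))
    msgs <- c(msgs, "bits must be a logical matrix")
  if (ncol(object@bits) != object@nbits)
    msgs <- c(msgs, "ncol(bits) must equal nbits")
  if (is.null(rownames(object@bits)) && nrow(object@bits) > 0)
    msgs <- c(msgs, "bits must have compound ids as rownames")
  if (length(msgs)) msgs else TRUE
})

setMethod("length", "FingerprintSet", function(x) nrow(x@bits))

setMethod("show", "FingerprintSet", function(object) {
  cat(sprintf("FingerprintSet: %d x %s(%d bits), mean density %.3f\n",
              nrow(object@bits), object@kind, object@nbits,
              if (nrow(object@bits)) mean(object@bits) else NA_real_))
})

#' Extract one compound's fingerprint from a FingerprintSet
#'
#' @param fps a `FingerprintSet`
#' @param id compound identifier (rowname)
#' @return a [Fingerprint-class] object
#' @export
fingerprintAt <- function(fps, id) {
  stopifnot(is(fps, "FingerprintSet"))
  if (!id %in% rownames(fps@bits)) keyMissingError(id, "FingerprintSet")
  new("Fingerprint", kind = fps@kind,
      bits = as.integer(which(fps@bits[id, ])) - 1L, length = fps@nbits)
}

# ---------------------------------------------------------------------------
# ConformerSet
# ---------------------------------------------------------------------------

#' ConformerSet: a seeded conformer ensemble for one compound
#'
#' Heavy-atom 3D conformers sharing one atom ordering, plus the typed
#' pharmacophore features derived from each conformer's geometry. Produced
#' by [generateConformers()]; consumed by the shape-overlay stage.
#'
#' @slot compoundId character scalar.
#' @slot elements character, element symbol per heavy atom.
#' @slot radii numeric, van der Waals (Bondi) radius per atom, angstroms.
#' @slot coords list of numeric matrices (atoms x 3), one per conformer,
#'   identical atom ordering.
#' @slot features list of data.frames (columns `type`, `x`, `y`, `z`), one
#'   per conformer: typed pharmacophore points (donor, acceptor, cation,
#'   anion, hydrophobe, aromatic).
#' @slot seed integer scalar used for torsion sampling.
#' @slot maxConformers integer scalar, requested ensemble ceiling.
#' @exportClass ConformerSet
setClass("ConformerSet",
  representation(compoundId = "character", elements = "character",
                 radii = "numeric", coords = "list", features = "list",
                 seed = "integer", maxConformers = "integer"))

setValidity("ConformerSet", function(object) {
  msgs <- character()
  nat <- length(object@elements)
  if (length(object@radii) != nat)
    msgs <- c(msgs, "radii/elements length mismatch")
  if (length(object@coords) < 1L)
    msgs <- c(msgs, "at least one conformer required")
  if (length(object@coords) > object@maxConformers)
    msgs <- c(msgs, "more conformers than maxConformers")
  for (m in object@coords) {
    if (!is.matrix(m) || nrow(m) != nat || ncol(m) != 3L) {
      msgs <- c(msgs, "each conformer must be an atoms x 3 matrix"); break
    }
    if (!all(is.finite(m))) { msgs <- c(msgs, "non-finite coordinates"); break }
  }
  if (length(object@features) != length(object@coords))
    msgs <- c(msgs, "one feature table per conformer required")
  if (length(msgs)) msgs else TRUE
})

#' @describeIn ConformerSet number of conformers in the ensemble
#' @param x,object a `ConformerSet`
#' @export
setMethod("length", "ConformerSet", function(x) length(x@coords))

#' Accessors for ConformerSet
#' @param x a `ConformerSet`
#' @param i conformer index
#' @return `conformerCoords()` one conformer's coordinate matrix;
#'   `conformerFeatures()` its pharmacophore feature table;
#'   `atomRadii()` the per-atom vdW radii.
#' @export
conformerCoords <- function(x, i = 1L) x@coords[[i]]

#' @rdname conformerCoords
#' @export
conformerFeatures <- function(x, i = 1L) x@features[[i]]

#' @rdname conformerCoords
#' @export
atomRadii <- function(x) x@radii

setMethod("show", "ConformerSet", function(object) {
  cat(sprintf("ConformerSet '%s': %d heavy atoms, %d conformer(s), seed %d\n",
              object@compoundId, length(object@elements),
              length(object@coords), object@seed))
})
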