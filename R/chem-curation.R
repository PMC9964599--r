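#' @title Compound and bioactivity curation
#'
#' @description Implements the curation stage of the repurposing workflow:
#' structure standardization (salt stripping, hydrogen completion, canonical
#' identity keys), the bioactivity filter rules for cell-based and
#' target-based records, best-value deduplication, active-compound selection
#' and drug/active overlap removal, plus the seven-descriptor panel used to
#' compare compound collections.
#'
#' @name chem_curation
NULL

.CELL_TYPES <- c("GI50", "EC50", "IC50")
.TARGET_TYPES <- c("IC50", "Ki", "Kd", "EC50")
.RELATIONS <- c("<", ">", "=")

.BIOACTIVITY_COLS <- c("compound_id", "activity_scope", "scope_id",
                       "standard_type", "standard_relation",
                       "standard_value", "standard_units", "assay_type",
                       "target_type", "target_organism")

#' @keywords internal
.checkBioactivityCols <- function(records) {
  miss <- setdiff(.BIOACTIVITY_COLS, names(records))
  if (length(miss))
    stop("bioactivity table is missing columns: ",
         paste(miss, collapse = ", "))
  invisible(records)
}

# ---------------------------------------------------------------------------
# Structure standardization
# ---------------------------------------------------------------------------

#' @keywords internal
.canonicalSmiles <- function(smiles) {
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "CAN", paste0(smiles, " x\n"))),
    error = function(e) "")
  can <- sub("\t.*$", "", sub("\n$", "", out))
  if (!nzchar(can)) parseError(smiles)
  can
}

#' @keywords internal
.heavyAtomCount <- function(smiles) {
  # count atoms other than explicit/implicit hydrogen from the molblock
  g <- .parseMolblock(.sdfFromSmiles(smiles), smiles)
  g$nHeavy
}

#' Standardize one raw SMILES into its parent structure
#'
#' Splits multi-fragment (salt) inputs, keeps the largest covalent fragment
#' by heavy-atom count, completes hydrogens, verifies valences, and derives
#' the canonical identity key. The key is invariant to the atom ordering of
#' the input SMILES.
#'
#' @param raw_smiles single SMILES string.
#' @param id compound identifier to attach.
#' @return a list with `id`, `smiles` (input), `structure_key` (canonical
#'   parent SMILES), `mw` (daltons).
#' @examples
#' standardizeStructure("CC(=O)[O-].[Na+]")$structure_key
#' @export
standardizeStructure <- function(raw_smiles, id = "compound") {
  if (!is.character(raw_smiles) || length(raw_smiles) != 1L ||
      is.na(raw_smiles) || !nzchar(trimws(raw_smiles)))
    parseError(raw_smiles, "empty SMILES")
  raw_smiles <- trimws(raw_smiles)

  frags <- strsplit(raw_smiles, ".", fixed = TRUE)[[1]]
  frags <- frags[nzchar(frags)]
  if (!length(frags)) parseError(raw_smiles, "empty SMILES")
  if (length(frags) > 1L) {
    sizes <- vapply(frags, .heavyAtomCount, integer(1))
    parent <- frags[[which.max(sizes)]]
  } else parent <- frags[[1]]

  g <- .parseMolblock(.sdfFromSmiles(parent), parent)
  .checkValence(g, parent)
  key <- .canonicalSmiles(parent)

  mols <- ChemmineOB::forEachMol("SMILES", paste0(key, " x"), identity)
  mw <- ChemmineOB::prop_OB(mols)$MW[1]

  list(id = id, smiles = raw_smiles, structure_key = key, mw = mw)
}

#' Standardize a vector of SMILES into a CompoundSet
#'
#' Vectorized [standardizeStructure()]. Standardization is idempotent: the
#' structure key of a key is the key itself.
#'
#' @param smiles character vector of raw SMILES.
#' @param ids unique compound identifiers (default `cpd1..cpdN`).
#' @param source collection label: `"cell_active_set"`, `"drug_set"` or `""`.
#' @param onError `"stop"` raises a `parseError` on the first bad structure;
#'   `"drop"` removes bad structures with a logged count.
#' @return a [CompoundSet-class].
#' @export
standardizeCompounds <- function(smiles, ids = NULL,
                                 source = c("", "cell_active_set",
                                            "drug_set"),
                                 onError = c("stop", "drop")) {
  source <- match.arg(source)
  onError <- match.arg(onError)
  if (is.null(ids)) ids <- paste0("cpd", seq_along(smiles))
  stopifnot(length(ids) == length(smiles), !anyDuplicated(ids))

  recs <- vector("list", length(smiles))
  bad <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    recs[[i]] <- tryCatch(standardizeStructure(smiles[i], ids[i]),
                          parseError = function(e) e)
    if (inherits(recs[[i]], "parseError")) {
      if (onError == "stop") stop(recs[[i]])
      bad[i] <- TRUE
    }
  }
  if (any(bad))
    logInfo("standardize: dropped %d of %d structures", sum(bad),
            length(smiles))
  keep <- which(!bad)
  new("CompoundSet",
      ids = ids[keep],
      smiles = vapply(recs[keep], `[[`, "", "smiles"),
      structureKey = vapply(recs[keep], `[[`, "", "structure_key"),
      mw = vapply(recs[keep], `[[`, 0, "mw"),
      source = source)
}

# ---------------------------------------------------------------------------
# Bioactivity filters
# ---------------------------------------------------------------------------

#' Filter cell-based bioactivity records
#'
#' Retains records satisfying all three clauses of the cell-assay rule:
#' standard type in \{GI50, EC50, IC50\}, standard relation in
#' \{"<", ">", "="\}, and standard units equal to the literal string "nM".
#' Order is preserved; the input is never mutated.
#'
#' @param records data.frame of bioactivity rows with `activity_scope ==
#'   "cell"`.
#' @return the retained subset, same columns and order.
#' @export
filterCellBioactivities <- function(records) {
  .checkBioactivityCols(records)
  stopifnot(all(records$activity_scope == "cell"))
  keep <- records$standard_type %in% .CELL_TYPES &
    records$standard_relation %in% .RELATIONS &
    records$standard_units == "nM"
  logInfo("filterCellBioactivities: %d in, %d retained", nrow(records),
          sum(keep))
  records[keep, , drop = FALSE]
}

#' Filter target-based bioactivity records
#'
#' Retains records satisfying the six-clause rule for target annotations
#' (type in \{IC50, Ki, Kd, EC50\}; relation "="; units "nM"; target type
#' "Single protein"; organism "Homo Sapiens"; assay type "B"), then
#' deduplicates per (compound, target) keeping the best (lowest nM) value.
#'
#' @param records data.frame of bioactivity rows with `activity_scope ==
#'   "target"`.
#' @param dedup deduplicate after filtering (default TRUE).
#' @return the retained (and deduplicated) subset.
#' @export
filterTargetBioactivities <- function(records, dedup = TRUE) {
  .checkBioactivityCols(records)
  stopifnot(all(records$activity_scope == "target"))
  keep <- records$standard_type %in% .TARGET_TYPES &
    records$standard_relation == "=" &
    records$standard_units == "nM" &
    records$target_type == "Single protein" &
    records$target_organism == "Homo Sapiens" &
    records$assay_type == "B"
  out <- records[keep, , drop = FALSE]
  logInfo("filterTargetBioactivities: %d in, %d retained", nrow(records),
          nrow(out))
  if (dedup) out <- dedupBest(out)
  out
}

#' Keep the best (most potent) record per (compound, scope) group
#'
#' Within each (compound_id, scope_id) group the record with the numerically
#' smallest standard value (lowest nM, i.e. highest potency) is retained.
#' Ties keep the first record in input order, making the result
#' deterministic.
#'
#' @param records data.frame of bioactivity rows, homogeneous in
#'   `activity_scope`.
#' @return one row per group, in order of each group's first appearance.
#' @export
dedupBest <- function(records) {
  .checkBioactivityCols(records)
  if (!nrow(records)) return(records)
  key <- paste(records$compound_id, records$scope_id, sep = "\r")
  ord <- order(match(key, unique(key)), records$standard_value,
               seq_len(nrow(records)))
  r <- records[ord, , drop = FALSE]
  out <- r[!duplicated(paste(r$compound_id, r$scope_id, sep = "\r")), ,
           drop = FALSE]
  logInfo("dedupBest: %d in, %d groups", nrow(records), nrow(out))
  out
}

#' Select active compounds by potency and molecular weight
#'
#' A compound qualifies when at least one of its (deduplicated) cell records
#' certifies potency at or below the cutoff and its molecular weight falls
#' in the closed range. Records with relation "=" or "<" and value <= cutoff
#' certify; ">" records never do (a lower bound cannot prove potency).
#'
#' @param records deduplicated cell-scope bioactivity rows.
#' @param compounds a [CompoundSet-class] resolving every compound_id.
#' @param potency_cutoff_nm potency cutoff in nM (default 1000 = 1 uM).
#' @param mw_range closed molecular-weight window in daltons.
#' @return character vector of qualifying compound ids (first-appearance
#'   order).
#' @export
selectActives <- function(records, compounds, potency_cutoff_nm = 1000,
                          mw_range = c(180, 850)) {
  .checkBioactivityCols(records)
  mwtab <- compoundMw(compounds)
  miss <- setdiff(unique(records$compound_id), names(mwtab))
  if (length(miss)) keyMissingError(miss[1], "CompoundSet")
  certifies <- records$standard_relation %in% c("=", "<") &
    records$standard_value <= potency_cutoff_nm
  ids <- unique(records$compound_id[certifies])
  mwok <- mwtab[ids] >= mw_range[1] & mwtab[ids] <= mw_range[2]
  out <- ids[mwok]
  logInfo("selectActives: %d compounds in, %d selected",
          length(unique(records$compound_id)), length(out))
  out
}

#' Remove drugs structurally present in the active set
#'
#' Drops every drug whose canonical structure key occurs among the actives;
#' identity is judged on the desalted parent structure, not the raw SMILES.
#'
#' @param drug_set,active_set [CompoundSet-class] objects.
#' @return the filtered drug `CompoundSet`.
#' @export
removeOverlap <- function(drug_set, active_set) {
  stopifnot(is(drug_set, "CompoundSet"), is(active_set, "CompoundSet"))
  keep <- !(drug_set@structureKey %in% active_set@structureKey)
  logInfo("removeOverlap: %d drugs in, %d retained", length(drug_set),
          sum(keep))
  drug_set[which(keep)]
}

# ---------------------------------------------------------------------------
# Descriptor panel
# ---------------------------------------------------------------------------

#' Compute the seven-descriptor comparison panel
#'
#' LogP, topological polar surface area, hydrogen-bond donor and acceptor
#' counts and molecular weight are delegated to OpenBabel's standard
#' definitions. Molecular volume is estimated on a grid over the heavy-atom
#' van der Waals spheres (Bondi radii) of the lowest-index conformer;
#' ovality is the molecular (vdW) surface area divided by the surface area
#' of the sphere of equal volume (>= 1, = 1 for a single sphere). Set
#' `ovality = "reciprocal"` for the inverse convention (< 1 scale).
#'
#' @param smiles standardized SMILES (one structure).
#' @param grid grid spacing in angstrom for the volume estimate.
#' @param ovality `"ratio"` (surface/sphere-surface, default) or
#'   `"reciprocal"`.
#' @param seed seed for the conformer used for volume/ovality.
#' @return data.frame with columns logp, psa, hbd, hba, mw, volume, ovality.
#' @export
computeDescriptors <- function(smiles, grid = 0.2,
                               ovality = c("ratio", "reciprocal"),
                               seed = 1L) {
  ovality <- match.arg(ovality)
  mols <- ChemmineOB::forEachMol("SMILES", paste0(smiles, " x"), identity)
  p <- ChemmineOB::prop_OB(mols)

  cs <- generateConformers(smiles, n = 1L, seed = seed, id = "desc")
  xyz <- conformerCoords(cs, 1L)
  vol <- gridVolume(xyz, atomRadii(cs), grid)
  sa <- vdwSurfaceArea(xyz, atomRadii(cs))
  rEq <- (3 * vol / (4 * pi))^(1 / 3)
  ov <- sa / (4 * pi * rEq^2)
  if (ovality == "reciprocal") ov <- 1 / ov

  data.frame(logp = p$logP[1], psa = p$TPSA[1], hbd = p$HBD[1],
             hba = p$HBA2[1], mw = p$MW[1], volume = vol, ovality = ov)
}

#' Grid estimate of the union volume of van der Waals spheres
#'
#' @param xyz heavy-atom coordinate matrix (angstrom).
#' @param radii per-atom radii (angstrom).
#' @param grid grid spacing (angstrom).
#' @return volume in cubic angstrom.
#' @export
gridVolume <- function(xyz, radii, grid = 0.2) {
  stopifnot(nrow(xyz) == length(radii), all(is.finite(xyz)))
  cpp_grid_volume(xyz, radii, grid)
}

#' van der Waals surface area by sphere-point sampling
#'
#' Shrake-Rupley style: points are distributed quasi-uniformly on each atom
#' sphere and counted when not buried inside any other sphere.
#'
#' @param xyz heavy-atom coordinate matrix (angstrom).
#' @param radii per-atom radii (angstrom).
#' @param npoints sphere points per atom.
#' @return surface area in square angstrom.
#' @export
vdwSurfaceArea <- function(xyz, radii, npoints = 512L) {
  stopifnot(nrow(xyz) == length(radii))
  cpp_vdw_surface(xyz, radii, as.integer(npoints))
}
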