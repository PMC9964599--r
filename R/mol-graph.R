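## Molecular graph utilities shared by the descriptor, conformer and
## pharmacophore code. Structures enter as SMILES; OpenBabel (via ChemmineOB)
## supplies the connection table and a deterministic 2D depiction layout that
## seeds the 3D builder. Only heavy atoms are retained in the graph; hydrogen
## counts per heavy atom are recorded for donor typing and valence checks.

# Bondi van der Waals radii (angstrom); fallback 1.7 for unparameterized
# elements keeps the shape stage defined on exotic inputs.
.BONDI <- c(H = 1.20, C = 1.70, N = 1.55, O = 1.52, F = 1.47, P = 1.80,
            S = 1.80, Cl = 1.75, Br = 1.85, I = 1.98, B = 1.92, Si = 2.10,
            Se = 1.90, Ne = 1.54)

vdwRadius <- function(elements) {
  r <- .BONDI[elements]
  r[is.na(r)] <- 1.70
  unname(r)
}

# Maximum bond-order sum (after implicit H completion) tolerated per neutral
# element; a positive/negative formal charge shifts the allowance by one.
.MAX_VALENCE <- c(C = 4, N = 3, O = 2, F = 1, Cl = 1, Br = 1, I = 1,
                  S = 6, P = 5, B = 3, Si = 4, Se = 6, H = 1, Ne = 0)

# 2D depiction layouts use unit bond lengths; scale to a typical covalent
# bond length in angstroms.
.BOND_SCALE <- 1.5

#' @keywords internal
.sdfFromSmiles <- function(smiles, title = "mol", gen2d = TRUE,
                           addH = TRUE) {
  nms <- c(if (gen2d) "gen2d", if (addH) "h")
  opts <- if (length(nms))
    data.frame(names = nms, args = rep("", length(nms)))
  else NULL
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(smiles, " ", title, "\n"), options = opts)),
    error = function(e) "")
  if (!nzchar(out) || !grepl("V2000", out, fixed = TRUE))
    parseError(smiles)
  out
}

# Parse one V2000 molblock into an annotated heavy-atom graph.
#
# Returns list(elements, coords [heavy x 3, angstrom-scaled 2D layout],
# hcount, charge, bonds data.frame(a, b, order), aromaticAtoms (logical),
# aromaticRings (list of heavy-atom index vectors), nHeavy).
#' @keywords internal
.parseMolblock <- function(sdfstr, smiles = "") {
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  natoms <- as.integer(substr(counts, 1, 3))
  nbonds <- as.integer(substr(counts, 4, 6))
  if (is.na(natoms) || natoms < 1L) parseError(smiles, "empty molecule")

  atomLines <- lines[5:(4 + natoms)]
  xyz <- matrix(0, natoms, 3)
  xyz[, 1] <- as.numeric(substr(atomLines, 1, 10))
  xyz[, 2] <- as.numeric(substr(atomLines, 11, 20))
  xyz[, 3] <- as.numeric(substr(atomLines, 21, 30))
  elements <- trimws(substr(atomLines, 32, 34))

  bonds <- if (nbonds > 0) {
    bl <- lines[(5 + natoms):(4 + natoms + nbonds)]
    data.frame(a = as.integer(substr(bl, 1, 3)),
               b = as.integer(substr(bl, 4, 6)),
               order = as.integer(substr(bl, 7, 9)))
  } else data.frame(a = integer(), b = integer(), order = integer())

  charge <- integer(natoms)
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    toks <- as.integer(strsplit(trimws(sub("^M  CHG *[0-9]+", "", ln)),
                                "[[:space:]]+")[[1]])
    if (length(toks) >= 2)
      for (k in seq(1, length(toks) - 1, by = 2))
        charge[toks[k]] <- toks[k + 1]
  }

  isH <- elements == "H"
  heavyIdx <- which(!isH)
  if (!length(heavyIdx)) parseError(smiles, "no heavy atoms")
  map <- integer(natoms); map[heavyIdx] <- seq_along(heavyIdx)

  hcount <- integer(length(heavyIdx))
  keep <- logical(nrow(bonds))
  for (i in seq_len(nrow(bonds))) {
    a <- bonds$a[i]; b <- bonds$b[i]
    if (isH[a] && !isH[b]) hcount[map[b]] <- hcount[map[b]] + 1L
    else if (isH[b] && !isH[a]) hcount[map[a]] <- hcount[map[a]] + 1L
    else if (!isH[a] && !isH[b]) keep[i] <- TRUE
  }
  hb <- bonds[keep, , drop = FALSE]
  hb$a <- map[hb$a]; hb$b <- map[hb$b]

  list(elements = elements[heavyIdx],
       coords = xyz[heavyIdx, , drop = FALSE] * .BOND_SCALE,
       hcount = hcount, charge = charge[heavyIdx],
       bonds = hb, nHeavy = length(heavyIdx))
}

# Aromatic ring perception on the heavy-atom graph via ChemmineR's ring
# finder (applied to the same molblock).
#' @keywords internal
.aromaticRings <- function(sdfstr) {
  sdf <- suppressWarnings(ChemmineR::read.SDFset(ChemmineR::read.SDFstr(
    strsplit(sdfstr, "\n", fixed = TRUE)[[1]])))
  r <- tryCatch(ChemmineR::rings(sdf[[1]], type = "all", arom = TRUE),
                error = function(e) list(RINGS = list(), AROMATIC = logical()))
  if (!length(r$RINGS)) return(list())
  idx <- lapply(r$RINGS, function(at) as.integer(sub("^[A-Za-z]+_", "", at)))
  idx[which(r$AROMATIC)]
}

#' Build the annotated heavy-atom graph for one structure
#'
#' @param smiles a single SMILES string (already standardized).
#' @return a list with elements, angstrom-scaled planar coordinates, per-atom
#'   hydrogen counts and formal charges, the heavy-atom bond table, aromatic
#'   ring membership, and per-atom vdW radii.
#' @keywords internal
molGraph <- function(smiles) {
  sdfstr <- .sdfFromSmiles(smiles)
  g <- .parseMolblock(sdfstr, smiles)
  aromRingsAll <- .aromaticRings(sdfstr)
  # ring indices refer to the full (H-included) molblock written in the same
  # atom order; H atoms never occur in rings, and heavy atoms precede any
  # renumbering only through `map` in .parseMolblock. Reconstruct the map.
  lines <- strsplit(sdfstr, "\n", fixed = TRUE)[[1]]
  natoms <- as.integer(substr(lines[4], 1, 3))
  elementsAll <- trimws(substr(lines[5:(4 + natoms)], 32, 34))
  map <- integer(natoms); map[elementsAll != "H"] <- seq_len(g$nHeavy)
  g$aromaticRings <- lapply(aromRingsAll, function(ix) map[ix])
  g$aromaticAtoms <- logical(g$nHeavy)
  for (ring in g$aromaticRings) g$aromaticAtoms[ring] <- TRUE
  g$ringBond <- .ringBondFlags(g$bonds, g$nHeavy)
  g$radii <- vdwRadius(g$elements)
  g$smiles <- smiles
  g
}

# Flag bonds that lie in any cycle (removal does not disconnect the graph).
#' @keywords internal
.ringBondFlags <- function(bonds, n) {
  m <- nrow(bonds)
  if (!m) return(logical())
  adj <- vector("list", n)
  for (i in seq_len(m)) {
    adj[[bonds$a[i]]] <- c(adj[[bonds$a[i]]], i)
    adj[[bonds$b[i]]] <- c(adj[[bonds$b[i]]], i)
  }
  vapply(seq_len(m), function(drop) {
    src <- bonds$a[drop]; dst <- bonds$b[drop]
    seen <- logical(n); seen[src] <- TRUE; queue <- src
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (bi in adj[[v]]) {
        if (bi == drop) next
        w <- if (bonds$a[bi] == v) bonds$b[bi] else bonds$a[bi]
        if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
      }
    }
    seen[dst]
  }, logical(1))
}

# Valence sanity check: bond-order sum + implicit H must not exceed the
# element's allowance (shifted by formal charge). OpenBabel is permissive,
# so hypervalent mistakes like pentavalent carbon are caught here.
#' @keywords internal
.checkValence <- function(g, smiles) {
  bsum <- numeric(g$nHeavy)
  if (nrow(g$bonds))
    for (i in seq_len(nrow(g$bonds))) {
      o <- g$bonds$order[i]
      if (o == 4) o <- 1.5  # aromatic molfile bond
      bsum[g$bonds$a[i]] <- bsum[g$bonds$a[i]] + o
      bsum[g$bonds$b[i]] <- bsum[g$bonds$b[i]] + o
    }
  tot <- ceiling(bsum - 1e-9) + g$hcount
  maxv <- .MAX_VALENCE[g$elements]
  maxv[is.na(maxv)] <- 6
  maxv <- maxv + ifelse(g$elements %in% c("N", "O"), pmax(g$charge, 0),
                        abs(g$charge) * 0)
  bad <- which(tot > maxv & !(g$elements == "S" & tot <= 6) &
                 !(g$elements == "P" & tot <= 5))
  if (length(bad))
    parseError(smiles, sprintf("illegal valence on atom %d (%s)",
                               bad[1], g$elements[bad[1]]))
  invisible(TRUE)
}
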