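#' @title Gaussian shape overlay and TanimotoCombo scoring
#'
#' @description Open re-implementation of 3D ligand shape comparison with
#' the familiar score semantics: each heavy atom is modelled as an isotropic
#' Gaussian of amplitude 2.7 whose integral equals its hard-sphere volume;
#' first-order pairwise overlap volumes give ShapeTanimoto
#' \eqn{V_{AB} / (V_{AA} + V_{BB} - V_{AB})} after rigid-body optimization
#' (principal-axes alignment, four axis-flip starts, Nelder-Mead
#' refinement). ColorTanimoto scores same-type pharmacophore feature overlap
#' at the optimal shape transform, and TanimotoCombo is their sum, in
#' [0, 2].
#'
#' @name shape_3d
NULL

.GAUSS_P <- 2.7
.COLOR_ALPHA <- 0.5   # 1/(2*width^2) with feature width 1.0 angstrom
.COLOR_P <- 2.7

#' Gaussian width parameter matching an atom's hard-sphere volume
#'
#' Solves `p * (pi/alpha)^{3/2} = 4/3 * pi * r^3` for alpha.
#'
#' @param r vdW radius (angstrom).
#' @param p Gaussian amplitude (default 2.7).
#' @return alpha in 1/angstrom^2.
#' @export
alphaFromRadius <- function(r, p = .GAUSS_P) {
  pi * (3 * p / (4 * pi * r^3))^(2 / 3)
}

#' First-order Gaussian overlap volume between two conformers
#'
#' @param xyzA,xyzB heavy-atom coordinates (angstrom).
#' @param radiiA,radiiB per-atom vdW radii.
#' @param transform optional rigid transform (as returned by
#'   [optimizeOverlay()]) applied to `xyzA` first.
#' @param p Gaussian amplitude.
#' @return overlap volume in cubic angstrom; symmetric under swapping the
#'   arguments with the inverse transform.
#' @export
gaussianOverlapVolume <- function(xyzA, radiiA, xyzB, radiiB,
                                  transform = NULL, p = .GAUSS_P) {
  if (!is.null(transform)) xyzA <- applyTransform(xyzA, transform)
  cpp_overlap_volume(xyzA, alphaFromRadius(radiiA, p),
                     xyzB, alphaFromRadius(radiiB, p), p)
}

#' Apply a rigid transform
#'
#' @param xyz coordinate matrix.
#' @param transform list with `center`, `R` (3x3 rotation) and `shift`.
#' @return transformed coordinates `(xyz - center) %*% R + shift`.
#' @export
applyTransform <- function(xyz, transform) {
  sweep(sweep(xyz, 2, transform$center) %*% transform$R, 2,
        transform$shift, `+`)
}

#' @keywords internal
identityTransform <- function() {
  list(center = c(0, 0, 0), R = diag(3), shift = c(0, 0, 0))
}

# Deterministic canonical frame: centroid at the origin, axes along the
# principal axes of the coordinate spread, signs fixed so the largest-
# magnitude loading of each axis is positive, right-handed, coordinates
# rounded to 1e-6 angstrom. Rounding makes the optimizer's input - and so
# its output - invariant to any rigid pre-transformation of the molecule.
#' @keywords internal
.canonicalFrame <- function(xyz) {
  ctr <- colMeans(xyz)
  X <- sweep(xyz, 2, ctr)
  C <- crossprod(X) / nrow(X)
  e <- eigen(C, symmetric = TRUE)
  Q <- e$vectors
  for (k in 1:3) {
    v <- Q[, k]
    if (v[which.max(abs(v))] < 0) Q[, k] <- -v
  }
  if (det(Q) < 0) Q[, 3] <- -Q[, 3]
  list(coords = round(X %*% Q, 6), center = ctr, Q = Q)
}

#' @keywords internal
.rotvecToMatrix <- function(w) {
  th <- sqrt(sum(w^2))
  if (th < 1e-12) return(diag(3))
  u <- w / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

.FLIPS <- list(diag(c(1, 1, 1)), diag(c(1, -1, -1)),
               diag(c(-1, 1, -1)), diag(c(-1, -1, 1)))

#' Optimize the rigid overlay of two conformers
#'
#' Maximizes ShapeTanimoto over rigid transforms: both molecules are put in
#' their canonical principal-axes frames, the four proper axis flips seed
#' the search, and each start is refined with Nelder-Mead over the six
#' rigid-body parameters (at most `maxit` iterations, objective tolerance
#' `reltol`).
#'
#' @param xyzA,xyzB heavy-atom coordinates.
#' @param radiiA,radiiB per-atom vdW radii.
#' @param refine run Nelder-Mead refinement after the flip starts (default
#'   TRUE; FALSE gives the cheap alignment-only score used for ensemble
#'   pre-screening).
#' @param maxit,reltol Nelder-Mead controls.
#' @param all_starts also return the refined result of every flip start in
#'   `$starts` (used by the ensemble scorer to break shape-degenerate
#'   alignment ties by pharmacophore overlap).
#' @return list with `transform` (maps `xyzA` into `xyzB`'s frame),
#'   `shape_tanimoto`, and the overlap volumes `vab`, `vaa`, `vbb`; with
#'   `all_starts`, additionally `starts`, a list of
#'   (transform, shape_tanimoto) per flip.
#' @export
optimizeOverlay <- function(xyzA, radiiA, xyzB, radiiB, refine = TRUE,
                            maxit = 200L, reltol = 1e-4,
                            all_starts = FALSE) {
  alphaA <- alphaFromRadius(radiiA)
  alphaB <- alphaFromRadius(radiiB)
  fa <- .canonicalFrame(xyzA)
  fb <- .canonicalFrame(xyzB)
  A <- fa$coords; B <- fb$coords
  vaa <- cpp_overlap_volume(A, alphaA, A, alphaA, .GAUSS_P)
  vbb <- cpp_overlap_volume(B, alphaB, B, alphaB, .GAUSS_P)

  evalVab <- function(flip, par) {
    R <- .rotvecToMatrix(par[1:3]) %*% flip
    At <- A %*% t(R)
    At <- sweep(At, 2, par[4:6], `+`)
    cpp_overlap_volume(At, alphaA, B, alphaB, .GAUSS_P)
  }
  # compose: x -> ((x - centerA) %*% Qa %*% t(R) + t) %*% t(Qb) + centerB
  asResult <- function(flip, par, vab) {
    R <- .rotvecToMatrix(par[1:3]) %*% flip
    list(transform = list(center = fa$center,
                          R = fa$Q %*% t(R) %*% t(fb$Q),
                          shift = drop(par[4:6] %*% t(fb$Q)) + fb$center),
         shape_tanimoto = vab / (vaa + vbb - vab),
         vab = vab, vaa = vaa, vbb = vbb)
  }

  starts <- vector("list", length(.FLIPS))
  for (fi in seq_along(.FLIPS)) {
    flip <- .FLIPS[[fi]]
    par <- rep(0, 6); vab <- evalVab(flip, par)
    if (refine) {
      opt <- stats::optim(rep(0, 6), function(p) -evalVab(flip, p),
                          method = "Nelder-Mead",
                          control = list(maxit = maxit, reltol = reltol))
      if (-opt$value > vab) { vab <- -opt$value; par <- opt$par }
    }
    starts[[fi]] <- asResult(flip, par, vab)
  }
  best <- starts[[which.max(vapply(starts, `[[`, 0, "vab"))]]
  if (all_starts) best$starts <- starts
  best
}

#' Pharmacophore (color) Tanimoto at a given transform
#'
#' Gaussian overlap restricted to same-type feature pairs (width 1.0
#' angstrom, amplitude 2.7), normalized as
#' \eqn{C_{AB} / (C_{AA} + C_{BB} - C_{AB})}. Returns 0 when either
#' molecule has no features.
#'
#' @param featA,featB feature data.frames (`type`, `x`, `y`, `z`) from
#'   [conformerFeatures()].
#' @param transform rigid transform applied to `featA` coordinates.
#' @return similarity in [0, 1].
#' @export
colorTanimoto <- function(featA, featB, transform = NULL) {
  if (!nrow(featA) || !nrow(featB)) return(0)
  xa <- as.matrix(featA[, c("x", "y", "z")])
  xb <- as.matrix(featB[, c("x", "y", "z")])
  if (!is.null(transform)) xa <- applyTransform(xa, transform)
  ta <- match(featA$type, .FEATURE_TYPES)
  tb <- match(featB$type, .FEATURE_TYPES)
  cab <- cpp_feature_overlap(ta, xa, tb, xb, .COLOR_ALPHA, .COLOR_P)
  caa <- cpp_feature_overlap(ta, xa, ta, xa, .COLOR_ALPHA, .COLOR_P)
  cbb <- cpp_feature_overlap(tb, xb, tb, xb, .COLOR_ALPHA, .COLOR_P)
  denom <- caa + cbb - cab
  if (denom <= 0) return(0)
  max(0, min(1, cab / denom))
}

#' @keywords internal
.comboDirected <- function(confA, confB, prescreen_keep) {
  nA <- length(confA); nB <- length(confB)
  pairs <- expand.grid(i = seq_len(nA), j = seq_len(nB))

  comboOf <- function(i, j, ov) {
    # among the refined flip starts, shape ties can hide large color
    # differences (near-symmetric scaffolds); pick the start with the best
    # shape+color sum
    cands <- if (!is.null(ov$starts)) ov$starts else list(ov)
    best <- NULL
    for (cand in cands) {
      st <- max(0, min(1, cand$shape_tanimoto))
      ct <- colorTanimoto(confA@features[[i]], confB@features[[j]],
                          cand$transform)
      if (is.null(best) || st + ct > best$combo)
        best <- list(combo = st + ct, st = st, ct = ct,
                     transform = cand$transform)
    }
    best
  }

  if (nrow(pairs) > prescreen_keep) {
    pre <- vapply(seq_len(nrow(pairs)), function(k) {
      ov <- optimizeOverlay(confA@coords[[pairs$i[k]]], confA@radii,
                            confB@coords[[pairs$j[k]]], confB@radii,
                            refine = FALSE, all_starts = TRUE)
      comboOf(pairs$i[k], pairs$j[k], ov)$combo
    }, 0)
    pairs <- pairs[order(-pre)[seq_len(prescreen_keep)], , drop = FALSE]
  }

  best <- NULL
  for (k in seq_len(nrow(pairs))) {
    i <- pairs$i[k]; j <- pairs$j[k]
    ov <- optimizeOverlay(confA@coords[[i]], confA@radii,
                          confB@coords[[j]], confB@radii,
                          all_starts = TRUE)
    res <- comboOf(i, j, ov)
    if (is.null(best) || res$combo > best$tanimoto_combo)
      best <- list(drug_id = confA@compoundId,
                   active_id = confB@compoundId,
                   shape_tanimoto = res$st, color_tanimoto = res$ct,
                   tanimoto_combo = res$combo,
                   best_conformer_pair = c(i, j),
                   best_transform = res$transform)
  }
  best
}

#' @keywords internal
.invertTransform <- function(tr) {
  list(center = tr$shift, R = t(tr$R), shift = tr$center)
}

#' TanimotoCombo between two conformer ensembles
#'
#' Every conformer pair is overlaid (shape optimization first, color scored
#' at the optimal shape transform) and the best shape+color sum is
#' reported. For ensembles larger than `prescreen_keep` pairs, an
#' alignment-only pre-screen ranks the conformer pairs and only the top
#' pairs get full Nelder-Mead refinement. The overlay is run in both
#' directions and the better result kept, so the score is symmetric in its
#' arguments by construction.
#'
#' @param confA,confB [ConformerSet-class] objects (e.g. drug and active).
#' @param prescreen_keep number of conformer pairs refined after the
#'   pre-screen (default 3).
#' @return list with `drug_id`, `active_id`, `shape_tanimoto`,
#'   `color_tanimoto`, `tanimoto_combo`, `best_conformer_pair` (pair of
#'   indices, first index into `confA`) and `best_transform` (maps `confA`
#'   coordinates onto `confB`).
#' @export
tanimotoCombo <- function(confA, confB, prescreen_keep = 3L) {
  stopifnot(is(confA, "ConformerSet"), is(confB, "ConformerSet"))
  fwd <- .comboDirected(confA, confB, prescreen_keep)
  rev <- .comboDirected(confB, confA, prescreen_keep)
  if (rev$tanimoto_combo > fwd$tanimoto_combo) {
    fwd <- list(drug_id = confA@compoundId, active_id = confB@compoundId,
                shape_tanimoto = rev$shape_tanimoto,
                color_tanimoto = rev$color_tanimoto,
                tanimoto_combo = rev$tanimoto_combo,
                best_conformer_pair = rev(rev$best_conformer_pair),
                best_transform = .invertTransform(rev$best_transform))
  }
  fwd
}

#' Score 2D-cascade survivor pairs with the 3D stage
#'
#' Generates conformer ensembles lazily (one per distinct compound) and
#' scores each surviving (drug, active) pair with [tanimotoCombo()].
#'
#' @param pairs data.frame with columns `drug_id`, `active_id` (2D-cascade
#'   survivors).
#' @param drugs,actives [CompoundSet-class] objects resolving the ids.
#' @param n_conformers ensemble ceiling per compound.
#' @param seed master seed; each compound's ensemble seed is derived from
#'   it deterministically.
#' @return data.frame(drug_id, active_id, shape_tanimoto, color_tanimoto,
#'   tanimoto_combo, conf_drug, conf_active).
#' @export
overlayScores <- function(pairs, drugs, actives, n_conformers = 10L,
                          seed = 1L) {
  keys <- c(structureKey(drugs), structureKey(actives))
  cache <- new.env(parent = emptyenv())
  ensemble <- function(cid) {
    if (!is.null(cache[[cid]])) return(cache[[cid]])
    if (!cid %in% names(keys)) keyMissingError(cid, "compound sets")
    cs <- generateConformers(keys[[cid]], n = n_conformers,
                             seed = .deriveSeed(seed, cid), id = cid)
    cache[[cid]] <- cs
    cs
  }
  rows <- vector("list", nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    sc <- tanimotoCombo(ensemble(pairs$drug_id[k]),
                        ensemble(pairs$active_id[k]))
    rows[[k]] <- data.frame(
      drug_id = sc$drug_id, active_id = sc$active_id,
      shape_tanimoto = sc$shape_tanimoto,
      color_tanimoto = sc$color_tanimoto,
      tanimoto_combo = sc$tanimoto_combo,
      conf_drug = sc$best_conformer_pair[1],
      conf_active = sc$best_conformer_pair[2])
  }
  out <- if (length(rows)) do.call(rbind, rows)
  else data.frame(drug_id = character(), active_id = character(),
                  shape_tanimoto = numeric(), color_tanimoto = numeric(),
                  tanimoto_combo = numeric(), conf_drug = integer(),
                  conf_active = integer())
  rownames(out) <- NULL
  out
}

# Stable per-compound seed derived from the master seed and the id string
# (kept below 2^31).
#' @keywords internal
.deriveSeed <- function(seed, id) {
  h <- 0
  for (ch in utf8ToInt(id)) h <- (h * 31 + ch) %% 1000003
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483587)
}

#' TanimotoCombo cascade filter
#'
#' Retains overlay scores with `tanimoto_combo >= t_combo` (default 1.5).
#'
#' @param scores data.frame from [overlayScores()].
#' @param t_combo threshold in [0, 2].
#' @return the retained subset, order preserved.
#' @export
cascadeFilter3D <- function(scores, t_combo = 1.5) {
  stopifnot("tanimoto_combo" %in% names(scores))
  keep <- scores$tanimoto_combo >= t_combo
  logInfo("cascadeFilter3D: %d scores in, %d retained", nrow(scores),
          sum(keep))
  scores[keep, , drop = FALSE]
}
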