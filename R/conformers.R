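#' @title Deterministic seeded conformer ensembles
#'
#' @description The 3D similarity stage needs reproducible conformer
#' ensembles. The builder starts from OpenBabel's deterministic planar
#' depiction layout (scaled to angstrom bond lengths), then lifts the
#' structure into 3D by sampling seeded torsion angles around every
#' acyclic rotatable bond. Candidates with steric clashes are rejected and
#' the accepted ensemble is pruned so every pair of conformers differs by
#' at least `min_rmsd` heavy-atom RMSD after optimal superposition. All
#' randomness flows from the `seed` argument, so identical inputs give
#' bitwise-identical coordinates.
#'
#' @name shape_3d_conformers
NULL

#' @keywords internal
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(expr)
}

# Rotatable bonds: acyclic single bonds between two non-terminal heavy
# atoms, excluding amide C-N bonds (kept planar).
#' @keywords internal
.rotatableBonds <- function(g) {
  if (!nrow(g$bonds)) return(integer())
  deg <- tabulate(c(g$bonds$a, g$bonds$b), g$nHeavy)
  amide <- logical(nrow(g$bonds))
  # an amide bond: C(=O)-N
  dblO <- rep(FALSE, g$nHeavy)
  for (i in seq_len(nrow(g$bonds)))
    if (g$bonds$order[i] == 2) {
      if (g$elements[g$bonds$a[i]] == "O") dblO[g$bonds$b[i]] <- TRUE
      if (g$elements[g$bonds$b[i]] == "O") dblO[g$bonds$a[i]] <- TRUE
    }
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$a[i]; b <- g$bonds$b[i]
    amide[i] <- (g$elements[a] == "N" && dblO[b]) ||
      (g$elements[b] == "N" && dblO[a])
  }
  which(g$bonds$order == 1 & !g$ringBond & deg[g$bonds$a] > 1L &
          deg[g$bonds$b] > 1L & !amide)
}

# Atoms on the `b` side of acyclic bond (a, b).
#' @keywords internal
.bondSide <- function(g, bondIdx) {
  a <- g$bonds$a[bondIdx]; b <- g$bonds$b[bondIdx]
  adj <- vector("list", g$nHeavy)
  for (i in seq_len(nrow(g$bonds))) {
    if (i == bondIdx) next
    adj[[g$bonds$a[i]]] <- c(adj[[g$bonds$a[i]]], g$bonds$b[i])
    adj[[g$bonds$b[i]]] <- c(adj[[g$bonds$b[i]]], g$bonds$a[i])
  }
  seen <- logical(g$nHeavy); seen[b] <- TRUE; queue <- b
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    for (w in adj[[v]]) if (!seen[w]) { seen[w] <- TRUE; queue <- c(queue, w) }
  }
  which(seen)
}

# Rotate `side` atoms by `angle` radians about the a->b bond axis.
#' @keywords internal
.rotateAboutBond <- function(xyz, a, b, side, angle) {
  axis <- xyz[b, ] - xyz[a, ]
  nrm <- sqrt(sum(axis^2))
  if (nrm < 1e-9) return(xyz)
  u <- axis / nrm
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  pivot <- xyz[a, ]
  xyz[side, ] <- sweep(sweep(xyz[side, , drop = FALSE], 2, pivot) %*% t(R),
                       2, pivot, `+`)
  xyz
}

#' Heavy-atom RMSD after optimal (Kabsch) superposition
#'
#' @param xyzA,xyzB coordinate matrices with identical atom ordering.
#' @return RMSD in angstrom.
#' @export
alignedRmsd <- function(xyzA, xyzB) {
  stopifnot(nrow(xyzA) == nrow(xyzB))
  A <- sweep(xyzA, 2, colMeans(xyzA))
  B <- sweep(xyzB, 2, colMeans(xyzB))
  s <- svd(t(A) %*% B)
  d <- sign(det(s$v %*% t(s$u)))
  R <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  sqrt(mean(rowSums((A %*% t(R) - B)^2)))
}

#' @keywords internal
.clashPairs <- function(g) {
  n <- g$nHeavy
  if (n < 4L) return(matrix(integer(), 0, 2))
  # graph distances via BFS; exclude 1-2 and 1-3 pairs from the clash check
  adj <- vector("list", n)
  for (i in seq_len(nrow(g$bonds))) {
    adj[[g$bonds$a[i]]] <- c(adj[[g$bonds$a[i]]], g$bonds$b[i])
    adj[[g$bonds$b[i]]] <- c(adj[[g$bonds$b[i]]], g$bonds$a[i])
  }
  near <- matrix(FALSE, n, n)
  for (v in seq_len(n)) {
    near[v, v] <- TRUE
    for (w in adj[[v]]) {
      near[v, w] <- TRUE
      for (u in adj[[w]]) near[v, u] <- TRUE
    }
  }
  idx <- which(upper.tri(near) & !near, arr.ind = TRUE)
  storage.mode(idx) <- "integer"
  idx
}

#' Generate a seeded conformer ensemble
#'
#' @param smiles standardized SMILES of the compound.
#' @param n ensemble ceiling (default 10).
#' @param seed integer seed controlling torsion sampling.
#' @param id compound identifier stored in the result.
#' @param min_rmsd pruning threshold: accepted conformers differ pairwise by
#'   at least this heavy-atom RMSD (angstrom, default 0.5).
#' @param clash_dist minimum allowed distance between atoms separated by
#'   three or more bonds (angstrom).
#' @param max_tries candidate draws before giving up on filling the
#'   ensemble.
#' @return a [ConformerSet-class] with 1..n conformers.
#' @export
generateConformers <- function(smiles, n = 10L, seed = 1L, id = "compound",
                               min_rmsd = 0.5, clash_dist = 1.8,
                               max_tries = 8L * n) {
  g <- tryCatch(molGraph(smiles), parseError = function(e) stop(e))
  base <- g$coords
  if (!all(is.finite(base))) embedError(id, "layout produced non-finite coordinates")

  rot <- .rotatableBonds(g)
  sides <- lapply(rot, function(bi) .bondSide(g, bi))
  clash <- .clashPairs(g)
  minDist <- function(xyz) {
    if (!nrow(clash)) Inf else cpp_min_pair_dist(xyz, clash)
  }

  confs <- list(base)
  .withSeed(seed, {
    if (length(rot) && n > 1L) {
      tries <- 0L
      while (length(confs) < n && tries < max_tries) {
        tries <- tries + 1L
        cand <- base
        for (k in seq_along(rot)) {
          ang <- (sample(c(-120, -60, 60, 120, 180), 1L) +
                    stats::runif(1, -15, 15)) * pi / 180
          cand <- .rotateAboutBond(cand, g$bonds$a[rot[k]],
                                   g$bonds$b[rot[k]], sides[[k]], ang)
        }
        if (minDist(cand) < clash_dist) next
        ok <- all(vapply(confs, function(cc) alignedRmsd(cc, cand),
                         0) >= min_rmsd)
        if (ok) confs[[length(confs) + 1L]] <- cand
      }
    }
  })

  feats <- lapply(confs, function(cc) typeFeatures(g, cc))
  new("ConformerSet", compoundId = id, elements = g$elements,
      radii = g$radii, coords = confs, features = feats,
      seed = as.integer(seed), maxConformers = as.integer(n))
}
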