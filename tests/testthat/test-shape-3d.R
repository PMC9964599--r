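test_that("conformer ensembles are seeded, pruned and deterministic", {
  smi <- "CC(=O)Nc1ccc(OCCN2CCN(C)CC2)cc1"
  c1 <- generateConformers(smi, n = 8, seed = 5)
  c2 <- generateConformers(smi, n = 8, seed = 5)
  expect_identical(c1@coords, c2@coords)   # bitwise determinism
  expect_lte(length(c1), 8L)
  expect_gte(length(c1), 2L)               # flexible molecule
  # pairwise RMSD >= 0.5 after pruning (brute force over all pairs)
  if (length(c1) > 1) {
    for (i in seq_len(length(c1) - 1))
      for (j in (i + 1):length(c1))
        expect_gte(alignedRmsd(conformerCoords(c1, i),
                               conformerCoords(c1, j)), 0.5)
  }
  # a different seed explores different torsions
  c3 <- generateConformers(smi, n = 8, seed = 6)
  expect_false(identical(c1@coords, c3@coords))
  # rigid benzene: one conformer
  expect_equal(length(generateConformers("c1ccccc1", n = 10, seed = 1)), 1L)
})

test_that("analytic Gaussian overlap matches grid integration", {
  # two single atoms: d = 0 versus d = r, both against quadrature
  r <- 1.7
  a <- matrix(0, 1, 3)
  for (d in c(0, r)) {
    b <- matrix(c(d, 0, 0), 1, 3)
    va <- gaussianOverlapVolume(a, r, b, r)
    vg <- gridGaussianOverlap(a, r, b, r, grid = 0.2)
    expect_lt(abs(va - vg) / vg, 0.02, label = sprintf("d=%g", d))
  }
  v0 <- gaussianOverlapVolume(a, r, a, r)
  vr <- gaussianOverlapVolume(a, r, matrix(c(r, 0, 0), 1, 3), r)
  expect_lt(vr, v0)
  # distant atoms barely overlap
  far <- gaussianOverlapVolume(a, r, matrix(c(100, 0, 0), 1, 3), r)
  expect_lt(far, 1e-6)
  # self-overlap is strictly positive and symmetric under swapping
  lib <- smallLibrary()
  cs <- generateConformers(structureKey(lib)[[3]], n = 1, seed = 1)
  xyz <- conformerCoords(cs, 1); rr <- atomRadii(cs)
  expect_gt(gaussianOverlapVolume(xyz, rr, xyz, rr), 0)
  cs2 <- generateConformers(structureKey(lib)[[9]], n = 1, seed = 1)
  expect_equal(gaussianOverlapVolume(xyz, rr, conformerCoords(cs2, 1),
                                     atomRadii(cs2)),
               gaussianOverlapVolume(conformerCoords(cs2, 1),
                                     atomRadii(cs2), xyz, rr))
  # molecule-level quadrature oracle (coarser than the acceptance run)
  vam <- gaussianOverlapVolume(xyz, rr, conformerCoords(cs2, 1),
                               atomRadii(cs2))
  vgm <- gridGaussianOverlap(xyz, rr, conformerCoords(cs2, 1),
                             atomRadii(cs2), grid = 0.25)
  expect_lt(abs(vam - vgm) / vgm, 0.02)
})

test_that("self-overlay of a rotated/translated copy is recovered", {
  lib <- smallLibrary()
  cs <- generateConformers(structureKey(lib)[[5]], n = 1, seed = 3)
  xyz <- conformerCoords(cs, 1); r <- atomRadii(cs)
  tr <- randomRigidTransform(101)
  moved <- sweep(xyz %*% tr$R, 2, tr$t, `+`)
  ov <- optimizeOverlay(xyz, r, moved, r)
  expect_gte(ov$shape_tanimoto, 0.99)
  # transform really maps A onto B
  expect_lt(max(abs(applyTransform(xyz, ov$transform) - moved)), 0.5)
  # single atom self-overlay is exactly 1
  a <- matrix(0, 1, 3)
  expect_equal(optimizeOverlay(a, 1.7, a + 3, 1.7)$shape_tanimoto, 1.0)
  # small fragment versus a large ring system cannot overlay well
  small <- generateConformers("C", n = 1, seed = 1)
  big <- generateConformers("c1ccc2ccc3ccccc3c2c1", n = 1, seed = 1)
  ovb <- optimizeOverlay(conformerCoords(small, 1), atomRadii(small),
                         conformerCoords(big, 1), atomRadii(big))
  expect_lt(ovb$shape_tanimoto, 0.5)
})

test_that("overlay score is invariant to rigid pre-transformation", {
  lib <- smallLibrary()
  csA <- generateConformers(structureKey(lib)[[2]], n = 1, seed = 2)
  csB <- generateConformers(structureKey(lib)[[11]], n = 1, seed = 2)
  A <- conformerCoords(csA, 1); B <- conformerCoords(csB, 1)
  ra <- atomRadii(csA); rb <- atomRadii(csB)
  ref <- optimizeOverlay(A, ra, B, rb)$shape_tanimoto
  for (s in 1:3) {
    tr <- randomRigidTransform(200 + s)
    A2 <- sweep(A %*% tr$R, 2, tr$t, `+`)
    expect_lt(abs(optimizeOverlay(A2, ra, B, rb)$shape_tanimoto - ref),
              1e-6)
  }
})

test_that("color tanimoto: identity, disjoint types, self-recovery", {
  feat <- data.frame(type = c("donor", "acceptor", "aromatic"),
                     x = c(0, 2, 4), y = 0, z = 0)
  expect_equal(colorTanimoto(feat, feat), 1.0)
  donor <- data.frame(type = "donor", x = 0, y = 0, z = 0)
  acceptor <- data.frame(type = "acceptor", x = 0, y = 0, z = 0)
  expect_equal(colorTanimoto(donor, acceptor), 0.0)
  none <- data.frame(type = character(), x = numeric(), y = numeric(),
                     z = numeric())
  expect_equal(colorTanimoto(none, feat), 0.0)

  # phenol versus a rotated copy of itself, at the optimizer's transform
  cs <- generateConformers("Oc1ccccc1", n = 1, seed = 1)
  xyz <- conformerCoords(cs, 1)
  tr <- randomRigidTransform(77)
  moved <- sweep(xyz %*% tr$R, 2, tr$t, `+`)
  fmov <- conformerFeatures(cs, 1)
  fm <- as.matrix(fmov[, c("x", "y", "z")])
  fmov[, c("x", "y", "z")] <- sweep(fm %*% tr$R, 2, tr$t, `+`)
  ov <- optimizeOverlay(xyz, atomRadii(cs), moved, atomRadii(cs))
  expect_gte(colorTanimoto(conformerFeatures(cs, 1), fmov, ov$transform),
             0.95)
})

test_that("ensemble TanimotoCombo: identity, bounds, symmetry, max rule", {
  lib <- smallLibrary()
  keys <- structureKey(lib)
  csA <- generateConformers(keys[[6]], n = 3, seed = 4, id = "A")
  same <- generateConformers(keys[[6]], n = 3, seed = 4, id = "A2")
  tcSelf <- tanimotoCombo(csA, same)
  expect_gte(tcSelf$tanimoto_combo, 1.98)

  csB <- generateConformers(keys[[13]], n = 3, seed = 4, id = "B")
  fwd <- tanimotoCombo(csA, csB)
  rev <- tanimotoCombo(csB, csA)
  expect_equal(fwd$tanimoto_combo, rev$tanimoto_combo, tolerance = 1e-9)
  expect_gte(fwd$shape_tanimoto, 0); expect_lte(fwd$shape_tanimoto, 1)
  expect_gte(fwd$color_tanimoto, 0); expect_lte(fwd$color_tanimoto, 1)
  expect_equal(fwd$tanimoto_combo,
               fwd$shape_tanimoto + fwd$color_tanimoto)

  # reported score equals the brute-force maximum over conformer pairs
  noPre <- tanimotoCombo(csA, csB, prescreen_keep = 9L)
  expect_gte(noPre$tanimoto_combo + 1e-9, fwd$tanimoto_combo)
  best <- -Inf
  for (i in seq_len(length(csA))) for (j in seq_len(length(csB))) {
    one <- tanimotoCombo(
      new("ConformerSet", compoundId = "a", elements = csA@elements,
          radii = csA@radii, coords = csA@coords[i],
          features = csA@features[i], seed = 1L, maxConformers = 1L),
      new("ConformerSet", compoundId = "b", elements = csB@elements,
          radii = csB@radii, coords = csB@coords[j],
          features = csB@features[j], seed = 1L, maxConformers = 1L))
    best <- max(best, one$tanimoto_combo)
  }
  expect_equal(noPre$tanimoto_combo, best, tolerance = 1e-6)
})

test_that("3D cascade filter thresholds at TanimotoCombo 1.5", {
  sc <- data.frame(drug_id = "d", active_id = "a",
                   tanimoto_combo = c(1.6, 1.5, 1.49, 0.2))
  out <- suppressMessages(cascadeFilter3D(sc))
  expect_equal(out$tanimoto_combo, c(1.6, 1.5))
  expect_equal(nrow(suppressMessages(
    cascadeFilter3D(sc[integer(), ]))), 0L)
})
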