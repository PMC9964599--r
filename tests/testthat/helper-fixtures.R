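# Shared fixtures, built once per test run and memoized. All fixture
# content is a deterministic function of the seeds used here.

.fixtureCache <- new.env(parent = emptyenv())

memoFixture <- function(name, builder) {
  if (is.null(.fixtureCache[[name]]))
    .fixtureCache[[name]] <- suppressMessages(suppressWarnings(builder()))
  .fixtureCache[[name]]
}

# small library shared by curation / fingerprint / shape tests
smallLibrary <- function() {
  memoFixture("smallLibrary", function() {
    buildCompoundLibrary(simulationConfig(seed = 7, n_scaffolds = 2,
                                          n_decorations = 8))
  })
}

# small but complete simulation for pipeline-level tests
smallSim <- function() {
  memoFixture("smallSim", function() {
    simulateAll(simulationConfig(seed = 11, n_analog_drugs = 12,
                                 n_distractor_drugs = 12,
                                 n_per_driver = 40))
  })
}

# a clean (dirt-free, duplicate-free) bioactivity table builder
cleanCellTable <- function(compound_ids, values_nm, cell_line = "PC-3",
                           type = "IC50", relation = "=", units = "nM") {
  data.frame(compound_id = compound_ids, activity_scope = "cell",
             scope_id = cell_line, standard_type = type,
             standard_relation = relation, standard_value = values_nm,
             standard_units = units, assay_type = "F", target_type = "",
             target_organism = "Homo Sapiens")
}

cleanTargetTable <- function(compound_ids, values_nm, target_id = "T1",
                             type = "Ki", relation = "=", units = "nM",
                             target_type = "Single protein",
                             organism = "Homo Sapiens", assay = "B") {
  data.frame(compound_id = compound_ids, activity_scope = "target",
             scope_id = target_id, standard_type = type,
             standard_relation = relation, standard_value = values_nm,
             standard_units = units, assay_type = assay,
             target_type = target_type, target_organism = organism)
}

# independent brute-force Tanimoto on explicit bit-index sets
bruteTanimoto <- function(bitsA, bitsB) {
  ni <- length(intersect(bitsA, bitsB))
  nu <- length(union(bitsA, bitsB))
  if (nu == 0) 1 else ni / nu
}

# independent Spearman oracle: explicit average ranks via sorting, then
# the textbook Pearson sum formula on the ranks
bruteSpearman <- function(x, y) {
  avgRank <- function(v) {
    n <- length(v)
    r <- numeric(n)
    for (i in seq_len(n)) r[i] <- sum(v < v[i]) + (1 + sum(v == v[i])) / 2
    r
  }
  rx <- avgRank(x); ry <- avgRank(y)
  n <- length(x)
  num <- sum(rx * ry) - n * mean(rx) * mean(ry)
  den <- sqrt((sum(rx^2) - n * mean(rx)^2) * (sum(ry^2) - n * mean(ry)^2))
  num / den
}

# independent grid integration of the product of two summed Gaussian
# densities (quadrature oracle for the analytic pairwise overlap)
gridGaussianOverlap <- function(xyzA, radiiA, xyzB, radiiB, grid = 0.2,
                                p = 2.7) {
  alphaA <- alphaFromRadius(radiiA, p)
  alphaB <- alphaFromRadius(radiiB, p)
  all <- rbind(xyzA, xyzB)
  lo <- apply(all, 2, min) - 3.5
  hi <- apply(all, 2, max) + 3.5
  xs <- seq(lo[1], hi[1], by = grid)
  ys <- seq(lo[2], hi[2], by = grid)
  zs <- seq(lo[3], hi[3], by = grid)
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  dens <- function(xyz, alpha) {
    d <- numeric(nrow(pts))
    for (i in seq_len(nrow(xyz))) {
      d2 <- (pts[, 1] - xyz[i, 1])^2 + (pts[, 2] - xyz[i, 2])^2 +
        (pts[, 3] - xyz[i, 3])^2
      d <- d + p * exp(-alpha[i] * d2)
    }
    d
  }
  sum(dens(xyzA, alphaA) * dens(xyzB, alphaB)) * grid^3
}

randomRigidTransform <- function(seed) {
  set.seed(seed)
  th <- runif(3, -pi, pi)
  Rx <- matrix(c(1, 0, 0, 0, cos(th[1]), sin(th[1]),
                 0, -sin(th[1]), cos(th[1])), 3, 3)
  Ry <- matrix(c(cos(th[2]), 0, -sin(th[2]), 0, 1, 0,
                 sin(th[2]), 0, cos(th[2])), 3, 3)
  Rz <- matrix(c(cos(th[3]), sin(th[3]), 0, -sin(th[3]), cos(th[3]), 0,
                 0, 0, 1), 3, 3)
  list(R = Rx %*% Ry %*% Rz, t = runif(3, -8, 8))
}
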