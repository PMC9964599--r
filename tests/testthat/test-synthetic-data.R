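test_that("compound library enumeration is deterministic and valid", {
  cfg <- simulationConfig(seed = 7, n_scaffolds = 2, n_decorations = 8)
  lib1 <- smallLibrary()
  lib2 <- suppressMessages(buildCompoundLibrary(cfg))
  expect_identical(structureKey(lib1), structureKey(lib2))
  expect_equal(length(lib1), 16L)   # scaffold x decoration product
  # every emitted structure standardizes and sits in the MW window
  expect_true(all(compoundMw(lib1) >= 180 & compoundMw(lib1) <= 850))
  expect_true(all(nzchar(structureKey(lib1))))
})

test_that("noiseless unit-slope link gives Spearman rho of exactly 1", {
  cfg <- simulationConfig(
    seed = 3, n_scaffolds = 2, n_decorations = 8, n_per_driver = 5,
    driver_targets = data.frame(target_id = "T_DRV1", link_slope = 1,
                                noise_sd_log10 = 0),
    decoy_targets = "T_DEC1", dirty_fraction = 0, duplicate_fraction = 0)
  pl <- suppressMessages(plantBioactivities(smallLibrary(), cfg))
  st <- pl$ground_truth$planted_stats
  drv <- st[grep("T_DRV1", names(st))]
  expect_true(all(vapply(drv, `[[`, 0, "rho") == 1.0))
})

test_that("decoy targets have no compound-level link (empirical null)", {
  lib <- smallLibrary()
  rhos <- c()
  for (seed in 1:60) {
    cfg <- simulationConfig(
      seed = seed, n_scaffolds = 2, n_decorations = 8, n_per_driver = 16,
      n_cell_lines = 1,
      driver_targets = data.frame(target_id = "T_DRV1", link_slope = 1,
                                  noise_sd_log10 = 0.3),
      decoy_targets = "T_DEC1", dirty_fraction = 0,
      duplicate_fraction = 0)
    pl <- suppressMessages(plantBioactivities(lib, cfg))
    st <- pl$ground_truth$planted_stats
    rhos <- c(rhos, vapply(st[grep("T_DEC1", names(st))], `[[`, 0, "rho"))
  }
  expect_lt(mean(abs(rhos)), 0.25)
  expect_lt(abs(mean(rhos)), 0.1)
})

test_that("dirty-row injection violates exactly the filter clauses", {
  cfg <- simulationConfig(seed = 5, n_scaffolds = 2, n_decorations = 8,
                          n_per_driver = 10, dirty_fraction = 0,
                          duplicate_fraction = 0)
  pl <- suppressMessages(plantBioactivities(smallLibrary(), cfg))
  cell <- pl$cell_records[!pl$cell_records$dirty, ]
  dirty <- injectDirtyRows(cell, 0.5, seed = 9)
  flagged <- which(dirty$dirty)
  expect_gt(length(flagged), 0)
  kept <- suppressMessages(filterCellBioactivities(
    dirty[names(dirty) != "dirty"]))
  # every clean row survives, every corrupted row is removed
  expect_equal(nrow(kept), nrow(dirty) - length(flagged))
  expect_false(any(rownames(kept) %in% rownames(dirty)[flagged]))
  # zero fraction is a no-op
  same <- injectDirtyRows(cell, 0, seed = 9)
  expect_false(any(same$dirty))
})

test_that("analog drugs carry the planted 2D signal; bookkeeping holds", {
  sim <- smallSim()
  gt <- sim$ground_truth
  # analog_map keys all exist in the drug fixture
  expect_true(all(names(gt$analog_map) %in% compoundIds(sim$drugs)))
  expect_true(all(gt$analog_map %in% compoundIds(sim$library)))
  expect_true(all(gt$distractor_ids %in% compoundIds(sim$drugs)))
  # driver/decoy sets disjoint
  expect_length(intersect(gt$driver_set, gt$decoy_set), 0)
  # recorded self-verified analog similarity meets the contract
  expect_true(all(gt$analog_tc[, "maccs"] >= 0.8))
  expect_true(all(gt$analog_tc[, "ecfp4"] >= 0.3))
})

test_that("fixtures are deterministic and round-trip through disk", {
  cfg <- simulationConfig(seed = 19, n_scaffolds = 2, n_decorations = 8,
                          n_per_driver = 10, n_analog_drugs = 5,
                          n_distractor_drugs = 5)
  sim1 <- suppressMessages(suppressWarnings(simulateAll(cfg)))
  sim2 <- suppressMessages(suppressWarnings(simulateAll(cfg)))
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  writeFixtures(sim1, d1); writeFixtures(sim2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", 1e7),
                     readBin(file.path(d2, f), "raw", 1e7), info = f)
  }
  # round trip: records equal field for field
  back <- suppressMessages(readFixtures(d1))
  orig <- rbind(sim1$cell_records, sim1$target_records)
  rownames(orig) <- NULL
  expect_equal(back$bioactivities$compound_id, orig$compound_id)
  expect_equal(back$bioactivities$standard_value, orig$standard_value,
               tolerance = 1e-12)
  expect_identical(structureKey(back$drugs), structureKey(sim1$drugs))
  # SDF re-parse count matches the SMILES count
  sdf <- ChemmineR::read.SDFset(file.path(d1, "drugs.sdf"))
  expect_equal(length(sdf), length(sim1$drugs))
  # manifest records the master seed
  man <- jsonlite::read_json(file.path(d1, "manifest.json"),
                             simplifyVector = TRUE)
  expect_equal(man$seed, 19)
})
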