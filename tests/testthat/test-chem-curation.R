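test_that("standardization strips salts, canonicalizes and is idempotent", {
  rec <- standardizeStructure("CC(=O)[O-].[Na+]")
  expect_false(grepl("Na", rec$structure_key))
  expect_false(grepl(".", rec$structure_key, fixed = TRUE))
  # largest covalent fragment is kept
  rec2 <- standardizeStructure("CCCCCCCC.C")
  expect_equal(rec2$structure_key, standardizeStructure("CCCCCCCC")$structure_key)
  # idempotent: standardizing a key returns the key
  expect_equal(standardizeStructure(rec$structure_key)$structure_key,
               rec$structure_key)
  # stable across runs
  expect_equal(standardizeStructure("CC(=O)[O-].[Na+]")$structure_key,
               rec$structure_key)
})

test_that("structure keys are invariant to the input atom ordering", {
  pairs <- list(c("c1ccccc1", "C1=CC=CC=C1"),
                c("CCO", "OCC"),
                c("CC(=O)Nc1ccccc1", "c1ccccc1NC(C)=O"),
                c("CCN(CC)CC", "N(CC)(CC)CC"),
                c("Oc1ccc(Cl)cc1", "Clc1ccc(O)cc1"))
  for (p in pairs)
    expect_equal(standardizeStructure(p[1])$structure_key,
                 standardizeStructure(p[2])$structure_key, info = p[1])
})

test_that("malformed and hypervalent structures raise parseError", {
  expect_error(standardizeStructure("C1CC"), class = "parseError")
  expect_error(standardizeStructure(""), class = "parseError")
  expect_error(standardizeStructure("CC(C)(C)(C)C"), class = "parseError")
  expect_error(standardizeStructure("not a smiles"), class = "parseError")
})

test_that("cell bioactivity filter applies all three clauses", {
  base <- cleanCellTable(paste0("c", 1:6), rep(500, 6))
  base$standard_type[2] <- "Ki"           # wrong type
  base$standard_relation[3] <- "~"        # forbidden relation
  base$standard_units[4] <- "uM"          # micromolar
  base$standard_units[5] <- "nm"          # wrong spelling, rejected
  base$standard_relation[6] <- "<"        # "<" is allowed
  out <- suppressMessages(filterCellBioactivities(base))
  expect_equal(out$compound_id, c("c1", "c6"))
  # subset property: no record invented, no field mutated
  expect_true(all(apply(out, 1, paste, collapse = "\r") %in%
                    apply(base, 1, paste, collapse = "\r")))
})

test_that("target bioactivity filter applies all six clauses", {
  base <- cleanTargetTable(paste0("c", 1:7), rep(50, 7))
  base$standard_type[2] <- "GI50"
  base$standard_relation[3] <- "<"
  base$standard_units[4] <- "uM"
  base$target_type[5] <- "Protein complex"
  base$target_organism[6] <- "Rattus norvegicus"
  base$assay_type[7] <- "F"
  out <- suppressMessages(filterTargetBioactivities(base))
  expect_equal(out$compound_id, "c1")
})

test_that("dedupBest keeps the minimum value per group", {
  tab <- cleanCellTable(c("c1", "c1", "c1", "c2"), c(100, 50, 75, 30))
  tab$standard_type[2] <- "GI50"
  tab$scope_id[4] <- "DU-145"
  out <- suppressMessages(dedupBest(tab))
  expect_equal(nrow(out), 2L)
  expect_equal(out$standard_value[out$compound_id == "c1"], 50)
  # brute-force check on a random table
  set.seed(3)
  big <- cleanCellTable(sample(paste0("c", 1:8), 60, replace = TRUE),
                        round(runif(60, 1, 1e4)),
                        cell_line = sample(c("PC-3", "LNCaP"), 60,
                                           replace = TRUE))
  dd <- suppressMessages(dedupBest(big))
  grp <- paste(big$compound_id, big$scope_id)
  expect_equal(nrow(dd), length(unique(grp)))
  for (g in unique(grp)) {
    expect_equal(dd$standard_value[paste(dd$compound_id, dd$scope_id) == g],
                 min(big$standard_value[grp == g]))
  }
  # a single record passes through unchanged
  one <- cleanCellTable("c9", 10)
  expect_equal(suppressMessages(dedupBest(one)), one)
})

test_that("active selection honours relation semantics and the MW window", {
  lib <- smallLibrary()
  ids <- compoundIds(lib)[1:4]
  tab <- cleanCellTable(ids, c(500, 500, 1500, 1000))
  tab$standard_relation[2] <- ">"   # lower bound cannot certify potency
  sel <- suppressMessages(selectActives(tab, lib))
  expect_true(ids[1] %in% sel)
  expect_false(ids[2] %in% sel)   # ">" record
  expect_false(ids[3] %in% sel)   # above cutoff
  expect_true(ids[4] %in% sel)    # boundary inclusive (<= 1000 nM)

  # "<" certifies
  tab2 <- cleanCellTable(ids[1], 800)
  tab2$standard_relation <- "<"
  expect_equal(suppressMessages(selectActives(tab2, lib)), ids[1])

  # MW window: a compound below 180 Da is rejected even when potent
  tiny <- suppressMessages(
    standardizeCompounds(c("CCO"), "tiny", source = "cell_active_set"))
  expect_length(suppressMessages(
    selectActives(cleanCellTable("tiny", 10), tiny)), 0)

  # monotonicity: raising the cutoff never shrinks the selection
  set.seed(5)
  vals <- round(10^runif(length(compoundIds(lib)), 1, 5))
  tab3 <- cleanCellTable(compoundIds(lib), vals)
  cuts <- c(100, 1000, 10000, 1e5)
  sels <- lapply(cuts, function(ct) suppressMessages(
    selectActives(tab3, lib, potency_cutoff_nm = ct)))
  for (k in seq_len(length(cuts) - 1))
    expect_true(all(sels[[k]] %in% sels[[k + 1]]))

  # unresolvable compound id
  expect_error(suppressMessages(
    selectActives(cleanCellTable("ghost", 5), lib)),
    class = "keyMissingError")
})

test_that("overlap removal uses structural identity, not raw SMILES", {
  actives <- suppressMessages(standardizeCompounds(
    c("Oc1ccccc1"), "a1", source = "cell_active_set"))
  drugs <- suppressMessages(standardizeCompounds(
    c("c1ccccc1O", "Cc1ccccc1O"), c("d1", "d2"), source = "drug_set"))
  out <- suppressMessages(removeOverlap(drugs, actives))
  expect_equal(compoundIds(out), "d2")  # d1 identical as a structure
  # empty active set: identity
  none <- suppressMessages(standardizeCompounds(character(),
                                                character(),
                                                source = "cell_active_set"))
  expect_equal(compoundIds(suppressMessages(removeOverlap(drugs, none))),
               c("d1", "d2"))
})

test_that("descriptor panel: sphere limits, donor/acceptor counts", {
  # single atom: grid volume within 2% of the closed form, ovality ~ 1
  cs <- generateConformers("[Ne]", n = 1, seed = 1)
  r <- atomRadii(cs)
  vol <- gridVolume(conformerCoords(cs, 1), r, grid = 0.2)
  expect_lt(abs(vol - 4 / 3 * pi * r^3) / (4 / 3 * pi * r^3), 0.02)
  d <- computeDescriptors("[Ne]")
  expect_lt(abs(d$ovality - 1), 0.05)
  expect_equal(computeDescriptors("[Ne]", ovality = "reciprocal")$ovality,
               1 / d$ovality)

  # water-like molecule: one donor heavy atom, at least one acceptor
  dw <- computeDescriptors("O")
  expect_equal(dw$hbd, 1)
  expect_gte(dw$hba, 1)

  # full panel present and sane on a drug-like structure
  dd <- computeDescriptors("CC(=O)Nc1ccc(O)cc1")
  expect_true(all(c("logp", "psa", "hbd", "hba", "mw", "volume",
                    "ovality") %in% names(dd)))
  expect_gt(dd$mw, 150); expect_gt(dd$volume, 50); expect_gt(dd$ovality, 1)
})
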