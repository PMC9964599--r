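test_that("activity classification partitions the potency axis", {
  expect_equal(classifyActivity(500), "highly_active")
  expect_equal(classifyActivity(5000), "scarcely_active")
  expect_equal(classifyActivity(20000), "inactive")
  # boundaries: 1000 nM is highly active, 10000 nM is inactive
  expect_equal(classifyActivity(1000), "highly_active")
  expect_equal(classifyActivity(10000), "inactive")
  expect_equal(classifyActivity(1000.0001), "scarcely_active")
  # exactly one label per value, monotone in potency
  set.seed(8)
  v <- sort(10^runif(200, 0, 5.5))
  lab <- classifyActivity(v)
  expect_true(all(lab %in% c("highly_active", "scarcely_active",
                             "inactive")))
  ordLevel <- match(lab, c("highly_active", "scarcely_active", "inactive"))
  expect_true(all(diff(ordLevel) >= 0))
  expect_error(classifyActivity(-5), class = "domainError")
  expect_error(classifyActivity(0), class = "domainError")
})

test_that("candidate annotation sets flags from evidence", {
  hits <- data.frame(drug_id = c("d1", "d1", "d2", "d3"),
                     active_id = c("a1", "a2", "a1", "a3"),
                     tc_maccs = 0.9, tc_ecfp4 = 0.5,
                     tanimoto_combo = c(1.7, 1.9, 1.6, 1.55))
  meta <- data.frame(drug_id = c("d1", "d2"), name = c("one", "two"),
                     max_phase = c(3L, 1L), invivo_pc = c(TRUE, FALSE))
  bio <- rbind(
    cleanCellTable("d1", 104, cell_line = "LNCaP"),
    cleanTargetTable("d2", 50, target_id = "Tcorr"),
    cleanTargetTable("d3", 20000, target_id = "Tcorr"))
  clin <- data.frame(drug_id = "d2", trial_id = "NCT000001",
                     disease = "prostate cancer", phase = 2L)

  expect_warning(
    rep <- annotateCandidates(hits, meta, bio,
                              correlated_targets = "Tcorr",
                              clinical_table = clin),
    "no metadata")
  expect_equal(nrow(rep), 3L)
  r1 <- rep[rep$drug_id == "d1", ]
  expect_true(r1$in_vitro_pc); expect_true(r1$in_vivo_pc)
  expect_false(r1$pc_trial); expect_false(r1$pc_target)
  expect_equal(r1$best_active_id, "a2")   # highest combo
  expect_equal(r1$best_tanimoto_combo, 1.9)
  r2 <- rep[rep$drug_id == "d2", ]
  expect_true(r2$pc_trial); expect_true(r2$pc_target)
  expect_false(r2$in_vitro_pc)
  # inactive record on a correlated target does not set the flag
  r3 <- rep[rep$drug_id == "d3", ]
  expect_false(r3$pc_target)
  expect_equal(r3$target_annotations[[1]]$class, "inactive")
  expect_true(is.na(r3$name))
  # every flagged criterion is backed by evidence rows
  expect_equal(r2$target_annotations[[1]]$target_id, "Tcorr")
})

test_that("ranking is the documented deterministic total order", {
  rep <- data.frame(
    drug_id = c("dB", "dA", "dC", "dD"),
    name = "x", max_phase = c(1L, 1L, 4L, 2L),
    best_active_id = "a", best_tc_maccs = 0.9, best_tc_ecfp4 = 0.5,
    best_tanimoto_combo = c(1.6, 1.6, 1.8, 1.9),
    in_vitro_pc = c(TRUE, TRUE, TRUE, FALSE),
    in_vivo_pc = c(TRUE, TRUE, FALSE, FALSE),
    pc_trial = c(TRUE, TRUE, FALSE, FALSE),
    pc_target = FALSE)
  rep$target_annotations <- I(replicate(4, data.frame(), simplify = FALSE))
  rk <- rankCandidates(rep)
  # three flags beat one flag; ties break by combo, then phase, then id
  expect_equal(rk$drug_id, c("dA", "dB", "dC", "dD"))
  expect_equal(rk$rank, 1:4)
  # single report gets rank 1
  expect_equal(rankCandidates(rep[1, ])$rank, 1L)
})

test_that("report files are byte-identical across reruns", {
  sim <- smallSim()
  hits <- data.frame(drug_id = compoundIds(sim$drugs)[1:2],
                     active_id = compoundIds(sim$library)[1:2],
                     tc_maccs = c(0.9, 0.85), tc_ecfp4 = c(0.4, 0.5),
                     tanimoto_combo = c(1.8, 1.6))
  rep <- rankCandidates(suppressWarnings(annotateCandidates(
    hits, sim$drug_meta, sim$drug_bioactivities,
    sim$ground_truth$driver_set, sim$clinical_table)))
  d1 <- withr::local_tempdir()
  p1 <- writeCandidateReport(rep, file.path(d1, "r1"))
  p2 <- writeCandidateReport(rep, file.path(d1, "r2"))
  expect_identical(readBin(p1[["tsv"]], "raw", 1e6),
                   readBin(p2[["tsv"]], "raw", 1e6))
  expect_identical(readBin(p1[["json"]], "raw", 1e6),
                   readBin(p2[["json"]], "raw", 1e6))
  # JSON parses and round-trips key fields
  js <- jsonlite::read_json(p1[["json"]], simplifyVector = TRUE)
  expect_equal(nrow(js), nrow(rep))
  expect_equal(js$drug_id, rep$drug_id)
})
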