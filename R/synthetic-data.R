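#' @title Synthetic fixtures with planted ground truth
#'
#' @description Generates ChEMBL-like bioactivity tables and a
#' DrugBank-like drug library entirely from an embedded scaffold grammar,
#' with known ground truth: a compound library spanning drug-like property
#' ranges, per-cell-line antiproliferative potencies monotonically linked
#' to planted driver targets (and permuted decoy targets), near-analog
#' "drugs" derived from active compounds by single structural edits, and
#' structurally unrelated distractor drugs. Every quantity is a
#' deterministic function of the master seed.
#'
#' @name synthetic_data
NULL

# Active-library grammar: four heteroaromatic/amide cores, each with one
# substitution site, crossed with decorations (halogen / alkyl / amine /
# ether / aryl). Decorations use ring-closure digit 8 to avoid clashing
# with the cores' digits.
.CORES <- c(
  benzimidazole = "c1ccc2[nH]c(%s)nc2c1",
  quinazoline   = "c1ccc2c(c1)ncnc2N%s",
  chromone      = "O=c1cc(%s)oc2ccccc12",
  piperazinamide = "O=C(%s)N1CCN(C)CC1"
)

.DECORATIONS <- c(
  "CCCCC", "CCCCCC", "CCN(C)C", "CCCN(C)C", "CCCN8CCC(c9ccccc9)CC8",
  "CCOCC", "CCCOC", "CCOCCO", "c8ccccc8", "Cc8ccccc8", "c8ccc(F)cc8",
  "c8ccc(Cl)cc8", "c8ccc(C)cc8", "c8ccc(OC)cc8", "c8ccc(N(C)C)cc8",
  "CCc8ccccc8", "C8CCCCC8", "CC8CCCCC8", "CCN8CCCC8", "CCN8CCOCC8",
  "CCN8CCN(C)CC8", "CCCCF", "CCCCCl", "CCN8CCN(Cc9ccccc9)CC8",
  "CN8CCC(Oc9ccc(F)cc9)CC8", "c8ccc(S(=O)(=O)N(C)C)cc8", "c8ccncc8",
  "c8ccc(C(=O)N9CCOCC9)cc8", "CCOc8ccccc8", "CCOc8ccc(CN9CCOCC9)cc8"
)

# Distractor grammar: an unrelated aliphatic/glycoside/sulfonamide family.
.DISTRACTOR_CORES <- c(
  "OCC1OC(OC%s)C(O)C(O)C1O",
  "O=S(=O)(NC1CCCCC1)C%s",
  "O=C(OCC%s)C1CCC(N2CCOCC2)CC1",
  "OC1(CCNCC1)CC%s",
  "O=C(NCC%s)C1CCC(O)CC1"
)

.CELL_LINE_NAMES <- c("PC-3", "DU-145", "LNCaP", "22Rv-1", "VCaP")

#' Simulation configuration with study defaults
#'
#' @param seed master seed; all fixture content derives from it.
#' @param n_scaffolds,n_decorations library grammar size (product =
#'   library size).
#' @param n_cell_lines number of prostate cancer cell lines (max 5).
#' @param driver_targets data.frame(target_id, link_slope, noise_sd_log10)
#'   for the planted driver targets.
#' @param decoy_targets ids of permuted decoy targets (paired 1:1 with
#'   drivers).
#' @param n_per_driver compounds annotated per driver target.
#' @param n_analog_drugs,n_distractor_drugs drug-library composition.
#' @param analog_edit_ops edit operations used to derive analogs.
#' @param dirty_fraction fraction of bioactivity rows corrupted with a
#'   filter-violating field.
#' @param duplicate_fraction fraction of cell rows duplicated with a worse
#'   value (exercises best-value deduplication).
#' @param drug_evidence_fraction fraction of analog drugs given their own
#'   cell/target records, trial rows and in-vivo flags.
#' @return a `simulationConfig` list.
#' @export
simulationConfig <- function(seed = 42L, n_scaffolds = 4L,
                             n_decorations = 30L, n_cell_lines = 3L,
                             driver_targets = data.frame(
                               target_id = c("T_DRV1", "T_DRV2", "T_DRV3"),
                               link_slope = 1,
                               noise_sd_log10 = 0.3),
                             decoy_targets = c("T_DEC1", "T_DEC2",
                                               "T_DEC3"),
                             n_per_driver = 40L,
                             n_analog_drugs = 200L,
                             n_distractor_drugs = 200L,
                             analog_edit_ops = c("add_methyl",
                                                 "halogen_swap",
                                                 "ring_saturation"),
                             dirty_fraction = 0.2,
                             duplicate_fraction = 0.1,
                             drug_evidence_fraction = 0.4) {
  stopifnot(n_scaffolds <= length(.CORES),
            n_decorations <= length(.DECORATIONS),
            n_cell_lines <= length(.CELL_LINE_NAMES),
            all(driver_targets$noise_sd_log10 >= 0),
            length(decoy_targets) <= nrow(driver_targets))
  structure(list(seed = as.integer(seed), n_scaffolds = n_scaffolds,
                 n_decorations = n_decorations,
                 n_cell_lines = n_cell_lines,
                 driver_targets = driver_targets,
                 decoy_targets = decoy_targets,
                 n_per_driver = as.integer(n_per_driver),
                 n_analog_drugs = as.integer(n_analog_drugs),
                 n_distractor_drugs = as.integer(n_distractor_drugs),
                 analog_edit_ops = analog_edit_ops,
                 dirty_fraction = dirty_fraction,
                 duplicate_fraction = duplicate_fraction,
                 drug_evidence_fraction = drug_evidence_fraction),
            class = "simulationConfig")
}

#' Build the synthetic compound library
#'
#' Enumerates scaffold x decoration SMILES in deterministic order,
#' standardizes every structure and verifies the 180-850 Da window.
#'
#' @param config a [simulationConfig()].
#' @return a [CompoundSet-class] with a `grammar` attribute
#'   (data.frame id, core, decoration).
#' @export
buildCompoundLibrary <- function(config) {
  cores <- .CORES[seq_len(config$n_scaffolds)]
  decs <- .DECORATIONS[seq_len(config$n_decorations)]
  grid <- expand.grid(dec = seq_along(decs), core = seq_along(cores),
                      KEEP.OUT.ATTRS = FALSE)
  smiles <- sprintf(cores[grid$core], decs[grid$dec])
  ids <- sprintf("CPD%04d", seq_along(smiles))
  set <- standardizeCompounds(smiles, ids, source = "cell_active_set")
  mw <- compoundMw(set)
  if (any(mw < 180 | mw > 850))
    stop("library grammar produced structures outside the 180-850 Da window")
  attr(set, "grammar") <- data.frame(
    id = ids, core = names(cores)[grid$core], core_idx = grid$core,
    dec = decs[grid$dec], dec_idx = grid$dec)
  set
}

#' @keywords internal
.sampleTypes <- function(n, types) types[sample.int(length(types), n,
                                                    replace = TRUE)]

#' Plant per-target and per-cell bioactivities with known structure
#'
#' Each compound belongs to one driver target's chemical series
#' (round-robin assignment) and gets a latent log10 potency ~ U[1.5, 4.5]
#' on its own driver and a weak latent potency (U[4.8, 6.0]) on the
#' others. Cell potency per line is the minimum over drivers of
#' `link_slope * latent` plus Normal(0, noise_sd_log10) noise - the
#' best-target-drives-phenotype rule; with the series design that minimum
#' is always the compound's own driver, giving each driver a clean
#' monotone compound-level link. Decoy targets receive a seeded
#' permutation of their paired driver's values, destroying the pairing
#' while preserving the value distribution. Duplicate (worse-value) rows
#' and filter-violating dirty rows are then injected at the configured
#' fractions. The planted signal is self-verified on the clean records
#' and recorded in the ground truth.
#'
#' @param compounds library [CompoundSet-class] from
#'   [buildCompoundLibrary()].
#' @param config a [simulationConfig()].
#' @return list(cell_records, target_records, ground_truth).
#' @export
plantBioactivities <- function(compounds, config) {
  ids <- compoundIds(compounds)
  n <- length(ids)
  drv <- config$driver_targets
  nd <- nrow(drv)
  lines <- .CELL_LINE_NAMES[seq_len(config$n_cell_lines)]

  assign <- rep(seq_len(nd), length.out = n)  # round-robin series
  .withSeed(config$seed, {
    uOwn <- stats::runif(n, 1.5, 4.5)
    uOther <- matrix(stats::runif(n * nd, 4.8, 6.0), n, nd)
    for (i in seq_len(n)) uOther[i, assign[i]] <- uOwn[i]

    # --- target records (each driver annotates its own series) ---------
    trec <- list()
    for (t in seq_len(nd)) {
      members <- which(assign == t)[seq_len(min(config$n_per_driver,
                                                sum(assign == t)))]
      trec[[t]] <- data.frame(
        compound_id = ids[members], activity_scope = "target",
        scope_id = drv$target_id[t],
        standard_type = .sampleTypes(length(members), .TARGET_TYPES),
        standard_relation = "=",
        standard_value = 10^uOwn[members],
        standard_units = "nM", assay_type = "B",
        target_type = "Single protein", target_organism = "Homo Sapiens")
    }
    # decoys: permuted copies of the paired driver's values
    for (j in seq_along(config$decoy_targets)) {
      src <- trec[[j]]
      perm <- src
      perm$scope_id <- config$decoy_targets[j]
      perm$standard_value <- src$standard_value[
        sample.int(nrow(src))]
      trec[[nd + j]] <- perm
    }
    target_records <- do.call(rbind, trec)

    # --- cell records ---------------------------------------------------
    crec <- list()
    for (li in seq_along(lines)) {
      logcell <- vapply(seq_len(n), function(i) {
        m <- min(drv$link_slope * uOther[i, ])
        m + stats::rnorm(1, 0, drv$noise_sd_log10[assign[i]])
      }, 0)
      crec[[li]] <- data.frame(
        compound_id = ids, activity_scope = "cell", scope_id = lines[li],
        standard_type = .sampleTypes(n, .CELL_TYPES),
        standard_relation = "=", standard_value = 10^logcell,
        standard_units = "nM", assay_type = "F", target_type = "",
        target_organism = "Homo Sapiens")
    }
    cell_records <- do.call(rbind, crec)

    # duplicates with strictly worse values (dedup must discard them)
    if (config$duplicate_fraction > 0) {
      dup <- which(stats::runif(nrow(cell_records)) <
                     config$duplicate_fraction)
      if (length(dup)) {
        extra <- cell_records[dup, , drop = FALSE]
        extra$standard_value <- extra$standard_value *
          10^stats::runif(length(dup), 0.2, 1)
        cell_records <- rbind(cell_records, extra)
      }
    }

    # self-verify the planted statistical structure on clean records
    dedupCell <- dedupBest(cell_records)
    stats <- list()
    for (t in seq_len(nd)) {
      tr <- target_records[target_records$scope_id == drv$target_id[t], ]
      for (cl in lines) {
        pv <- buildPairs(tr, dedupCell, cl)
        s <- spearmanRho(pv$pairs$target_value_nm, pv$pairs$cell_value_nm)
        stats[[paste(drv$target_id[t], cl, sep = "|")]] <-
          list(rho = s$rho, n = s$n)
      }
    }
    for (j in seq_along(config$decoy_targets)) {
      tr <- target_records[
        target_records$scope_id == config$decoy_targets[j], ]
      for (cl in lines) {
        pv <- buildPairs(tr, dedupCell, cl)
        s <- spearmanRho(pv$pairs$target_value_nm, pv$pairs$cell_value_nm)
        stats[[paste(config$decoy_targets[j], cl, sep = "|")]] <-
          list(rho = s$rho, n = s$n)
      }
    }

    # dirty-row injection (after self-verification: the contract is about
    # the clean signal; the filters must remove the dirt)
    cell_records <- injectDirtyRows(cell_records,
                                    config$dirty_fraction,
                                    seed = config$seed + 1L)
    target_records <- injectDirtyRows(target_records,
                                      config$dirty_fraction,
                                      seed = config$seed + 2L)

    rownames(cell_records) <- rownames(target_records) <- NULL
    list(cell_records = cell_records, target_records = target_records,
         ground_truth = list(
           driver_set = drv$target_id,
           decoy_set = config$decoy_targets,
           series = data.frame(compound_id = ids,
                               driver = drv$target_id[assign]),
           latent_log10 = data.frame(compound_id = ids, u = uOwn),
           planted_stats = stats))
  })
}

#' Corrupt a fraction of bioactivity rows with filter-violating fields
#'
#' Each row is independently corrupted with probability `fraction`; a
#' corrupted row gets exactly one randomly chosen clause violation
#' appropriate to its scope (wrong standard type, forbidden relation,
#' micromolar units, wrong target type / organism / assay code). A
#' `dirty` logical column records which rows were touched.
#'
#' @param records bioactivity data.frame.
#' @param fraction corruption probability per row.
#' @param seed integer seed.
#' @return the table with corrupted rows and a `dirty` column.
#' @export
injectDirtyRows <- function(records, fraction, seed = 1L) {
  if (!nrow(records) || fraction <= 0) {
    records$dirty <- rep(FALSE, nrow(records))
    return(records)
  }
  .withSeed(seed, {
    hit <- stats::runif(nrow(records)) < fraction
    for (i in which(hit)) {
      scope <- records$activity_scope[i]
      mode <- if (scope == "cell") sample(3L, 1L) else sample(6L, 1L)
      if (scope == "cell") {
        if (mode == 1L) records$standard_type[i] <- "Ki"
        else if (mode == 2L) records$standard_relation[i] <- "~"
        else records$standard_units[i] <- "uM"
      } else {
        if (mode == 1L) records$standard_type[i] <- "GI50"
        else if (mode == 2L)
          records$standard_relation[i] <- sample(c("<", ">"), 1L)
        else if (mode == 3L) records$standard_units[i] <- "uM"
        else if (mode == 4L) records$target_type[i] <- "Protein complex"
        else if (mode == 5L)
          records$target_organism[i] <- "Rattus norvegicus"
        else records$assay_type[i] <- "F"
      }
    }
    records$dirty <- hit
    records
  })
}

# --- drug fixture ----------------------------------------------------------

#' @keywords internal
.applyEdit <- function(op, dec) {
  switch(op,
    add_methyl = paste0("C", dec),
    halogen_swap = {
      if (grepl("F", dec, fixed = TRUE)) sub("F", "Cl", dec, fixed = TRUE)
      else if (grepl("Cl", dec, fixed = TRUE))
        sub("Cl", "F", dec, fixed = TRUE)
      else if (grepl("Br", dec, fixed = TRUE))
        sub("Br", "Cl", dec, fixed = TRUE)
      else NA_character_
    },
    ring_saturation = {
      if (grepl("[cn]", dec)) chartr("cn", "CN", dec) else NA_character_
    },
    NA_character_)
}

#' Build the DrugBank-like drug fixture
#'
#' Analog drugs are seeded single-edit modifications of sampled sub-uM
#' active compounds (add-methyl, halogen swap or ring saturation applied
#' to the decoration of the compound's grammar entry); edits that fail to
#' parse, or that collide with an existing library structure, fall back to
#' the next operation. Distractor drugs come from a disjoint aliphatic
#' scaffold family. Metadata assigns clinical phases; a seeded subset of
#' analog drugs receives trial rows, in-vivo flags and its own cell/target
#' bioactivity records so every integration flag has planted evidence.
#'
#' @param compounds library [CompoundSet-class] (with its grammar
#'   attribute).
#' @param active_ids character, the selected active compound ids analogs
#'   are derived from.
#' @param config a [simulationConfig()].
#' @param ground_truth the ground-truth list from [plantBioactivities()]
#'   (used to plant drug target evidence); optional.
#' @return list(drugs [CompoundSet], drug_meta, clinical_table,
#'   drug_bioactivities, ground_truth additions: analog_map,
#'   distractor_ids).
#' @export
makeDrugFixture <- function(compounds, active_ids, config,
                            ground_truth = NULL) {
  grammar <- attr(compounds, "grammar")
  stopifnot(!is.null(grammar), length(active_ids) > 0)
  libKeys <- structureKey(compounds)
  cores <- .CORES[seq_len(config$n_scaffolds)]

  srcFps <- list(
    MACCS = fingerprints(compounds[active_ids], "MACCS"),
    ECFP4 = fingerprints(compounds[active_ids], "ECFP4"))

  .withSeed(config$seed + 10L, {
    analogSmiles <- character(0)
    analogSource <- character(0)
    analogOp <- character(0)
    analogTc <- list()
    nTry <- 0L
    while (length(analogSmiles) < config$n_analog_drugs &&
           nTry < 20L * config$n_analog_drugs) {
      nTry <- nTry + 1L
      src <- active_ids[sample.int(length(active_ids), 1L)]
      ge <- grammar[grammar$id == src, ]
      ops <- config$analog_edit_ops[
        sample.int(length(config$analog_edit_ops))]
      placed <- FALSE
      for (op in ops) {
        nd <- .applyEdit(op, ge$dec)
        if (is.na(nd)) next
        smi <- sprintf(cores[[ge$core_idx]], nd)
        rec <- tryCatch(standardizeStructure(smi),
                        SimCascadeError = function(e) NULL)
        if (is.null(rec)) next
        if (rec$structure_key %in% libKeys) next  # would vanish in overlap
        # self-verify the planted 2D signal: an edit that strays from its
        # source is not a near-analog and is rejected in favor of the
        # next operation
        fpM <- fingerprints(stats::setNames(rec$structure_key, "a"),
                            "MACCS")
        fpE <- fingerprints(stats::setNames(rec$structure_key, "a"),
                            "ECFP4")
        tcM <- tanimoto(fingerprintAt(fpM, "a"),
                        fingerprintAt(srcFps$MACCS, src))
        tcE <- tanimoto(fingerprintAt(fpE, "a"),
                        fingerprintAt(srcFps$ECFP4, src))
        if (tcM < 0.8 || tcE < 0.3) next
        analogSmiles <- c(analogSmiles, smi)
        analogSource <- c(analogSource, src)
        analogOp <- c(analogOp, op)
        analogTc[[length(analogTc) + 1L]] <- c(maccs = tcM, ecfp4 = tcE)
        placed <- TRUE
        break
      }
      if (!placed) warning(sprintf(
        "no near-analog edit applicable for active '%s'; skipped", src),
        call. = FALSE)
    }

    # distractors: deterministic enumeration of the disjoint grammar
    chains <- c("C", "CC", "CCC", "CCCC", "CCCCC")
    tails <- c("", "O", "N", "OC", "NC", "OCC", "NCC", "(C)C")
    ddecs <- as.vector(outer(chains, tails, paste0))
    dgrid <- expand.grid(dec = seq_along(ddecs),
                         core = seq_along(.DISTRACTOR_CORES),
                         KEEP.OUT.ATTRS = FALSE)
    dsmiles <- sprintf(.DISTRACTOR_CORES[dgrid$core], ddecs[dgrid$dec])
    dsmiles <- dsmiles[seq_len(min(config$n_distractor_drugs,
                                   length(dsmiles)))]

    allSmiles <- c(analogSmiles, dsmiles)
    ids <- sprintf("DB_SYN%04d", seq_along(allSmiles))
    drugs <- standardizeCompounds(allSmiles, ids, source = "drug_set",
                                  onError = "drop")
    isAnalog <- seq_along(allSmiles) <= length(analogSmiles)
    analogIds <- ids[isAnalog & ids %in% compoundIds(drugs)]
    distractorIds <- ids[!isAnalog & ids %in% compoundIds(drugs)]

    drug_meta <- data.frame(
      drug_id = compoundIds(drugs),
      name = paste0("synthetic-", tolower(compoundIds(drugs))),
      max_phase = sample(1:4, length(drugs), replace = TRUE),
      invivo_pc = FALSE)

    # evidence planting for a seeded subset of analog drugs
    evid <- analogIds[stats::runif(length(analogIds)) <
                        config$drug_evidence_fraction]
    drug_meta$invivo_pc[drug_meta$drug_id %in% evid] <-
      stats::runif(sum(drug_meta$drug_id %in% evid)) < 0.5

    clinical <- if (length(evid)) data.frame(
      drug_id = evid,
      trial_id = sprintf("NCT%06d", seq_along(evid)),
      disease = sample(c("prostate cancer", "solid tumor",
                         "breast cancer", "melanoma"),
                       length(evid), replace = TRUE),
      phase = sample(1:3, length(evid), replace = TRUE))
    else data.frame(drug_id = character(), trial_id = character(),
                    disease = character(), phase = integer())

    drugBio <- list()
    lines <- .CELL_LINE_NAMES[seq_len(config$n_cell_lines)]
    targets <- if (!is.null(ground_truth)) ground_truth$driver_set
    else character()
    for (d in evid) {
      if (stats::runif(1) < 0.8)
        drugBio[[length(drugBio) + 1L]] <- data.frame(
          compound_id = d, activity_scope = "cell",
          scope_id = lines[sample.int(length(lines), 1L)],
          standard_type = .sampleTypes(1L, .CELL_TYPES),
          standard_relation = "=",
          standard_value = 10^stats::runif(1, 1.5, 3),
          standard_units = "nM", assay_type = "F", target_type = "",
          target_organism = "Homo Sapiens")
      if (length(targets) && stats::runif(1) < 0.8)
        drugBio[[length(drugBio) + 1L]] <- data.frame(
          compound_id = d, activity_scope = "target",
          scope_id = targets[sample.int(length(targets), 1L)],
          standard_type = .sampleTypes(1L, .TARGET_TYPES),
          standard_relation = "=",
          standard_value = 10^stats::runif(1, 1, 4.7),
          standard_units = "nM", assay_type = "B",
          target_type = "Single protein",
          target_organism = "Homo Sapiens")
    }
    drug_bioactivities <- if (length(drugBio)) do.call(rbind, drugBio)
    else .emptyBioactivityTable()

    list(drugs = drugs, drug_meta = drug_meta,
         clinical_table = clinical,
         drug_bioactivities = drug_bioactivities,
         analog_map = stats::setNames(
           analogSource[match(analogIds, ids[isAnalog])], analogIds),
         analog_ops = stats::setNames(
           analogOp[match(analogIds, ids[isAnalog])], analogIds),
         analog_tc = do.call(rbind,
                             analogTc)[match(analogIds, ids[isAnalog]), ,
                                       drop = FALSE],
         distractor_ids = distractorIds)
  })
}

#' Run the full simulation
#'
#' Library, planted bioactivities and drug fixture in one call.
#'
#' @param config a [simulationConfig()].
#' @return list with library, cell_records, target_records, drugs,
#'   drug_meta, clinical_table, drug_bioactivities, ground_truth.
#' @export
simulateAll <- function(config = simulationConfig()) {
  library <- buildCompoundLibrary(config)
  planted <- plantBioactivities(library, config)

  cleanCell <- planted$cell_records[!planted$cell_records$dirty, ,
                                    drop = FALSE]
  actives <- selectActives(dedupBest(cleanCell), library)
  fixture <- makeDrugFixture(library, actives, config,
                             planted$ground_truth)

  gt <- planted$ground_truth
  gt$analog_map <- fixture$analog_map
  gt$analog_ops <- fixture$analog_ops
  gt$analog_tc <- fixture$analog_tc
  gt$distractor_ids <- fixture$distractor_ids
  gt$active_ids <- actives

  list(library = library, cell_records = planted$cell_records,
       target_records = planted$target_records, drugs = fixture$drugs,
       drug_meta = fixture$drug_meta,
       clinical_table = fixture$clinical_table,
       drug_bioactivities = fixture$drug_bioactivities,
       ground_truth = gt, config = config)
}

# --- fixture serialization -------------------------------------------------

#' @keywords internal
.writeTsv <- function(df, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, eol = "\n")
}

#' Write all fixtures to disk
#'
#' Writes the bioactivity table, library and drug SMILES, a drug SDF,
#' metadata and clinical tables, the ground-truth JSON and a manifest
#' listing paths and the master seed. Output is byte-reproducible (the
#' SDF timestamp line is neutralized).
#'
#' @param sim result of [simulateAll()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, the manifest list.
#' @export
writeFixtures <- function(sim, out_dir) {
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  p <- function(f) file.path(out_dir, f)

  bio <- rbind(sim$cell_records, sim$target_records)
  .writeTsv(bio, p("bioactivities.tsv"))
  .writeTsv(data.frame(smiles = compoundSmiles(sim$library),
                       compound_id = compoundIds(sim$library)),
            p("compounds.smi"))
  .writeTsv(data.frame(smiles = compoundSmiles(sim$drugs),
                       drug_id = compoundIds(sim$drugs)), p("drugs.smi"))
  .writeTsv(sim$drug_meta, p("drug_meta.tsv"))
  .writeTsv(sim$clinical_table, p("clinical.tsv"))
  .writeTsv(sim$drug_bioactivities, p("drug_bioactivities.tsv"))

  sdf <- ChemmineOB::convertFormat(
    "SMI", "SDF",
    paste(paste(compoundSmiles(sim$drugs), compoundIds(sim$drugs)),
          collapse = "\n"))
  sdf <- gsub(" OpenBabel[0-9]+", " SimCascade", sdf)
  writeLines(sdf, con <- file(p("drugs.sdf"), open = "wb"), sep = "")
  close(con)

  jsonlite::write_json(sim$ground_truth, p("ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    seed = sim$config$seed,
    files = list(bioactivities = "bioactivities.tsv",
                 compounds = "compounds.smi", drugs = "drugs.smi",
                 drugs_sdf = "drugs.sdf", drug_meta = "drug_meta.tsv",
                 clinical = "clinical.tsv",
                 drug_bioactivities = "drug_bioactivities.tsv",
                 ground_truth = "ground_truth.json"))
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}

#' Read fixtures back from disk
#'
#' @param dir directory written by [writeFixtures()].
#' @return list with the tables and compound sets (structures are
#'   re-standardized from the SMILES files).
#' @export
readFixtures <- function(dir) {
  rd <- function(f) utils::read.table(file.path(dir, f), sep = "\t",
                                      header = TRUE,
                                      stringsAsFactors = FALSE,
                                      quote = "", comment.char = "")
  bio <- rd("bioactivities.tsv")
  lib <- rd("compounds.smi")
  drg <- rd("drugs.smi")
  list(bioactivities = bio,
       cell_records = bio[bio$activity_scope == "cell", , drop = FALSE],
       target_records = bio[bio$activity_scope == "target", ,
                            drop = FALSE],
       library = standardizeCompounds(lib$smiles, lib$compound_id,
                                      source = "cell_active_set"),
       drugs = standardizeCompounds(drg$smiles, drg$drug_id,
                                    source = "drug_set"),
       drug_meta = rd("drug_meta.tsv"),
       clinical_table = rd("clinical.tsv"),
       drug_bioactivities = rd("drug_bioactivities.tsv"),
       ground_truth = jsonlite::read_json(
         file.path(dir, "ground_truth.json"), simplifyVector = TRUE))
}
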