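test_that("spearman matches textbook cases", {
  expect_equal(spearmanRho(c(100, 200, 300, 400), c(1, 2, 3, 4))$rho, 1.0)
  expect_equal(spearmanRho(c(1, 2, 3), c(3, 2, 1))$rho, -1.0)
  # classical rank-difference formula: rho = 1 - 6*sum(d^2)/(n(n^2-1))
  r <- spearmanRho(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(r$rho, 1 - 6 * 4 / (5 * 24))
  expect_equal(r$rho, 0.8)
  # invariance under strictly monotone transforms
  x <- c(3, 8, 2, 9, 5, 7); y <- c(10, 80, 35, 200, 22, 90)
  expect_equal(spearmanRho(x, y)$rho, spearmanRho(log10(x), -1 / y)$rho)
  expect_equal(spearmanRho(x, y)$rho, spearmanRho(10^x, y)$rho)
  # errors
  expect_error(spearmanRho(c(1, 2), c(1, 2)),
               class = "insufficientDataError")
  expect_error(spearmanRho(c(1, 1, 1), c(1, 2, 3)),
               class = "undefinedCorrelationError")
})

test_that("spearman agrees with the average-rank + Pearson oracle on an
           exhaustive small domain with heavy ties", {
  dom <- c(1, 2, 3)
  worst <- 0
  for (n in 3:4) {
    grids <- as.matrix(expand.grid(rep(list(dom), n)))
    ok <- apply(grids, 1, function(v) var(v) > 0)
    grids <- grids[ok, , drop = FALSE]
    # all ordered pairs of admissible vectors at this length
    for (i in seq_len(nrow(grids))) {
      x <- grids[i, ]
      # pair against a deterministic stride of the grid to keep the loop
      # bounded while covering every vector as both x and y
      js <- unique(c(i, ((i * 7 + seq_len(12)) %% nrow(grids)) + 1L))
      for (j in js) {
        y <- grids[j, ]
        d <- abs(spearmanRho(x, y)$rho - bruteSpearman(x, y))
        worst <- max(worst, d)
      }
    }
  }
  # longer vectors, sampled deterministically from the same domain
  set.seed(31)
  for (rep in 1:400) {
    n <- sample(5:8, 1)
    x <- sample(dom, n, replace = TRUE)
    y <- sample(dom, n, replace = TRUE)
    if (var(x) == 0 || var(y) == 0) next
    worst <- max(worst, abs(spearmanRho(x, y)$rho - bruteSpearman(x, y)))
  }
  expect_lt(worst, 1e-12)
})

test_that("p-values follow the t approximation with n-2 df", {
  set.seed(9)
  x <- rnorm(20); y <- 0.5 * x + rnorm(20)
  r <- spearmanRho(x, y)
  tstat <- r$rho * sqrt((r$n - 2) / (1 - r$rho^2))
  expect_equal(r$p_value, 2 * pt(-abs(tstat), r$n - 2))
  expect_gte(r$p_value, 0); expect_lte(r$p_value, 1)
})

test_that("Bonett-Wright interval matches its closed form and nests", {
  # independent recomputation of the closed form
  rho <- 0.6; n <- 30
  se <- sqrt((1 + rho^2 / 2) / (n - 3))
  lo <- tanh(atanh(rho) - qnorm(0.975) * se)
  hi <- tanh(atanh(rho) + qnorm(0.975) * se)
  ci <- rhoConfidenceInterval(rho, n)
  expect_equal(unname(ci), c(lo, hi), tolerance = 1e-10)
  expect_lt(ci[1], rho); expect_gt(ci[2], rho)
  # symmetric about zero when rho = 0
  ci0 <- rhoConfidenceInterval(0, 200)
  expect_equal(unname(ci0[1]), -unname(ci0[2]), tolerance = 1e-12)
  # 99% interval strictly contains the 95% interval
  ci99 <- rhoConfidenceInterval(0.6, 30, level = 0.99)
  expect_lt(ci99[1], ci[1]); expect_gt(ci99[2], ci[2])
  expect_error(rhoConfidenceInterval(0.5, 3),
               class = "insufficientDataError")
  # bootstrap alternative is seeded and reproducible
  set.seed(12); x <- rnorm(25); y <- x + rnorm(25)
  b1 <- rhoBootstrapInterval(x, y, seed = 4)
  b2 <- rhoBootstrapInterval(x, y, seed = 4)
  expect_identical(b1, b2)
  expect_lt(b1[1], b1[2])
})

test_that("pair building is an inner join with dedup preconditions", {
  tr <- cleanTargetTable(paste0("c", 1:12), 10 * (1:12))
  cr <- cleanCellTable(paste0("c", 5:12), 100 * (5:12))
  pv <- buildPairs(tr, cr, "PC-3")
  expect_equal(pv$n, 8L)
  expect_equal(pv$pairs$compound_id, paste0("c", 5:12))
  expect_equal(pv$pairs$target_value_nm, 10 * (5:12))
  # no shared compounds
  expect_equal(buildPairs(tr, cleanCellTable("zz", 5), "PC-3")$n, 0L)
  # duplicates violate the contract
  expect_error(buildPairs(tr, rbind(cr, cr[1, ]), "PC-3"),
               class = "duplicateKeyError")
})

test_that("annotation floor and selection rule behave at boundaries", {
  recs <- rbind(cleanTargetTable(paste0("c", 1:10), 1:10, "T10"),
                cleanTargetTable(paste0("c", 1:9), 1:9, "T9"))
  expect_equal(suppressMessages(minAnnotationFilter(recs)), "T10")
  expect_length(suppressMessages(
    minAnnotationFilter(recs[integer(), ])), 0L)

  res <- data.frame(
    target_id = c("a", "b", "c"), cell_line = "PC-3", n = 30,
    rho = c(0.55, 0.55, 0.39), p_value = c(1e-4, 1e-4, 1e-4),
    ci_low = c(0.42, 0.31, 0.35), ci_high = 0.9, selected = FALSE)
  expect_equal(selectTargets(res)$target_id, "a")
  expect_equal(selectTargets(res, require_ci = FALSE)$target_id,
               c("a", "b"))
})

test_that("planted drivers are recovered and decoys rejected", {
  sim <- smallSim()
  cell <- suppressMessages(dedupBest(filterCellBioactivities(
    sim$cell_records)))
  targ <- suppressMessages(filterTargetBioactivities(sim$target_records))
  corr <- suppressMessages(correlateTargets(targ, cell))
  gt <- sim$ground_truth
  sel <- unique(corr$target_id[corr$selected])
  expect_true(all(gt$driver_set %in% sel))
  expect_false(any(gt$decoy_set %in% sel))
  # sign convention: same potency scale on both axes gives positive rho
  expect_true(all(corr$rho[corr$target_id %in% gt$driver_set] > 0))
  # invariants of the result table
  ok <- !is.na(corr$rho)
  expect_true(all(corr$ci_low[ok] <= corr$rho[ok] &
                    corr$rho[ok] <= corr$ci_high[ok]))
})
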