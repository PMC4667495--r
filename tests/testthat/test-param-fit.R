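## Recovery experiments run against the synthetic forward model: reference
## charges generated by the solver under known (A*, B*, kappa*).

make_recovery_data <- function(seed, n, noise = 0, keys = NULL) {
  pool <- if (is.null(keys)) recovery_pool() else recovery_pool(keys)
  cfg <- generatorConfig(seed = seed, nMolecules = n, elementPool = pool,
                         chargeNoiseSigma = noise)
  makeGroundTruth(cfg, trueKappa = 0.44)
}

a_diff_error <- function(truth, fitted) {
  mm <- merge(truth, fitted, by = "typeKey")
  max(abs((mm$A.x - mm$A.x[1]) - (mm$A.y - mm$A.y[1])))
}

test_that("the anchored linear fit recovers the truth at the true kappa", {
  gt <- make_recovery_data(301L, 60L)
  f <- fitLinearForKappa(gt$examples, 0.44)
  expect_lt(f$residual, 1e-8)
  mm <- merge(paramEntries(gt$params), f$entries, by = "typeKey")
  expect_lt(max(abs(mm$B.x - mm$B.y)), 1e-6)
  expect_lt(max(abs(mm$A.x - mm$A.y)), 1e-6)   # scale anchored: absolute A
  ## the wrong kappa leaves a strictly larger residual
  f2 <- fitLinearForKappa(gt$examples, 0.64)
  expect_gt(f2$residual, f$residual + 1e-3)
})

test_that("the free-chiBar fit recovers B and A-differences up to the gauge", {
  gt <- make_recovery_data(302L, 60L)
  free <- strip_chibar(gt$examples)
  f <- fitLinearForKappa(free, 0.44)
  expect_lt(f$residual, 1e-8)
  mm <- merge(paramEntries(gt$params), f$entries, by = "typeKey")
  expect_lt(max(abs(mm$B.x - mm$B.y)), 1e-6)
  expect_lt(a_diff_error(paramEntries(gt$params), f$entries), 1e-6)
  ## residual grows monotonically with kappa in this mode
  f2 <- fitLinearForKappa(free, 0.64)
  expect_gt(f2$residual, f$residual)
})

test_that("types with too few atoms are refused by name", {
  gt <- make_recovery_data(303L, 8L)
  expect_error(fitLinearForKappa(gt$examples, 0.44, minAtomsPerType = 200L),
               "below 200 atoms")
  expect_error(fitLinearForKappa(gt$examples, 0.44, minAtomsPerType = 200L),
               "H1")
})

test_that("rank deficiency beyond the gauge is reported for degenerate designs", {
  ## one homonuclear diatomic with zero reference charges: A and B of the
  ## single type are unidentifiable even after fixing the gauge
  m <- Molecule("h2", c("H", "H"), rbind(c(0, 0, 0), c(0, 0, 0.74)))
  ex <- TrainingExample(m, c(0, 0))
  expect_warning(fitLinearForKappa(list(ex), 0.44, minAtomsPerType = 1L),
                 "rank deficiency")
})

test_that("the kappa search recovers kappa, B and A-differences without noise", {
  gt <- make_recovery_data(304L, 80L)
  fit <- searchKappa(gt$examples)
  expect_lt(abs(paramKappa(fit@params) - 0.44), 1e-3)
  mm <- merge(paramEntries(gt$params), paramEntries(fit@params), by = "typeKey")
  expect_lt(max(abs(mm$B.x - mm$B.y)), 1e-6)
  expect_lt(a_diff_error(paramEntries(gt$params), paramEntries(fit@params)),
            1e-6)
  expect_gte(fit@quality@r2, 0.9999)
  ## trace bookkeeping: every coarse grid point once, plus refinements
  grid <- seq(0.05, 1.50, by = 0.05)
  expect_equal(fit@kappaTrace$kappa[seq_along(grid)], grid)
  expect_equal(sum(fit@kappaTrace$stage == "grid"), length(grid))
  expect_gt(sum(fit@kappaTrace$stage == "refine"), 0L)
})

test_that("the winning kappa is locally optimal on the objective", {
  gt <- make_recovery_data(305L, 50L)
  cfg <- fitConfig()
  fit <- searchKappa(gt$examples, cfg)
  kBest <- paramKappa(fit@params)
  vBest <- evaluateKappaObjective(gt$examples, kBest, cfg)
  for (d in c(-5, 5) * 0.05) {
    k <- kBest + d
    if (k <= 0) next
    v <- evaluateKappaObjective(gt$examples, k, cfg)
    if (!is.na(v)) expect_lte(v, vBest + 1e-12)   # maximizing pooled R2
  }
})

test_that("validation on the training set reproduces the fit quality", {
  gt <- make_recovery_data(306L, 40L)
  fit <- searchKappa(gt$examples)
  q <- validateOnTestSet(fit@params, gt$examples)
  expect_equal(q@r2, fit@quality@r2, tolerance = 1e-12)
  expect_equal(q@rmsd, fit@quality@rmsd, tolerance = 1e-12)
  expect_equal(q@coverageFraction, fit@quality@coverageFraction)
})

test_that("uncovered molecules are skipped and counted in the coverage fraction", {
  gt <- make_recovery_data(307L, 40L)
  has_o2 <- vapply(gt$examples, function(e)
    "O2" %in% assignAtomTypes(e@molecule), logical(1))
  en <- paramEntries(gt$params)
  partial <- EEMParameterSet("partial", paramKappa(gt$params),
                             en[en$typeKey != "O2", ])
  q <- validateOnTestSet(partial, gt$examples)
  expect_equal(q@coverageFraction, (40 - sum(has_o2)) / 40)
  expect_equal(q@nMolecules, 40L - sum(has_o2))
  ## a set covering nothing is a contract error
  none <- EEMParameterSet("none", 0.4,
                          data.frame(typeKey = "Xe1", A = 2, B = 1))
  expect_error(validateOnTestSet(none, gt$examples), "covers none")
})

test_that("fitted sets generalize to held-out molecules from the same model", {
  gt <- make_recovery_data(308L, 60L)
  fit <- searchKappa(gt$examples)
  pool <- recovery_pool()
  heldCfg <- generatorConfig(seed = 9308L, nMolecules = 30L,
                             elementPool = pool)
  held <- makeGroundTruth(heldCfg, trueParams = gt$params)
  q <- validateOnTestSet(fit@params, held$examples)
  expect_gte(q@r2, 0.99)
})

test_that("the search is deterministic and more data never hurts", {
  gt <- make_recovery_data(309L, 30L)
  f1 <- searchKappa(gt$examples)
  f2 <- searchKappa(gt$examples)
  expect_equal(paramKappa(f1@params), paramKappa(f2@params), tolerance = 1e-12)
  expect_equal(paramEntries(f1@params), paramEntries(f2@params),
               tolerance = 1e-12)
  gtBig <- make_recovery_data(309L, 100L)
  fBig <- searchKappa(gtBig$examples)
  expect_lte(fBig@quality@rmsd, f1@quality@rmsd + 1e-8)
})

test_that("charges from a free-mode fit depend only on A-differences", {
  gt <- make_recovery_data(310L, 40L)
  fit <- searchKappa(strip_chibar(gt$examples))
  en <- paramEntries(fit@params)
  shifted <- EEMParameterSet("shifted", paramKappa(fit@params),
                             transform(en, A = A + 1.23))
  m <- gt$examples[[1]]@molecule
  expect_equal(charges(solveEEM(m, fit@params)),
               charges(solveEEM(m, shifted)), tolerance = 1e-12)
})

test_that("data demanding negative hardness are rejected", {
  ## reference data generated under a (deliberately unphysical) negative-B
  ## truth: the best-fitting candidate then carries B < 0 and the search
  ## must refuse to return it
  pool <- recovery_pool()
  keys <- unique(paste0(pool$element, pool$order))
  badTruth <- EEMParameterSet("antitruth", 0.44,
                              data.frame(typeKey = keys,
                                         A = seq(2.0, 3.0, length.out = 5),
                                         B = rep(-0.9, 5)))
  cfg <- generatorConfig(seed = 311L, nMolecules = 40L, elementPool = pool)
  gt <- makeGroundTruth(cfg, trueParams = badTruth)
  expect_error(searchKappa(gt$examples),
               "unphysical hardness|kappa search failed")
})
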