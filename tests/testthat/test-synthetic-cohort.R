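# Generative model: covariance construction, determinism, truncation,
# hubness-CBF linkage.

test_that("covariance reduces to the exact configured blocks", {
  # independence case
  cfg0 <- smallConfig(nRegions = 10L, nModules = 1L, withinModuleCorr = 0,
                      betweenModuleCorr = 0, hubRegions = integer(0),
                      hyperperfusionRegions = 2L, disconnectionRegions = 3L)
  expect_equal(buildCovariance(cfg0, "control"), diag(10))

  # two modules of two regions, no hubs: off-diagonals exactly within/between
  cfg <- smallConfig(nRegions = 4L, nModules = 2L, withinModuleCorr = 0.4,
                     betweenModuleCorr = 0.1, hubRegions = integer(0),
                     hyperperfusionRegions = 1L, disconnectionRegions = 2L)
  S <- buildCovariance(cfg, "control")
  expect_equal(diag(S), rep(1, 4))
  expect_equal(S[1, 2], 0.4)
  expect_equal(S[3, 4], 0.4)
  expect_equal(unname(S[1, 3]), 0.1)
  expect_equal(unname(S[2, 4]), 0.1)
})

test_that("patient attenuation scales incident covariance entries exactly", {
  cfg <- smallConfig(nRegions = 10L, disconnectionRegions = 1L,
                     disconnectionAttenuation = 0.5,
                     hubRegions = c(4L, 5L), hyperperfusionRegions = 7L)
  Sc <- buildCovariance(cfg, "control")
  Sp <- buildCovariance(cfg, "patient")
  expect_equal(Sp[1, -1], Sc[1, -1] / 2)
  expect_equal(Sp[-1, 1], Sc[-1, 1] / 2)
  expect_equal(Sp[-1, -1], Sc[-1, -1])
  expect_equal(diag(Sp), rep(1, 10))
})

test_that("hub rows carry more off-diagonal mass than non-hub rows", {
  cfg <- smallConfig(nRegions = 20L)
  S <- buildCovariance(cfg, "control")
  hubs <- cfg@hubRegions
  mass <- rowSums(S) - 1
  expect_gt(min(mass[hubs]), max(mass[-hubs]))
})

test_that("non-positive-definite configurations fail with a named error", {
  expect_error(
    buildCovariance(smallConfig(nRegions = 6L, nModules = 3L,
                                withinModuleCorr = 0.1,
                                betweenModuleCorr = 0.9,
                                hubRegions = integer(0),
                                hyperperfusionRegions = 1L,
                                disconnectionRegions = 2L)),
    "withinModuleCorr|positive definite")
})

test_that("identical config and seed give identical cohorts", {
  cfg <- smallConfig(seed = 99L)
  c1 <- generateCohort(cfg)
  c2 <- generateCohort(cfg)
  expect_identical(cbfMatrix(c1), cbfMatrix(c2))
  expect_identical(roiSeries(c1), roiSeries(c2))
  expect_identical(phenotype(c1), phenotype(c2))
})

test_that("cohort has the declared dimensions and strictly positive CBF", {
  cfg <- smallConfig(nPatients = 6L, nControls = 5L, nRegions = 15L,
                     nTimepoints = 30L, cbfBaselineMean = 5,
                     cbfNoiseSd = 8)  # stress positivity resampling
  coh <- suppressWarnings(generateCohort(cfg))
  expect_equal(dim(cbfMatrix(coh)), c(15L, 11L))
  expect_true(all(cbfMatrix(coh) > 0))
  expect_true(all(vapply(roiSeries(coh), function(m)
    all(dim(m) == c(30L, 15L)), logical(1))))
  expect_identical(truthInfo(coh)$hyperperfusionRegions,
                   cfg@hyperperfusionRegions)
})

test_that("MoCA truncation is respected in every subject", {
  coh <- generateCohort(smallConfig(nPatients = 40L, nControls = 40L,
                                    seed = 7L))
  ph <- phenotype(coh)
  expect_true(all(ph$moca[ph$group == "patient"] < 26))
  expect_true(all(ph$moca[ph$group == "control"] >= 26 &
                  ph$moca[ph$group == "control"] <= 30))
  expect_true(all(is.na(ph$hemoglobin[ph$group == "control"])))
  expect_true(all(!is.na(ph$hemoglobin[ph$group == "patient"])))
})

test_that("sample MoCA means track the configured group parameters", {
  coh <- generateCohort(cohortConfig(nRegions = 20L, nTimepoints = 40L,
                                     seed = 2024L))
  ph <- phenotype(coh)
  # within 3 standard errors of the configured (pre-truncation) means
  mP <- mean(ph$moca[ph$group == "patient"])
  mC <- mean(ph$moca[ph$group == "control"])
  expect_lt(abs(mP - 22.6), 3 * 3.6 / sqrt(45))
  expect_lt(abs(mC - 28.1), 3 * 2.2 / sqrt(40))
  # patient labs around the configured clinical distribution
  expect_lt(abs(mean(ph$hemoglobin[ph$group == "patient"]) - 95.36),
            3 * 4.12 / sqrt(45))
  expect_lt(abs(mean(ph$hematocrit[ph$group == "patient"]) - 27.17),
            3 * 1.79 / sqrt(45))
})

test_that("CBF-hubness coupling rises monotonically with the slope", {
  meanRho <- vapply(c(0, 5, 12), function(sl) {
    cfg <- cohortConfig(nPatients = 1L, nControls = 20L, nRegions = 30L,
                        nTimepoints = 40L, couplingSlopeControl = sl,
                        seed = 11L)
    coh <- generateCohort(cfg)
    h <- truthInfo(coh)$hubness
    ctrl <- groupLabels(coh) == "control"
    mean(apply(cbfMatrix(coh)[, ctrl], 2, function(v) cor(rank(v), rank(h))))
  }, numeric(1))
  expect_lt(abs(meanRho[1]), 0.12)  # slope 0: no coupling
  expect_gt(meanRho[2], meanRho[1])
  expect_gt(meanRho[3], meanRho[2])
})

test_that("short series trigger a rank-deficiency warning, not an error", {
  expect_warning(generateCohort(smallConfig(nRegions = 30L,
                                            nTimepoints = 20L)),
                 "rank-deficient")
})

test_that("cohort write/read round trip preserves every value", {
  coh <- generateCohort(smallConfig())
  dir <- withr::local_tempdir()
  writeCohort(coh, dir)
  back <- readCohort(dir)
  expect_equal(unname(cbfMatrix(back)), unname(cbfMatrix(coh)))
  expect_equal(unname(roiSeries(back, "P001")),
               unname(roiSeries(coh, "P001")))
  expect_equal(phenotype(back)$moca, phenotype(coh)$moca)
})
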