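test_that("identical configurations generate identical databases", {
  s1 <- smallSim(seed = 8)
  s2 <- smallSim(seed = 8)
  expect_identical(records(s1$db), records(s2$db))
  expect_identical(s1$descriptors, s2$descriptors)
  expect_identical(s1$properties, s2$properties)
  s3 <- smallSim(seed = 9)
  expect_false(identical(records(s1$db), records(s3$db)))
})

test_that("record counts follow the configuration", {
  cfg <- syntheticConfig(seed = 3, nOdorants = 50L, nORs = 6L,
                         nBehaviorOdorants = 20L, nSpecies = 2L)
  sim <- generateDatabase(cfg)
  rec <- records(sim$db)
  en <- rec[rec$technique == "empty_neuron", ]
  expect_equal(nrow(en), 50L * 6L)
  expect_equal(nrow(rec[rec$technique == "oocyte", ]), 50L * 6L)
  beh <- rec[rec$data_type == "BEHAVIOR" &
               rec$behavioral_context == "host_seeking_foraging", ]
  # 2 species x 3 assays x 4 decades x 2 replicates x 20 odorants
  expect_equal(nrow(beh), 2L * 3L * 4L * 2L * 20L)
  expect_equal(nrow(sim$properties), 51L)   # includes the EAG reference odorant
  expect_equal(nrow(sim$descriptors), 50L)
})

test_that("zero threshold and unit gain make oocyte records rectified copies", {
  sim <- generateDatabase(syntheticConfig(seed = 5, nOdorants = 30L,
                                          nORs = 4L, nBehaviorOdorants = 10L,
                                          oocyteThreshold = 0, oocyteGain = 1))
  rec <- records(sim$db)
  key <- function(d) paste(d$receptor_or_sensillum, d$odorant_canonical)
  en <- rec[rec$technique == "empty_neuron", ]
  oo <- rec[rec$technique == "oocyte", ]
  oo <- oo[match(key(en), key(oo)), ]
  expect_identical(oo$response_value, pmax(0, en$response_value))
})

test_that("no tuning pairs are lost when the property table is complete", {
  cfg <- syntheticConfig(seed = 6, nOdorants = 40L, nORs = 5L,
                         nBehaviorOdorants = 10L, missingPropertyRate = 0)
  sim <- generateDatabase(cfg)
  pairs <- selectTuningPairs(sim$db, sim$properties, "molecular_volume")
  expect_equal(nrow(pairs), 40L * 5L)
})

test_that("without planted slope and offsets the deltas are null-centered", {
  cfg <- syntheticConfig(seed = 14, concentrationSlope = 0,
                         assayOffsets = c(landing = 0, t_maze = 0, y_tube = 0,
                                          dual_port = 0, y_maze = 0))
  sim <- generateDatabase(cfg)
  cd <- concentrationPairDeltas(sim$db)
  se <- sd(cd@pairs$delta) / sqrt(nObs(cd))
  expect_lt(abs(meanDelta(cd)), 2 * se)
})

test_that("the full pipeline recovers the planted parameters at default sizes", {
  sim <- generateDatabase(syntheticConfig(seed = 51))
  # tuning center and width within 10%
  pairs <- selectTuningPairs(sim$db, sim$properties, "molecular_volume")
  fit <- fitGaussianTuning(pairs)
  expect_lt(abs(fit$b - sim$truth$b) / sim$truth$b, 0.10)
  expect_lt(abs(fit$sigma - sim$truth$sigma) / sim$truth$sigma, 0.10)
  # concentration slope within +/- 0.05 of beta = 0.2 (deltas are negative)
  cd <- concentrationPairDeltas(sim$db)
  expect_lt(abs(meanDelta(cd) - (-sim$truth$beta)), 0.05)
  # negative loading of preference on activation count: sign recovered
  oc <- orActivationVsPi(sim$db)
  expect_lt(pearsonR(oc), 0)
})

test_that("configuration invariants are enforced", {
  expect_error(syntheticConfig(responseNoiseSD = -1))
  expect_error(syntheticConfig(oocyteThreshold = -5))
  expect_error(syntheticConfig(inhibFraction = 1.5))
  expect_error(syntheticConfig(ovipositionMode = "sometimes"))
  expect_error(syntheticConfig(nOdorants = 10L, nBehaviorOdorants = 20L))
})
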