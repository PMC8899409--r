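test_that("odorant names resolve through the synonym table", {
  tab <- readSynonymTable(system.file("extdata", "synonyms_example.tsv",
                                      package = "odorDB"))
  id <- canonicalizeOdorant("isopentanol", tab)
  expect_equal(id$canonical_name, "3-methyl-1-butanol")
  expect_equal(id$molecular_weight, 88.15)
  # case / whitespace variants map to the same identity
  id2 <- canonicalizeOdorant("  3-Methyl-1-Butanol ", tab)
  expect_equal(id2$canonical_name, id$canonical_name)
  id3 <- canonicalizeOdorant("Isoamyl  Alcohol", tab)
  expect_equal(id3$canonical_name, "3-methyl-1-butanol")
  expect_error(canonicalizeOdorant("odorant-xyz-unknown", tab),
               class = "odorDB_unmapped_odorant")
})

test_that("preference index follows the two-choice formula and its symmetries", {
  expect_equal(computePreferenceIndex(75, 25), 0.5)
  expect_equal(computePreferenceIndex(40, 40), 0)
  expect_equal(computePreferenceIndex(0, 50), -1)
  expect_error(computePreferenceIndex(0, 0), class = "odorDB_undefined_index")
  expect_error(computePreferenceIndex(-1, 5), class = "odorDB_range")
  set.seed(1)
  for (i in 1:50) {
    a <- sample(0:100, 1); b <- sample(0:100, 1)
    if (a + b == 0) next
    pi_ab <- computePreferenceIndex(a, b)
    expect_true(pi_ab >= -1 && pi_ab <= 1)
    expect_equal(pi_ab, -computePreferenceIndex(b, a))
  }
})

test_that("percent attraction / repellency map linearly onto the PI scale", {
  expect_equal(convertPercentMetric("percent_attraction", 75), 0.5)
  expect_equal(convertPercentMetric("percent_attraction", 50), 0)
  expect_equal(convertPercentMetric("percent_repellency", 100), -1)
  # consistency with the two-choice interpretation
  expect_equal(convertPercentMetric("percent_attraction", 75),
               computePreferenceIndex(75, 25))
  expect_error(convertPercentMetric("percent_attraction", 120),
               class = "odorDB_range")
})

test_that("concentration conversions reproduce the worked examples", {
  lac <- convertConcentration(1.11e-5, "molar", molecular_weight = 90.08)
  expect_equal(lac$value, 1e-6)
  expect_equal(lac$unit_kind, "wv_g_per_ml")
  ppm <- convertConcentration(1, "ppm")
  expect_equal(ppm$value, 1e-6)  # 1 ppm = 1 mg/L = 1e-6 g/mL
  cloth <- convertConcentration(1e-6, "mass_per_area_with_volume",
                                area_cm2 = 6.6, volume_ml = 0.025)
  expect_equal(cloth$value, 2.64e-4)
  # dimensional consistency: 1 M of a MW-1000 compound is exactly 1 g/mL
  expect_identical(convertConcentration(1, "molar",
                                        molecular_weight = 1000)$value, 1)
  expect_equal(convertConcentration(0.01, "vv_fraction")$value, 0.01)
  dry <- convertConcentration(0.5, "dry_amount_g")
  expect_equal(dry$unit_kind, "dry_amount_g")
  expect_error(convertConcentration(1e-3, "molar"),
               class = "odorDB_missing_mw")
  expect_error(convertConcentration(1e-6, "mass_per_area_with_volume",
                                    area_cm2 = -1, volume_ml = 0.025),
               class = "odorDB_range")
})

test_that("background subtraction permits inhibition and is idempotent", {
  expect_equal(subtractBackground(50, 10, FALSE), 40)
  expect_equal(subtractBackground(5, 10, FALSE), -5)
  expect_equal(subtractBackground(40, 10, TRUE), 40)
})

test_that("decade rounding is nearest-power-of-ten with lower-exponent halves", {
  expect_equal(roundConcentrationDecade(3e-3), 1e-3)
  expect_equal(roundConcentrationDecade(1e-2), 1e-2)
  expect_equal(roundConcentrationDecade(9e-3), 1e-2)
  # exact half-case 10^(k + 1/2) rounds toward the lower exponent
  expect_equal(roundConcentrationDecade(10^-2.5), 1e-3)
  expect_error(roundConcentrationDecade(0), class = "odorDB_range")
  set.seed(2)
  c0 <- 10^runif(50, -6, 0)
  once <- roundConcentrationDecade(c0)
  expect_equal(roundConcentrationDecade(once), once)  # idempotent
  # dry amounts get no decade and never match solutions
  expect_true(is.na(concentrationDecade(0.5, "dry_amount_g")))
  # 0.3 sits closer to 10^-1 than to 10^0 on the log10 axis
  expect_equal(concentrationDecade(c(0.01, 0.3), c("vv_fraction",
                                                   "wv_g_per_ml")),
               c(-2, -1))
})

test_that("EAG normalization divides by the study's mean reference response", {
  rec <- rbind(
    data.frame(data_type = "EAG", species = "Aaeg",
               odorant_canonical = c("1-octen-3-ol", "odor-A"),
               concentration_value = 0.01, concentration_unit = "vv_fraction",
               response_value = c(2, 1), response_unit = "mV",
               technique = "eag", study_id = "s1",
               eag_reference = NA_character_, stringsAsFactors = FALSE))
  out <- normalizeEAG(rec)
  expect_equal(out$response_value, c(1, 0.5))
  expect_equal(unique(out$eag_reference), "1-octen-3-ol")
  # idempotent on flagged records
  expect_identical(normalizeEAG(out), out)
  noref <- rec[rec$odorant_canonical != "1-octen-3-ol", , drop = FALSE]
  expect_error(normalizeEAG(noref), class = "odorDB_missing_reference")
  zero <- rec; zero$response_value[1] <- 0
  expect_error(normalizeEAG(zero), class = "odorDB_zero_reference")
})

test_that("ResponseDB validity enforces the record invariants", {
  good <- behaviorRecord("a", 0.5, -2)
  bad <- good; bad$response_value <- 1.5
  expect_error(ResponseDB(bad))                               # PI out of range
  badOR <- orRecord("a", "OR1", 10)
  badOR$assay_category <- "y_tube"
  expect_error(ResponseDB(badOR))                             # assay on non-BEHAVIOR
  badOR2 <- orRecord("a", "OR1", 10)
  badOR2$receptor_or_sensillum <- NA_character_
  expect_error(ResponseDB(badOR2))                            # OR without receptor
  bad3 <- good; bad3$study_id <- ""
  expect_error(ResponseDB(bad3))                              # empty study
  ok <- ResponseDB(good)
  expect_s4_class(ok, "ResponseDB")
  expect_equal(nObs(ok), 1L)
})
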