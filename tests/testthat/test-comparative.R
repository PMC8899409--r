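test_that("sign-rank p-values match exhaustive enumeration up to n = 10", {
  set.seed(21)
  cases <- c(
    lapply(1:8, function(i) rnorm(sample(3:10, 1))),
    list(c(1, 1, -1, 2, 2),              # ties in |d|
         c(0, 0.5, -0.5, 2, 0),          # zeros dropped
         c(1, 2, 3), c(-1, -2, -3, -4)))
  for (d in cases) {
    res <- signRankTest(d)
    expect_identical(res$p.value, enumSignRankP(d))
  }
  # agreement with the normal approximation at larger n
  set.seed(22)
  d <- rnorm(60, 0.3)
  res <- signRankTest(d)
  ref <- wilcox.test(d, exact = FALSE, correct = TRUE)
  expect_equal(res$p.value, ref$p.value, tolerance = 1e-6)
})

test_that("technique crosstab reproduces the hand-counted example", {
  en <- rbind(orRecord("o1", "OR1", 5), orRecord("o2", "OR1", 0),
              orRecord("o3", "OR1", -3), orRecord("o4", "OR1", 0))
  oo <- rbind(orRecord("o1", "OR1", 0, technique = "oocyte"),
              orRecord("o2", "OR1", 0, technique = "oocyte"),
              orRecord("o3", "OR1", 0, technique = "oocyte"),
              orRecord("o4", "OR1", 2, technique = "oocyte"))
  ct <- crosstabTechniques(en, oo)
  expect_equal(ct@nPairs, 4L)
  expect_equal(ct@enNonzeroOoZero, 2L)
  expect_equal(ct@enZeroOoNonzero, 1L)
  expect_equal(ct@ooZeroBreakdown,
               c(en_positive = 1L, en_zero = 1L, en_negative = 1L))
  expect_equal(ct@meanSdEnGivenOoZeroNegative[["mean"]], -3)
  # identical datasets show no asymmetry
  ct2 <- crosstabTechniques(en, en)
  expect_equal(ct2@enNonzeroOoZero, 0L)
  expect_equal(ct2@enZeroOoNonzero, 0L)
  expect_error(crosstabTechniques(en, orRecord("zz", "OR9", 1,
                                               technique = "oocyte")),
               class = "odorDB_empty_join")
})

test_that("assay-category pairing averages within sets before pairing", {
  rec <- rbind(
    behaviorRecord("X", -0.4, -1, assay = "landing", study = "s1"),
    behaviorRecord("X", -0.2, -1, assay = "landing", study = "s2"),
    behaviorRecord("X", 0.1, -1, assay = "dual_port", study = "s3"),
    behaviorRecord("Y", 0.3, -1, assay = "landing", study = "s1"))
  pc <- pairByAssayCategory(rec, "landing", c("dual_port", "y_tube"))
  expect_equal(nObs(pc), 1L)               # odor Y has no non-landing data
  expect_equal(pc@pairs$value_a, -0.3)     # mean of -0.4 and -0.2
  expect_equal(pc@pairs$value_b, 0.1)
  expect_equal(meanDelta(pc), -0.4)
  # antisymmetry under swapping the category sets
  rec2 <- rbind(rec, behaviorRecord("Z", 0.5, -2, assay = "landing"),
                behaviorRecord("Z", 0.1, -2, assay = "y_tube"))
  a <- pairByAssayCategory(rec2, "landing", c("dual_port", "y_tube"))
  b <- pairByAssayCategory(rec2, c("dual_port", "y_tube"), "landing")
  expect_equal(meanDelta(a), -meanDelta(b))
  expect_equal(a@pairs$value_a - a@pairs$value_b,
               -(b@pairs$value_a - b@pairs$value_b))
  expect_error(pairByAssayCategory(rec, "wind_tunnel", "tip"),
               class = "odorDB_empty_comparison")
})

test_that("assay offset planted in the generator is recovered", {
  sim <- generateDatabase(syntheticConfig(seed = 41))
  pc <- pairByAssayCategory(sim$db, "landing", c("dual_port", "y_tube"),
                            species = c("Aaeg", "Cqui"))
  expect_gte(nObs(pc), 30L)
  expect_lt(abs(meanDelta(pc) - (-0.3)), 0.1)
})

test_that("preference vs oviposition matching enforces the 5-item minimum", {
  mk <- function(n) {
    do.call(rbind, lapply(seq_len(n), function(i) rbind(
      behaviorRecord(paste0("o", i), 0.1 * i - 0.3, -3),
      behaviorRecord(paste0("o", i), 0.1 * i - 0.3, -3, assay = "dual_port",
                     study = "s-ovi", context = "oviposition"))))
  }
  res <- correlatePiOviposition(mk(6), "Aaeg")
  expect_equal(pearsonR(res), 1)           # identical index vectors
  expect_equal(nObs(res), 6L)
  expect_error(correlatePiOviposition(mk(4), "Aaeg"),
               class = "odorDB_species_skipped")
})

test_that("cross-species matching uses equal decades, then one-decade nearest", {
  mk <- function(sp, odor, pi, dec)
    behaviorRecord(odor, pi, dec, species = sp)
  base <- do.call(rbind, lapply(1:10, function(i) rbind(
    mk("Aaeg", paste0("o", i), 0.05 * i, -2),
    mk("Cqui", paste0("o", i), 0.05 * i, -2))))
  res <- crossSpeciesCorrelation(base, "Aaeg", "Cqui")
  expect_equal(pearsonR(res), 1)
  # an odor two decades apart is excluded
  two <- rbind(base, mk("Aaeg", "far", 0.2, -2), mk("Cqui", "far", 0.4, -4))
  res2 <- crossSpeciesCorrelation(two, "Aaeg", "Cqui")
  expect_false("far" %in% res2@matchedItems$odorant_canonical)
  # one decade apart is matched
  one <- rbind(base, mk("Aaeg", "near", 0.2, -2), mk("Cqui", "near", 0.4, -3))
  res3 <- crossSpeciesCorrelation(one, "Aaeg", "Cqui")
  expect_true("near" %in% res3@matchedItems$odorant_canonical)
  # fewer than 10 common odorants: the pair is skipped
  expect_error(crossSpeciesCorrelation(base[1:18, ], "Aaeg", "Cqui"),
               class = "odorDB_pair_skipped")
})

test_that("concentration deltas need two points per cell and adjacent decades", {
  rec <- rbind(
    behaviorRecord("X", 0.3, -3, study = "s1"),
    behaviorRecord("X", 0.3, -3, study = "s2"),
    behaviorRecord("X", 0.1, -2, study = "s1"),
    behaviorRecord("X", 0.1, -2, study = "s2"))
  cd <- concentrationPairDeltas(rec)
  expect_equal(nObs(cd), 1L)
  expect_equal(cd@pairs$delta, -0.2)
  # a lone data point is not an eligible cell
  lone <- rbind(rec, behaviorRecord("X", 0.5, -1, study = "s1"))
  expect_equal(nObs(concentrationPairDeltas(lone)), 1L)
  # 100-fold separation yields no pair
  far <- rbind(
    behaviorRecord("Y", 0.2, -4, study = "s1"),
    behaviorRecord("Y", 0.2, -4, study = "s2"),
    behaviorRecord("Y", 0.1, -2, study = "s1"),
    behaviorRecord("Y", 0.1, -2, study = "s2"))
  expect_error(concentrationPairDeltas(far),
               class = "odorDB_empty_comparison")
  # sign filter on the lower-decade preference index
  neg <- rbind(
    behaviorRecord("Z", -0.3, -3, study = "s1"),
    behaviorRecord("Z", -0.3, -3, study = "s2"),
    behaviorRecord("Z", -0.5, -2, study = "s1"),
    behaviorRecord("Z", -0.5, -2, study = "s2"))
  both <- rbind(rec, neg)
  expect_equal(nObs(concentrationPairDeltas(both, "negative")), 1L)
  expect_equal(nObs(concentrationPairDeltas(both, "positive")), 1L)
  expect_equal(nObs(concentrationPairDeltas(both, "all")), 2L)
})

test_that("OR activation counts use the at-least-threshold rule", {
  en <- rbind(orRecord("o1", "OR1", 12), orRecord("o1", "OR2", 9),
              orRecord("o1", "OR3", -5), orRecord("o1", "OR4", 30),
              orRecord("o2", "OR1", 10), orRecord("o2", "OR2", 0),
              orRecord("o3", "OR1", 50), orRecord("o3", "OR2", 50))
  beh <- rbind(behaviorRecord("o1", 0.5, -2), behaviorRecord("o2", 0.1, -2),
               behaviorRecord("o3", -0.4, -2))
  res <- orActivationVsPi(rbind(en, beh), threshold = 10)
  counts <- res@matchedItems$n_activated[
    match(c("o1", "o2", "o3"), res@matchedItems$odorant_canonical)]
  expect_equal(counts, c(2L, 1L, 2L))      # exactly 10 counts as activated
  expect_error(orActivationVsPi(rbind(en[1:6, ], beh[1:2, ])),
               class = "odorDB_undefined_correlation")
})

test_that("matching operations are insensitive to input row order", {
  sim <- smallSim()
  rec <- records(sim$db)
  set.seed(5)
  shuf <- rec[sample(nrow(rec)), ]
  expect_equal(crosstabTechniques(shuf)@pairs, crosstabTechniques(rec)@pairs)
  a1 <- pairByAssayCategory(rec, "landing", c("dual_port", "y_tube"))
  a2 <- pairByAssayCategory(shuf, "landing", c("dual_port", "y_tube"))
  expect_equal(a1@pairs, a2@pairs)
  d1 <- concentrationPairDeltas(rec)
  d2 <- concentrationPairDeltas(shuf)
  expect_equal(d1@pairs, d2@pairs)
})
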