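test_that("noiseless Gaussian parameters are recovered to machine precision", {
  x <- seq(40, 160, length.out = 30)
  r <- 100 * exp(-(x - 100)^2 / (2 * 30^2))
  fit <- fitGaussianTuning(x, r)
  expect_lt(abs(fit$a - 100) / 100, 1e-6)
  expect_lt(abs(fit$b - 100) / 100, 1e-6)
  expect_lt(abs(fit$sigma - 30) / 30, 1e-6)
})

test_that("fit errors are raised for degenerate inputs", {
  expect_error(fitGaussianTuning(c(1, 2, 3), c(1, 2, 1)),
               class = "odorDB_degenerate_fit")
  expect_error(fitGaussianTuning(rep(2, 6), rnorm(6)),
               class = "odorDB_degenerate_fit")
  expect_error(fitGaussianTuning(c(1, 2, NA, 4), c(1, 2, 3, 4)),
               class = "odorDB_schema")
})

test_that("fitted sigma agrees with an independent solver on noisy data", {
  set.seed(7)
  for (i in 1:5) {
    x <- rnorm(80, 100, 40)
    r <- 100 * exp(-(x - 100)^2 / (2 * 30^2)) + rnorm(80, 0, 10)
    fit <- fitGaussianTuning(x, r)
    expect_equal(fit$sigma, nlsSigma(x, r), tolerance = 1e-5)
  }
})

test_that("sigma is invariant under reflection of the property axis", {
  set.seed(3)
  x <- rnorm(60, 0, 2)
  r <- 5 * exp(-(x - 0.5)^2 / 2) + rnorm(60, 0, 0.3)
  f1 <- fitGaussianTuning(x, r)
  f2 <- fitGaussianTuning(-x, r)
  expect_equal(f2$b, -f1$b, tolerance = 1e-12)
  expect_equal(f2$sigma, f1$sigma, tolerance = 1e-12)
})

test_that("permutation test is seeded, reproducible and grid-valued", {
  set.seed(5)
  x <- rnorm(50, 100, 40)
  r <- 100 * exp(-(x - 100)^2 / (2 * 30^2)) + rnorm(50, 0, 30)
  t1 <- permutationTestSigma(data.frame(x = x, response = r),
                             nShuffles = 100, seed = 42)
  t2 <- permutationTestSigma(data.frame(x = x, response = r),
                             nShuffles = 100, seed = 42)
  expect_identical(pValue(t1), pValue(t2))
  expect_true(pValue(t1) %in% seq(0, 1, by = 1 / 100))
  t3 <- permutationTestSigma(data.frame(x = x, response = r),
                             nShuffles = 100, seed = 43)
  expect_s4_class(t3, "TuningFit")
})

test_that("median permutation p increases with planted noise", {
  medP <- function(noise_sd) {
    ps <- vapply(1:8, function(i) {
      set.seed(100 + i)
      x <- rnorm(60, 100, 40)
      r <- 30 * exp(-(x - 100)^2 / (2 * 30^2)) + rnorm(60, 0, noise_sd)
      pValue(permutationTestSigma(data.frame(x = x, response = r),
                                  nShuffles = 100, seed = i))
    }, numeric(1))
    median(ps)
  }
  p_low <- medP(3)
  p_mid <- medP(60)
  p_high <- medP(500)
  expect_lte(p_low, p_mid)
  expect_lte(p_mid, p_high)
})

test_that("eligible properties need at least ten distinct values", {
  odors <- sprintf("o%02d", 1:12)
  props <- data.frame(odorant_canonical = odors,
                      binary = rep(c(0, 1), 6),
                      rich = seq_len(12) / 7,
                      ten = c(1:10, 1, 2),
                      check.names = FALSE)
  expect_equal(eligibleProperties(props, odors), c("rich", "ten"))
  expect_equal(eligibleProperties(props, character(0)), character(0))
  expect_equal(eligibleProperties(props, odors[1:5]), character(0))
})

test_that("tuning pairs are selected at one decade with known properties", {
  rec <- rbind(orRecord("a", "OR1", 10), orRecord("b", "OR1", 20),
               orRecord("c", "OR1", 30), orRecord("a", "OR2", 5, decade = -3))
  props <- data.frame(odorant_canonical = c("a", "b", "c"),
                      vol = c(90, NA, 110))
  pairs <- selectTuningPairs(rec, props, "vol", decade = 1e-2)
  expect_equal(nrow(pairs), 2L)  # b lacks the property, OR2 is at 1e-3
  expect_setequal(pairs$odorant, c("a", "c"))
  expect_error(selectTuningPairs(rec, props, "vol", decade = 1e-6),
               class = "odorDB_empty_selection")
})

test_that("per-property shuffle streams are order-independent", {
  sim <- smallSim()
  fits1 <- tuningAnalysis(sim$db, sim$properties, nShuffles = 50, seed = 9)
  # reversing the property columns must not change any per-property p
  propsRev <- sim$properties[, c(1, rev(seq_len(ncol(sim$properties) - 1)) + 1)]
  fits2 <- tuningAnalysis(sim$db, propsRev, nShuffles = 50, seed = 9)
  expect_setequal(names(fits1), names(fits2))
  for (p in names(fits1))
    expect_identical(pValue(fits1[[p]]), pValue(fits2[[p]]))
})
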