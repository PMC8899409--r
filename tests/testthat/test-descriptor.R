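test_that("descriptor filter drops missing, low-variance and redundant columns", {
  set.seed(1)
  n <- 40
  base <- rnorm(n)
  m <- cbind(const = rep(2, n),             # zero variance
             a = base,
             a_dup = base,                  # r = 1 with a -> dropped
             b = rnorm(n),
             holes = replace(rnorm(n), 3, NA))  # missing value
  out <- filterDescriptors(m)
  expect_equal(colnames(out), c("a", "b"))
  stages <- attr(out, "stages")
  expect_true(all(diff(stages) <= 0))        # count never increases
  # idempotence
  out2 <- filterDescriptors(out)
  expect_equal(colnames(out2), colnames(out))
  expect_equal(unname(out2[, ]), unname(out[, ]))
})

test_that("greedy correlation filter matches a brute-force oracle", {
  set.seed(42)
  for (trial in 1:20) {
    n <- 30
    latent <- matrix(rnorm(n * 2), n)
    m <- sapply(1:6, function(j) {
      w <- runif(1)
      latent %*% rnorm(2) * w + rnorm(n) * (1 - w)
    })
    colnames(m) <- paste0("d", 1:6)
    out <- filterDescriptors(m, var_min = 0)
    kept <- colnames(out)
    dropped <- setdiff(colnames(m), kept)
    cm <- abs(cor(m))
    # every retained pair is below the threshold
    if (length(kept) > 1)
      expect_true(all(cm[kept, kept][upper.tri(diag(length(kept)))] <= 0.95))
    # every dropped column conflicts with an EARLIER retained survivor
    for (d in dropped) {
      earlier <- kept[match(kept, colnames(m)) < match(d, colnames(m))]
      expect_true(any(cm[d, earlier] > 0.95))
    }
  }
})

test_that("odorant split sizes round with remainder to train and are seeded", {
  odors <- sprintf("o%03d", 1:112)
  sp <- splitOdorants(odors, seed = 7)
  expect_equal(lengths(sp)[c("train", "validation", "test")],
               c(train = 78L, validation = 17L, test = 17L))
  expect_setequal(unlist(sp), odors)                      # exhaustive
  expect_equal(anyDuplicated(unlist(sp)), 0L)             # disjoint
  expect_identical(splitOdorants(odors, seed = 7), sp)    # deterministic
  expect_error(splitOdorants(odors[1:5]), class = "odorDB_config")
  expect_error(splitOdorants(odors, fractions = c(0.5, 0.3, 0.3)),
               class = "odorDB_config")
})

test_that("network training is deterministic and learns a linear target", {
  set.seed(10)
  X <- matrix(rnorm(112 * 8), 112,
              dimnames = list(sprintf("o%03d", 1:112), paste0("d", 1:8)))
  w <- rnorm(8)
  y <- drop(X %*% w); names(y) <- rownames(X)
  rs <- vapply(1:10, function(s) {
    sp <- splitOdorants(rownames(X), seed = s)
    mod <- trainORModel(X, y, sp$train, sp$validation, seed = s)
    cor(predict(mod, X[sp$test, ]), y[sp$test])
  }, numeric(1))
  expect_gte(median(rs), 0.95)
  # determinism: identical seed, identical predictions
  sp <- splitOdorants(rownames(X), seed = 1)
  m1 <- trainORModel(X, y, sp$train, sp$validation, seed = 3)
  m2 <- trainORModel(X, y, sp$train, sp$validation, seed = 3)
  expect_identical(predict(m1, X[sp$test, ]), predict(m2, X[sp$test, ]))
  expect_error(trainORModel(X, replace(y, 1, NaN), sp$train, sp$validation),
               class = "odorDB_data")
})

test_that("structureless targets give test correlations centered near zero", {
  set.seed(11)
  X <- matrix(rnorm(112 * 8), 112,
              dimnames = list(sprintf("o%03d", 1:112), paste0("d", 1:8)))
  rs <- vapply(1:10, function(s) {
    y <- rnorm(112); names(y) <- rownames(X)
    sp <- splitOdorants(rownames(X), seed = s)
    mod <- trainORModel(X, y, sp$train, sp$validation, seed = s)
    cor(predict(mod, X[sp$test, ]), y[sp$test])
  }, numeric(1))
  expect_lt(abs(median(rs)), 0.35)
})

test_that("control predictions conserve the response multiset", {
  m1 <- matrix(5, 1, 1, dimnames = list("OR1", "o1"))
  expect_equal(controlPredictions(m1, seed = 1), m1)
  m <- matrix(rnorm(6 * 9), 6, dimnames = list(paste0("OR", 1:6),
                                               paste0("o", 1:9)))
  sh <- controlPredictions(m, seed = 2)
  expect_equal(sort(as.vector(sh)), sort(as.vector(m)))
  expect_identical(sh, controlPredictions(m, seed = 2))
  shr <- controlPredictions(m, seed = 2, per_row = TRUE)
  for (i in 1:6)
    expect_equal(unname(sort(shr[i, ])), unname(sort(m[i, ])))
})

test_that("prediction evaluation reproduces hand-computed R and MAE", {
  act <- matrix(c(1, 2, 3, 4, 0, 1, 0, 2), 2, byrow = TRUE,
                dimnames = list(c("OR1", "OR2"), paste0("o", 1:4)))
  perfect <- evaluatePredictions(act, act, -act)
  expect_equal(perOR(perfect)$r, c(1, 1))
  expect_equal(perOR(perfect)$mae, c(0, 0))
  expect_equal(perOR(perfect, control = TRUE)$r, c(-1, -1))
  pred <- act; pred[1, ] <- c(2, 2, 2, 5)   # |diffs| = 1, 0, 1, 1
  res <- evaluatePredictions(pred, act, -act)
  expect_equal(perOR(res)$mae[1], mean(c(1, 0, 1, 1)))
  # zero-variance actuals: correlation undefined and flagged
  act0 <- act; act0[2, ] <- 7
  res0 <- evaluatePredictions(pred, act0, -act0)
  expect_true(is.na(perOR(res0)$r[2]))
  expect_true(perOR(res0)$degenerate[2])
})

test_that("planted descriptor structure beats the shuffled control", {
  sim <- generateDatabase(syntheticConfig(seed = 31, nOdorants = 60L,
                                          nORs = 10L,
                                          nBehaviorOdorants = 20L))
  m <- responseMatrix(sim$db)
  res <- runDescriptorModel(m, sim$descriptors, seed = 2, maxEpochs = 200)
  expect_gt(median(perOR(res)$r, na.rm = TRUE),
            median(perOR(res, control = TRUE)$r, na.rm = TRUE))
})
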