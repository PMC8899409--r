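## Descriptor-based prediction of per-OR responses: descriptor filtering
## cascade, per-OR feedforward network, shuffled-response control, and
## per-OR correlation / error evaluation.

#' @include conditions.R AllClasses.R
NULL

#' Read an odorant x descriptor matrix
#'
#' CSV with an `odorant_canonical` key column and one numeric column per
#' molecular descriptor; missing entries blank.
#'
#' @param path CSV path.
#' @return numeric matrix with odorants as rownames.
#' @export
readDescriptorMatrix <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"odorant_canonical" %in% names(tab))
    odorStop("odorDB_schema",
             "descriptor file needs an 'odorant_canonical' column")
  if (anyDuplicated(tab$odorant_canonical))
    odorStop("odorDB_schema", "duplicate odorants in descriptor file")
  m <- as.matrix(tab[, setdiff(names(tab), "odorant_canonical"), drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- tab$odorant_canonical
  if (anyDuplicated(colnames(m)))
    odorStop("odorDB_schema", "duplicate descriptor names")
  m
}

#' Filter molecular descriptors: missingness, variance, mutual correlation
#'
#' The cascade drops, in order: descriptors with any missing value;
#' descriptors with variance below `var_min` (computed on the raw,
#' unstandardized values — the threshold is scale-dependent by design);
#' then, scanning the remaining descriptors in their original order,
#' any descriptor whose absolute Pearson correlation with an
#' already-retained descriptor exceeds `corr_max` (greedy keep-first, so
#' the survivor set is reproducible given the input column order). The
#' cascade is idempotent and never increases the descriptor count.
#'
#' @param m odorant x descriptor numeric matrix.
#' @param var_min minimum raw variance (default 0.005).
#' @param corr_max maximum absolute pairwise correlation among survivors
#'   (default 0.95).
#' @return the filtered matrix; attribute `"stages"` records the
#'   descriptor count after each stage.
#' @export
filterDescriptors <- function(m, var_min = 0.005, corr_max = 0.95) {
  if (!is.matrix(m)) m <- as.matrix(m)
  n0 <- ncol(m)
  complete <- colSums(is.na(m)) == 0L
  m1 <- m[, complete, drop = FALSE]
  v <- apply(m1, 2L, stats::var)
  m2 <- m1[, v >= var_min, drop = FALSE]
  keep <- logical(ncol(m2))
  for (j in seq_len(ncol(m2))) {
    if (!any(keep)) { keep[j] <- TRUE; next }
    r <- abs(stats::cor(m2[, j], m2[, keep, drop = FALSE]))
    r[is.na(r)] <- 0
    keep[j] <- all(r <= corr_max)
  }
  out <- m2[, keep, drop = FALSE]
  if (ncol(out) == 0L)
    odorSkip("odorDB_empty_matrix", "no descriptors survive the filter cascade")
  attr(out, "stages") <- c(input = n0, complete = ncol(m1),
                           variance = ncol(m2), correlation = ncol(out))
  out
}

#' Random train / validation / test partition of odorants
#'
#' Sizes are rounded to the nearest integer for the validation and test
#' sets, with the remainder going to the training set, so the three parts
#' are disjoint and exhaustive (112 odorants under the default 70/15/15
#' split give 78/17/17).
#'
#' @param odorants character vector (at least 10).
#' @param fractions train/validation/test fractions summing to 1.
#' @param seed partition seed.
#' @return list with elements `train`, `validation`, `test`.
#' @export
splitOdorants <- function(odorants, fractions = c(0.70, 0.15, 0.15),
                          seed = 1L) {
  if (length(fractions) != 3L || abs(sum(fractions) - 1) > 1e-8)
    odorStop("odorDB_config", "fractions must be three numbers summing to 1")
  n <- length(odorants)
  if (n < 10L)
    odorStop("odorDB_config", "at least 10 odorants are required to split")
  nVal <- round(n * fractions[2])
  nTest <- round(n * fractions[3])
  nTrain <- n - nVal - nTest
  perm <- .withSeed(seed, sample(odorants))
  list(train = perm[seq_len(nTrain)],
       validation = perm[nTrain + seq_len(nVal)],
       test = perm[nTrain + nVal + seq_len(nTest)])
}

#' Train a per-OR response model on molecular descriptors
#'
#' Fits a feedforward neural network (three hidden layers of 50 units by
#' default, tanh activations, linear output) to predict one OR's responses
#' from filtered descriptors. Descriptors and responses are standardized
#' to zero mean / unit SD on the training set; the validation set drives
#' early stopping. Training is deterministic given the seed.
#'
#' @param descriptors odorant x descriptor matrix (already filtered).
#' @param responses named numeric vector of responses (spikes/s), covering
#'   at least the train and validation odorants.
#' @param train,validation character vectors of odorant names.
#' @param arch hidden layer sizes.
#' @param seed initialization seed.
#' @param lr,maxEpochs,patience optimizer settings (full-batch Adam).
#' @return an object of class `"orModel"`; use [predict()] to obtain
#'   predictions for new odorants.
#' @export
trainORModel <- function(descriptors, responses, train, validation,
                         arch = c(50L, 50L, 50L), seed = 1L, lr = 0.01,
                         maxEpochs = 400L, patience = 30L) {
  need <- c(train, validation)
  if (!all(need %in% rownames(descriptors)) || !all(need %in% names(responses)))
    odorStop("odorDB_schema",
             "descriptors/responses missing for some train or validation odorants")
  X <- descriptors[train, , drop = FALSE]
  y <- responses[train]
  if (any(!is.finite(X)) || any(!is.finite(y)))
    odorStop("odorDB_data", "non-finite values in training inputs")
  center <- colMeans(X)
  scale <- apply(X, 2L, stats::sd)
  scale[scale == 0 | !is.finite(scale)] <- 1
  yc <- mean(y); ys <- stats::sd(y)
  if (!is.finite(ys) || ys == 0) ys <- 1
  std <- function(M) sweep(sweep(M, 2L, center), 2L, scale, "/")
  fit <- .mlpTrain(std(X), (y - yc) / ys,
                   std(descriptors[validation, , drop = FALSE]),
                   (responses[validation] - yc) / ys,
                   hidden = arch, lr = lr, maxEpochs = maxEpochs,
                   patience = patience, seed = seed)
  structure(list(net = fit$net, center = center, scale = scale,
                 ycenter = yc, yscale = ys, arch = arch, seed = seed,
                 valMSE = fit$val, bestEpoch = fit$epoch),
            class = "orModel")
}

#' @rdname trainORModel
#' @param object an `"orModel"`.
#' @param newdata odorant x descriptor matrix.
#' @param ... ignored.
#' @export
predict.orModel <- function(object, newdata, ...) {
  X <- sweep(sweep(newdata, 2L, object$center), 2L, object$scale, "/")
  out <- .mlpPredict(object$net, X) * object$yscale + object$ycenter
  names(out) <- rownames(newdata)
  out
}

#' Shuffled-response control predictions
#'
#' Randomly permutes the entries of the OR x odorant response matrix
#' (globally by default, matching a literal shuffle of the whole matrix;
#' set `per_row = TRUE` to permute within each OR) and returns the
#' shuffled matrix, whose entries serve as the control "predictions".
#' The multiset of response values is conserved.
#'
#' @param response_matrix OR x odorant numeric matrix.
#' @param seed shuffle seed.
#' @param per_row permute within rows instead of globally.
#' @return shuffled matrix with the original dimnames.
#' @export
controlPredictions <- function(response_matrix, seed = 1L, per_row = FALSE) {
  m <- response_matrix
  .withSeed(seed, {
    if (per_row) {
      for (i in seq_len(nrow(m))) m[i, ] <- m[i, sample.int(ncol(m))]
    } else {
      m[] <- m[sample.int(length(m))]
    }
  })
  m
}

#' Evaluate per-OR predictions against actual responses
#'
#' Per OR: Pearson correlation between predicted and actual responses on
#' the test odorants, and the mean absolute error. Model and control are
#' compared across ORs with a two-sided paired sign-rank test (on the
#' correlations and on the errors). ORs whose actual test responses have
#' zero variance get an undefined (`NA`) correlation and are flagged.
#'
#' @param predicted,actual,control_predicted OR x test-odorant matrices
#'   with matching dimnames.
#' @param split_seed seed of the partition, recorded in the result.
#' @return a [PredictionResult-class].
#' @export
evaluatePredictions <- function(predicted, actual, control_predicted,
                                split_seed = 1L) {
  if (!identical(dim(predicted), dim(actual)) ||
      !identical(dim(control_predicted), dim(actual)))
    odorStop("odorDB_schema", "prediction and actual matrices must align")
  if (ncol(actual) == 0L)
    odorStop("odorDB_schema", "empty test set")
  perOR <- function(pred) {
    do.call(rbind, lapply(seq_len(nrow(actual)), function(i) {
      a <- actual[i, ]; p <- pred[i, ]
      r <- if (length(a) >= 3L && stats::sd(a) > 0 && stats::sd(p) > 0)
        stats::cor(p, a) else NA_real_
      data.frame(or = rownames(actual)[i], r = r,
                 mae = mean(abs(p - a)), nTest = length(a),
                 degenerate = length(a) < 3L || stats::sd(a) == 0,
                 stringsAsFactors = FALSE)
    }))
  }
  mod <- perOR(predicted)
  ctl <- perOR(control_predicted)
  ok <- !is.na(mod$r) & !is.na(ctl$r)
  pR <- if (any(ok)) signRankTest(mod$r[ok], ctl$r[ok])$p.value else NA_real_
  pM <- signRankTest(mod$mae, ctl$mae)$p.value
  new("PredictionResult", perOR = mod, controlPerOR = ctl,
      comparisonR = pR, comparisonMAE = pM,
      splitSeed = as.integer(split_seed))
}

#' OR x odorant response matrix from a ResponseDB
#'
#' Builds the response matrix used by the descriptor model from the OR
#' records at one concentration decade, averaging duplicate measurements
#' of the same (receptor, odorant) pair.
#'
#' @param db [ResponseDB-class] or standardized record data.frame.
#' @param decade concentration decade (default 1e-2).
#' @param technique which OR technique to use (default empty neuron).
#' @param species optional species filter.
#' @return OR x odorant numeric matrix (NA where unmeasured).
#' @export
responseMatrix <- function(db, decade = 1e-2, technique = "empty_neuron",
                           species = NULL) {
  rec <- .getRecords(db)
  rec <- rec[rec$data_type == "OR" & rec$technique == technique, ,
             drop = FALSE]
  if (!is.null(species)) rec <- rec[rec$species %in% species, , drop = FALSE]
  dec <- concentrationDecade(rec$concentration_value, rec$concentration_unit)
  rec <- rec[!is.na(dec) & dec == round(log10(decade)), , drop = FALSE]
  if (nrow(rec) == 0L)
    odorSkip("odorDB_empty_selection", "no OR records at the requested decade")
  agg <- stats::aggregate(response_value ~ receptor_or_sensillum +
                            odorant_canonical, data = rec, FUN = mean)
  ors <- sort(unique(agg$receptor_or_sensillum))
  ods <- sort(unique(agg$odorant_canonical))
  m <- matrix(NA_real_, length(ors), length(ods), dimnames = list(ors, ods))
  m[cbind(match(agg$receptor_or_sensillum, ors),
          match(agg$odorant_canonical, ods))] <- agg$response_value
  m
}

#' Descriptor-model pipeline: filter, split, train per OR, compare to control
#'
#' Runs the full prediction workflow: descriptor filtering, a seeded
#' train/validation/test partition of the odorants, one network per OR,
#' shuffled-matrix control predictions, and per-OR evaluation.
#'
#' @param response_matrix OR x odorant matrix (as from [responseMatrix()]);
#'   ORs with missing responses on any partition odorant are dropped.
#' @param descriptors odorant x descriptor matrix (unfiltered is fine).
#' @param fractions train/validation/test fractions.
#' @param arch hidden layer sizes.
#' @param seed master seed: drives the partition, the per-OR network
#'   initializations and the control shuffle.
#' @param control_per_row permute the control within rows instead of
#'   globally.
#' @param ... passed to [trainORModel()].
#' @return a [PredictionResult-class].
#' @export
runDescriptorModel <- function(response_matrix, descriptors,
                               fractions = c(0.70, 0.15, 0.15),
                               arch = c(50L, 50L, 50L), seed = 1L,
                               control_per_row = FALSE, ...) {
  odorants <- intersect(colnames(response_matrix), rownames(descriptors))
  m <- response_matrix[, odorants, drop = FALSE]
  keep <- rowSums(is.na(m)) == 0L
  m <- m[keep, , drop = FALSE]
  if (nrow(m) == 0L)
    odorStop("odorDB_data", "no OR has complete responses over the odorants")
  desc <- filterDescriptors(descriptors[odorants, , drop = FALSE])
  split <- splitOdorants(odorants, fractions, seed = seed)
  pred <- matrix(NA_real_, nrow(m), length(split$test),
                 dimnames = list(rownames(m), split$test))
  for (i in seq_len(nrow(m))) {
    fitSeed <- .propertySeed(seed, rownames(m)[i])
    mod <- trainORModel(desc, m[i, ], split$train, split$validation,
                        arch = arch, seed = fitSeed, ...)
    pred[i, ] <- predict(mod, desc[split$test, , drop = FALSE])
  }
  ctl <- controlPredictions(m, seed = .propertySeed(seed, "control"),
                            per_row = control_per_row)
  evaluatePredictions(pred, m[, split$test, drop = FALSE],
                      ctl[, split$test, drop = FALSE], split_seed = seed)
}
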