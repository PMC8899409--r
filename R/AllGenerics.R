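#' @include AllClasses.R
NULL

#' Extract the record table from a ResponseDB
#'
#' @param x a [ResponseDB-class].
#' @return data.frame of standardized records.
#' @export
setGeneric("records", function(x) standardGeneric("records"))

#' @rdname records
#' @export
setMethod("records", "ResponseDB", function(x) x@records)

#' Number of records / pairs / items in a result object
#'
#' @param x an odorDB result object.
#' @return integer count.
#' @export
setGeneric("nObs", function(x) standardGeneric("nObs"))

#' @rdname nObs
#' @export
setMethod("nObs", "ResponseDB", function(x) nrow(x@records))
#' @rdname nObs
#' @export
setMethod("nObs", "TuningFit", function(x) x@n)
#' @rdname nObs
#' @export
setMethod("nObs", "PairedComparison", function(x) x@n)
#' @rdname nObs
#' @export
setMethod("nObs", "CorrelationResult", function(x) x@n)

#' p-value of a result object
#'
#' @param x an odorDB result object carrying a p-value.
#' @return numeric p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "TuningFit", function(x) x@pValue)
#' @rdname pValue
#' @export
setMethod("pValue", "PairedComparison", function(x) x@pValue)
#' @rdname pValue
#' @export
setMethod("pValue", "CorrelationResult", function(x) x@pValue)

#' Mean paired difference of a PairedComparison
#'
#' @param x a [PairedComparison-class].
#' @return numeric mean delta.
#' @export
setGeneric("meanDelta", function(x) standardGeneric("meanDelta"))

#' @rdname meanDelta
#' @export
setMethod("meanDelta", "PairedComparison", function(x) x@meanDelta)

#' Pearson correlation coefficient of a CorrelationResult
#'
#' @param x a [CorrelationResult-class].
#' @return numeric correlation.
#' @export
setGeneric("pearsonR", function(x) standardGeneric("pearsonR"))

#' @rdname pearsonR
#' @export
setMethod("pearsonR", "CorrelationResult", function(x) x@pearsonR)

#' Fitted Gaussian tuning parameters
#'
#' @param x a [TuningFit-class].
#' @return named numeric vector `c(a, b, sigma)`.
#' @export
setGeneric("tuningParams", function(x) standardGeneric("tuningParams"))

#' @rdname tuningParams
#' @export
setMethod("tuningParams", "TuningFit",
          function(x) c(a = x@a, b = x@b, sigma = x@sigma))

#' Matched items of a CorrelationResult
#'
#' @param x a [CorrelationResult-class].
#' @return data.frame of matched items.
#' @export
setGeneric("matchedItems", function(x) standardGeneric("matchedItems"))

#' @rdname matchedItems
#' @export
setMethod("matchedItems", "CorrelationResult", function(x) x@matchedItems)

#' Matched pairs of a PairedComparison
#'
#' @param x a [PairedComparison-class].
#' @return data.frame of matched pairs.
#' @export
setGeneric("pairedValues", function(x) standardGeneric("pairedValues"))

#' @rdname pairedValues
#' @export
setMethod("pairedValues", "PairedComparison", function(x) x@pairs)

#' Per-OR model and control performance of a PredictionResult
#'
#' @param x a [PredictionResult-class].
#' @param control logical; return the shuffled-control table instead.
#' @return data.frame with columns `or`, `r`, `mae`, `nTest`.
#' @export
setGeneric("perOR", function(x, control = FALSE) standardGeneric("perOR"))

#' @rdname perOR
#' @export
setMethod("perOR", "PredictionResult", function(x, control = FALSE) {
  if (control) x@controlPerOR else x@perOR
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "ResponseDB", function(object) {
  rec <- object@records
  cat("ResponseDB with", nrow(rec), "records\n")
  if (nrow(rec)) {
    tab <- table(rec$data_type)
    cat("  data types: ",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n",
        sep = "")
    cat("  species:    ", paste(sort(unique(rec$species)), collapse = ", "),
        "\n", sep = "")
    cat("  odorants:   ", length(unique(rec$odorant_canonical)),
        "  studies: ", length(unique(rec$study_id)), "\n", sep = "")
  }
})

setMethod("show", "TuningFit", function(object) {
  cat(sprintf(
    "TuningFit '%s': n = %d, a = %.3g, b = %.4g, sigma = %.4g, p = %.4g (%d shuffles)\n",
    object@property, object@n, object@a, object@b, object@sigma,
    object@pValue, object@nShuffles))
  if (object@nFailedShuffles > 0L)
    cat("  ", object@nFailedShuffles, "shuffle fit(s) failed to converge\n")
})

setMethod("show", "PredictionResult", function(object) {
  cat("PredictionResult over", nrow(object@perOR), "ORs\n")
  cat(sprintf("  median test R: model %.3f vs control %.3f (sign-rank p = %.3g)\n",
              stats::median(object@perOR$r, na.rm = TRUE),
              stats::median(object@controlPerOR$r, na.rm = TRUE),
              object@comparisonR))
  cat(sprintf("  median MAE:    model %.2f vs control %.2f (sign-rank p = %.3g)\n",
              stats::median(object@perOR$mae, na.rm = TRUE),
              stats::median(object@controlPerOR$mae, na.rm = TRUE),
              object@comparisonMAE))
})

setMethod("show", "TechniqueCrosstab", function(object) {
  cat("TechniqueCrosstab over", object@nPairs, "shared OR-odorant pairs\n")
  cat(sprintf("  empty-neuron nonzero & oocyte zero: %d (%.1f%%)\n",
              object@enNonzeroOoZero,
              100 * object@enNonzeroOoZero / max(1L, object@nPairs)))
  cat(sprintf("  empty-neuron zero & oocyte nonzero: %d (%.1f%%)\n",
              object@enZeroOoNonzero,
              100 * object@enZeroOoNonzero / max(1L, object@nPairs)))
  bk <- object@ooZeroBreakdown
  cat(sprintf("  oocyte-zero breakdown: en>0 %d, en=0 %d, en<0 %d\n",
              bk[["en_positive"]], bk[["en_zero"]], bk[["en_negative"]]))
})

setMethod("show", "PairedComparison", function(object) {
  cat(sprintf("PairedComparison: n = %d, mean delta = %.4g, sign-rank p = %.4g\n",
              object@n, object@meanDelta, object@pValue))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("CorrelationResult: n = %d, R = %.3f, p = %.4g\n",
              object@n, object@pearsonR, object@pValue))
})
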