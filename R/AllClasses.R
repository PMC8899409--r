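#' @import methods
NULL

## ---------------------------------------------------------------------------
## Standardized record schema
## ---------------------------------------------------------------------------

#' Column names of the standardized flat-file record schema
#'
#' One row per response measurement. `data_type` is one of `"OR"`, `"SSR"`,
#' `"EAG"`, `"BEHAVIOR"`; `concentration_unit` is one of `"vv_fraction"`,
#' `"wv_g_per_ml"`, `"dry_amount_g"`; behavioral responses are preference
#' indices in \eqn{[-1, 1]}.
#'
#' @return Character vector of column names.
#' @export
responseSchema <- function() {
  c("data_type", "species", "odorant_canonical", "compound_id",
    "concentration_value", "concentration_unit", "response_value",
    "response_unit", "technique", "receptor_or_sensillum", "assay_category",
    "behavioral_context", "age_days_min", "age_days_max", "sex", "study_id",
    "eag_reference", "background_subtracted")
}

.DATA_TYPES  <- c("OR", "SSR", "EAG", "BEHAVIOR")
.TECHNIQUES  <- c("empty_neuron", "oocyte", "ssr_native", "eag", "behavior")
.CONC_UNITS  <- c("vv_fraction", "wv_g_per_ml", "dry_amount_g")
.ASSAYS      <- c("y_tube", "dual_port", "wind_tunnel", "tip", "landing",
                  "y_maze", "t_maze")
.CONTEXTS    <- c("host_seeking_foraging", "oviposition")

#' ResponseDB: a standardized odorant-response database
#'
#' An S4 container wrapping a data frame of standardized response records
#' (one row per measurement, columns given by [responseSchema()]). The
#' validity method enforces the record invariants: behavioral responses are
#' preference indices in \eqn{[-1, 1]}, assay categories appear only on
#' behavioral records, OR records carry a receptor identifier, every record
#' has a non-empty study identifier, and concentrations are non-negative in
#' a recognized standardized unit.
#'
#' @slot records data.frame of standardized records.
#' @export
setClass("ResponseDB", representation(records = "data.frame"))

setValidity("ResponseDB", function(object) {
  rec <- object@records
  missing_cols <- setdiff(responseSchema(), names(rec))
  if (length(missing_cols))
    return(paste("missing columns:", paste(missing_cols, collapse = ", ")))
  if (nrow(rec) == 0L) return(TRUE)
  msgs <- character()
  if (!all(rec$data_type %in% .DATA_TYPES))
    msgs <- c(msgs, "data_type must be one of OR, SSR, EAG, BEHAVIOR")
  if (!all(rec$technique %in% .TECHNIQUES))
    msgs <- c(msgs, "unrecognized technique")
  if (!all(rec$concentration_unit %in% .CONC_UNITS))
    msgs <- c(msgs, "concentration_unit must be standardized")
  if (any(!is.na(rec$concentration_value) & rec$concentration_value < 0))
    msgs <- c(msgs, "concentration_value must be non-negative")
  beh <- rec$data_type == "BEHAVIOR"
  if (any(beh & (rec$response_value < -1 | rec$response_value > 1), na.rm = TRUE))
    msgs <- c(msgs, "BEHAVIOR response_value must lie in [-1, 1]")
  if (any(!beh & !is.na(rec$assay_category)))
    msgs <- c(msgs, "assay_category present only for BEHAVIOR records")
  if (any(beh & !rec$assay_category %in% c(NA, .ASSAYS)))
    msgs <- c(msgs, "unrecognized assay_category")
  or <- rec$data_type == "OR"
  if (any(or & (is.na(rec$receptor_or_sensillum) |
                !nzchar(rec$receptor_or_sensillum))))
    msgs <- c(msgs, "OR records must name a receptor")
  if (any(is.na(rec$study_id) | !nzchar(rec$study_id)))
    msgs <- c(msgs, "study_id must be non-empty")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

#' Construct a ResponseDB from a data frame of standardized records
#'
#' Missing optional columns are added as `NA`; the validity method then
#' enforces the schema invariants.
#'
#' @param records data.frame with (a subset of) the [responseSchema()]
#'   columns. `data_type`, `species`, `odorant_canonical`,
#'   `concentration_value`, `concentration_unit`, `response_value` and
#'   `study_id` are required.
#' @return A [ResponseDB-class] object.
#' @examples
#' db <- ResponseDB(data.frame(
#'   data_type = "BEHAVIOR", species = "Aaeg",
#'   odorant_canonical = "3-methyl-1-butanol",
#'   concentration_value = 0.01, concentration_unit = "vv_fraction",
#'   response_value = 0.5, response_unit = "pi", technique = "behavior",
#'   assay_category = "y_tube", study_id = "doe2020"))
#' nrow(records(db))
#' @export
ResponseDB <- function(records) {
  records <- as.data.frame(records)
  required <- c("data_type", "species", "odorant_canonical",
                "concentration_value", "concentration_unit",
                "response_value", "study_id")
  miss <- setdiff(required, names(records))
  if (length(miss))
    odorStop("odorDB_schema", paste("required columns absent:",
                                    paste(miss, collapse = ", ")))
  for (col in setdiff(responseSchema(), names(records))) {
    records[[col]] <- if (col %in% c("compound_id", "concentration_value",
                                     "response_value", "age_days_min",
                                     "age_days_max")) NA_real_
    else if (col == "background_subtracted") NA
    else NA_character_
  }
  if (is.null(records$technique) || all(is.na(records$technique))) {
    records$technique <- c(OR = "empty_neuron", SSR = "ssr_native",
                           EAG = "eag", BEHAVIOR = "behavior")[records$data_type]
  }
  records <- records[, responseSchema()]
  rownames(records) <- NULL
  new("ResponseDB", records = records)
}

## ---------------------------------------------------------------------------
## Analysis result classes
## ---------------------------------------------------------------------------

#' TuningFit: Gaussian tuning of OR responses to one physicochemical property
#'
#' Result of fitting \eqn{r = a \exp(-(x - b)^2 / (2\sigma^2))} to
#' (property value, response) pairs and assessing the fitted width
#' \eqn{\sigma} against a shuffle null.
#'
#' @slot property property name.
#' @slot n number of OR-odorant pairs used in the fit.
#' @slot a fitted amplitude (spikes/s).
#' @slot b fitted tuning center (property units).
#' @slot sigma fitted tuning width: the standard deviation of the Gaussian
#'   (property units).
#' @slot pValue fraction of shuffles with \eqn{\sigma_{shuffle} \le
#'   \sigma_{actual}}.
#' @slot nShuffles number of shuffles (p-value resolution is `1/nShuffles`).
#' @slot nFailedShuffles shuffle fits that failed to converge (counted as
#'   \eqn{\sigma_{shuffle} = \infty}).
#' @slot seed integer seed that generated the shuffle stream.
#' @export
setClass("TuningFit", representation(
  property = "character", n = "integer", a = "numeric", b = "numeric",
  sigma = "numeric", pValue = "numeric", nShuffles = "integer",
  nFailedShuffles = "integer", seed = "integer"))

setValidity("TuningFit", function(object) {
  if (length(object@sigma) == 1L && !is.na(object@sigma) && object@sigma <= 0)
    return("sigma must be positive for a successful fit")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  TRUE
})

#' PredictionResult: per-OR descriptor-model performance vs shuffled control
#'
#' @slot perOR data.frame with columns `or`, `r` (Pearson correlation between
#'   predicted and actual responses on test odorants), `mae` (mean absolute
#'   error, spikes/s), `nTest`.
#' @slot controlPerOR same layout for the shuffled-control predictions.
#' @slot comparisonR two-sided paired sign-rank p-value, model vs control
#'   per-OR correlations.
#' @slot comparisonMAE two-sided paired sign-rank p-value, model vs control
#'   per-OR mean absolute errors.
#' @slot splitSeed seed of the train/validation/test partition.
#' @export
setClass("PredictionResult", representation(
  perOR = "data.frame", controlPerOR = "data.frame",
  comparisonR = "numeric", comparisonMAE = "numeric", splitSeed = "integer"))

setValidity("PredictionResult", function(object) {
  if (!identical(object@perOR$or, object@controlPerOR$or))
    return("perOR and controlPerOR must share the same OR set")
  r <- object@perOR$r
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    return("pearson r must lie in [-1, 1]")
  if (any(object@perOR$mae < 0, na.rm = TRUE))
    return("mean absolute error must be non-negative")
  TRUE
})

#' TechniqueCrosstab: empty-neuron vs oocyte response cross-tabulation
#'
#' Counts over shared (receptor, odorant, concentration decade) keys of
#' zero/non-zero response combinations in the two recording techniques,
#' with the breakdown of oocyte-zero pairs by the sign of the empty-neuron
#' response and summary statistics of the negative empty-neuron responses.
#'
#' @slot nPairs shared key count.
#' @slot enNonzeroOoZero pairs with non-zero empty-neuron and zero oocyte
#'   response.
#' @slot enZeroOoNonzero pairs with zero empty-neuron and non-zero oocyte
#'   response.
#' @slot ooZeroBreakdown named counts (`en_positive`, `en_zero`,
#'   `en_negative`) among oocyte-zero pairs.
#' @slot meanSdEnGivenOoZeroNegative mean and SD of empty-neuron responses
#'   among negative-response pairs with zero oocyte response (spikes/s).
#' @slot meanSdEnGivenOoNonzeroNegative same among pairs with non-zero
#'   oocyte response.
#' @slot pairs data.frame of joined pairs for auditability.
#' @export
setClass("TechniqueCrosstab", representation(
  nPairs = "integer", enNonzeroOoZero = "integer", enZeroOoNonzero = "integer",
  ooZeroBreakdown = "integer",
  meanSdEnGivenOoZeroNegative = "numeric",
  meanSdEnGivenOoNonzeroNegative = "numeric",
  pairs = "data.frame"))

setValidity("TechniqueCrosstab", function(object) {
  if (object@enNonzeroOoZero > object@nPairs ||
      object@enZeroOoNonzero > object@nPairs)
    return("cell counts cannot exceed the number of pairs")
  if (sum(object@ooZeroBreakdown) !=
      sum(object@pairs$oocyte == 0, na.rm = TRUE))
    return("oocyte-zero breakdown must sum to the oocyte-zero total")
  TRUE
})

#' PairedComparison: a paired two-sided sign-rank comparison
#'
#' @slot pairs data.frame of matched pairs with annotation columns and the
#'   two compared values `value_a`, `value_b`.
#' @slot n number of pairs.
#' @slot pValue two-sided paired Wilcoxon sign-rank p-value.
#' @slot meanDelta mean of `value_a - value_b` (or of the deltas for
#'   concentration pairs).
#' @export
setClass("PairedComparison", representation(
  pairs = "data.frame", n = "integer", pValue = "numeric",
  meanDelta = "numeric"))

setValidity("PairedComparison", function(object) {
  if (object@n != nrow(object@pairs)) return("n must equal nrow(pairs)")
  if (!is.na(object@pValue) && (object@pValue < 0 || object@pValue > 1))
    return("pValue must lie in [0, 1]")
  TRUE
})

#' CorrelationResult: a matched-item Pearson correlation
#'
#' @slot n number of matched items.
#' @slot pearsonR Pearson correlation coefficient.
#' @slot pValue two-sided p-value of the correlation test.
#' @slot matchedItems data.frame of the matched items (odorant,
#'   concentration decade(s), the two correlated values).
#' @export
setClass("CorrelationResult", representation(
  n = "integer", pearsonR = "numeric", pValue = "numeric",
  matchedItems = "data.frame"))

setValidity("CorrelationResult", function(object) {
  if (object@n != nrow(object@matchedItems))
    return("n must equal nrow(matchedItems)")
  if (!is.na(object@pearsonR) && abs(object@pearsonR) > 1 + 1e-12)
    return("pearsonR must lie in [-1, 1]")
  if (object@n < 3L) return("correlation defined only for n >= 3")
  TRUE
})
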