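## The standardization pipeline: raw heterogeneous report rows -> uniform
## record schema; plus flat-file I/O and the messy-variant emitter used by
## the round-trip validation.

#' @include conditions.R AllClasses.R curation.R synthetic.R
NULL

#' Column names of the raw (pre-standardization) report schema
#'
#' One row per reported measurement before unit/metric standardization.
#' `concentration_unit` is one of `"v/v"`, `"w/v"`, `"M"`, `"ppm"`,
#' `"g/cm2"` (with `area_cm2` and `volume_ml`), `"g_dry"`;
#' `response_metric` is one of `"spikes_s"`, `"nA"`, `"eag_norm"`,
#' `"eag_raw"`, `"preference_index"`, `"percent_attraction"`,
#' `"percent_repellency"`.
#'
#' @return character vector of column names.
#' @export
rawSchema <- function() {
  c("data_type", "species", "odorant_name", "concentration_value",
    "concentration_unit", "area_cm2", "volume_ml", "response_value",
    "response_metric", "technique", "receptor_or_sensillum",
    "assay_category", "behavioral_context", "age_days_min", "age_days_max",
    "sex", "study_id", "eag_reference", "background_subtracted",
    "solvent_response")
}

.RAW_UNIT_MAP <- c("v/v" = "vv_fraction", "w/v" = "wv_g_per_ml",
                   "M" = "molar", "ppm" = "ppm",
                   "g/cm2" = "mass_per_area_with_volume",
                   "g_dry" = "dry_amount_g")

#' Standardize raw report rows into a ResponseDB
#'
#' Applies, row by row: odorant synonym resolution (case- and
#' whitespace-insensitive; unknown names reject the row — never a silent
#' pass-through), concentration conversion to V/V fraction, g/mL or
#' flagged dry amount, preference-metric conversion to the preference
#' index, background subtraction of unsubtracted electrophysiology
#' responses, and per-study EAG normalization to a reference odorant
#' (1-octen-3-ol when present). The returned report lists every conversion
#' applied and every rejected row with its reason.
#'
#' @param raw data.frame in the [rawSchema()] layout.
#' @param synonyms synonym table (see [readSynonymTable()]); also supplies
#'   compound ids and the molecular weights needed for molar conversions.
#' @return list with `db` (a [ResponseDB-class], canonically ordered) and
#'   `report` (counts of rows in/out, conversion tallies, rejected rows).
#' @export
standardizeRecords <- function(raw, synonyms) {
  raw <- as.data.frame(raw)
  miss <- setdiff(rawSchema(), names(raw))
  if (length(miss))
    odorStop("odorDB_schema", paste("raw table missing columns:",
                                    paste(miss, collapse = ", ")))
  n <- nrow(raw)
  out <- .emptyRecord(n)
  keep <- rep(TRUE, n)
  reasons <- character(n)
  convConc <- character(n)
  convMetric <- character(n)

  for (i in seq_len(n)) {
    row <- raw[i, ]
    ok <- tryCatch({
      ident <- canonicalizeOdorant(row$odorant_name, synonyms)
      unit <- .RAW_UNIT_MAP[[as.character(row$concentration_unit)]]
      if (is.null(unit))
        odorStop("odorDB_range", sprintf("unknown concentration unit '%s'",
                                         row$concentration_unit))
      conc <- convertConcentration(
        row$concentration_value, unit,
        molecular_weight = ident$molecular_weight,
        area_cm2 = row$area_cm2, volume_ml = row$volume_ml)
      metric <- as.character(row$response_metric)
      val <- row$response_value
      runit <- switch(metric,
        spikes_s = "spikes_s", nA = "nA",
        eag_norm = , eag_raw = "normalized",
        preference_index = , percent_attraction = ,
        percent_repellency = "pi",
        odorStop("odorDB_range", sprintf("unknown response metric '%s'",
                                         metric)))
      bg <- row$background_subtracted
      eagRef <- row$eag_reference
      if (metric %in% c("percent_attraction", "percent_repellency")) {
        val <- .roundDec(convertPercentMetric(metric, val), 6)
      } else if (metric == "preference_index") {
        if (is.na(val) || abs(val) > 1)
          odorStop("odorDB_range", "preference index outside [-1, 1]")
      } else if (metric == "spikes_s") {
        if (!is.na(bg) && !bg) {
          val <- .roundDec(subtractBackground(val, row$solvent_response, FALSE), 4)
          bg <- TRUE
        }
      } else if (metric == "eag_raw") {
        eagRef <- NA_character_  # normalized below, per study
      }
      out$data_type[i] <- row$data_type
      out$species[i] <- row$species
      out$odorant_canonical[i] <- ident$canonical_name
      out$compound_id[i] <- ident$compound_id
      out$concentration_value[i] <- conc$value
      out$concentration_unit[i] <- conc$unit_kind
      out$response_value[i] <- val
      out$response_unit[i] <- runit
      out$technique[i] <- row$technique
      out$receptor_or_sensillum[i] <- row$receptor_or_sensillum
      out$assay_category[i] <- row$assay_category
      out$behavioral_context[i] <- row$behavioral_context
      out$age_days_min[i] <- row$age_days_min
      out$age_days_max[i] <- row$age_days_max
      out$sex[i] <- row$sex
      out$study_id[i] <- row$study_id
      out$eag_reference[i] <- eagRef
      out$background_subtracted[i] <- bg
      convConc[i] <- unit
      convMetric[i] <- metric
      TRUE
    }, odorDB_error = function(e) {
      reasons[i] <<- conditionMessage(e)
      FALSE
    })
    keep[i] <- ok
  }

  rejected <- data.frame(row = which(!keep),
                         odorant_name = raw$odorant_name[!keep],
                         reason = reasons[!keep], stringsAsFactors = FALSE)
  out <- out[keep, , drop = FALSE]

  ## per-study EAG normalization of not-yet-normalized studies
  eagTodo <- out$data_type == "EAG" & is.na(out$eag_reference)
  for (s in unique(out$study_id[eagTodo])) {
    rows <- out$data_type == "EAG" & out$study_id == s
    out[rows, ] <- normalizeEAG(out[rows, , drop = FALSE])
  }

  out <- out[.canonicalOrder(out), , drop = FALSE]
  rownames(out) <- NULL
  report <- list(
    n_input = n, n_standardized = nrow(out), n_rejected = sum(!keep),
    concentration_conversions = table(convConc[keep]),
    metric_conversions = table(convMetric[keep]),
    rejected = rejected)
  list(db = ResponseDB(out), report = report)
}

#' Write / read standardized records as CSV
#'
#' UTF-8, one header row, `NA` written as empty fields; numeric values are
#' written with enough digits that a written-and-reread database is
#' field-identical.
#'
#' @param db [ResponseDB-class] (or record data.frame) to write.
#' @param path CSV path.
#' @return `writeResponseRecords` returns `path` invisibly;
#'   `readResponseRecords` returns a [ResponseDB-class].
#' @export
writeResponseRecords <- function(db, path) {
  rec <- .getRecords(db)
  # standardized values carry <= 7 significant digits (reporting precision),
  # so the default 15-digit decimal rendering re-reads to identical doubles
  utils::write.csv(rec, path, row.names = FALSE, na = "", fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeResponseRecords
#' @export
readResponseRecords <- function(path) {
  rec <- utils::read.csv(path, stringsAsFactors = FALSE, na.strings = "",
                         fileEncoding = "UTF-8",
                         colClasses = c(
                           compound_id = "numeric",
                           concentration_value = "numeric",
                           response_value = "numeric",
                           age_days_min = "numeric",
                           age_days_max = "numeric",
                           background_subtracted = "logical"))
  ResponseDB(rec)
}

#' Emit a messy "raw" variant of standardized records
#'
#' Re-expresses a standardized database with randomized reporting
#' conventions: odorant synonyms, molar / ppm / mass-per-area
#' concentrations (for W/V records), percent attraction or repellency in
#' place of preference indices, per-study un-normalized EAG responses, and
#' per-study un-subtracted electrophysiology with the solvent response in
#' its own column. Running [standardizeRecords()] on the result recovers
#' the input table field-identically.
#'
#' @param db [ResponseDB-class] or standardized record data.frame.
#' @param synonyms synonym table covering the database's odorants (e.g.
#'   from [generateDatabase()]), used both to pick synonym spellings and
#'   to supply molecular weights for molar re-expression.
#' @param seed seed of the randomized reporting conventions.
#' @return data.frame in the [rawSchema()] layout.
#' @export
generateRawVariants <- function(db, synonyms, seed = 1L) {
  rec <- .getRecords(db)
  .withSeed(seed, .rawVariantImpl(rec, synonyms))
}

.rawVariantImpl <- function(rec, synonyms) {
  n <- nrow(rec)
  raw <- data.frame(
    data_type = rec$data_type, species = rec$species,
    odorant_name = rec$odorant_canonical,
    concentration_value = rec$concentration_value,
    concentration_unit = c(vv_fraction = "v/v", wv_g_per_ml = "w/v",
                           dry_amount_g = "g_dry")[rec$concentration_unit],
    area_cm2 = NA_real_, volume_ml = NA_real_,
    response_value = rec$response_value,
    response_metric = NA_character_,
    technique = rec$technique,
    receptor_or_sensillum = rec$receptor_or_sensillum,
    assay_category = rec$assay_category,
    behavioral_context = rec$behavioral_context,
    age_days_min = rec$age_days_min, age_days_max = rec$age_days_max,
    sex = rec$sex, study_id = rec$study_id,
    eag_reference = rec$eag_reference,
    background_subtracted = rec$background_subtracted,
    solvent_response = NA_real_, stringsAsFactors = FALSE)
  rownames(raw) <- NULL

  ## synonym spellings: canonical, upper-case or alias form
  canon <- rec$odorant_canonical
  variant <- sample(3L, n, replace = TRUE)
  raw$odorant_name <- ifelse(variant == 1L, canon,
                             ifelse(variant == 2L, toupper(canon),
                                    paste0("syn-", canon)))

  ## concentration re-expression for W/V records
  mwOf <- synonyms$molecular_weight[match(.normalizeName(canon),
                                          synonyms$synonym_key)]
  wv <- rec$concentration_unit == "wv_g_per_ml"
  mode <- integer(n)
  mode[wv] <- sample(4L, sum(wv), replace = TRUE)
  sel <- mode == 2L & !is.na(mwOf)     # molar
  raw$concentration_value[sel] <- rec$concentration_value[sel] * 1000 / mwOf[sel]
  raw$concentration_unit[sel] <- "M"
  sel <- mode == 3L                    # ppm
  raw$concentration_value[sel] <- rec$concentration_value[sel] * 1e6
  raw$concentration_unit[sel] <- "ppm"
  sel <- mode == 4L                    # surface density on a 6.6 cm2 cloth
  raw$concentration_value[sel] <- rec$concentration_value[sel] * 0.025 / 6.6
  raw$concentration_unit[sel] <- "g/cm2"
  raw$area_cm2[sel] <- 6.6
  raw$volume_ml[sel] <- 0.025

  ## response metrics
  isBeh <- rec$data_type == "BEHAVIOR"
  isEAG <- rec$data_type == "EAG"
  isSpk <- rec$response_unit == "spikes_s"
  raw$response_metric[isBeh] <- "preference_index"
  raw$response_metric[isEAG] <- "eag_norm"
  raw$response_metric[isSpk] <- "spikes_s"
  raw$response_metric[rec$response_unit == "nA"] <- "nA"

  bvar <- sample(3L, n, replace = TRUE)
  sel <- isBeh & bvar == 2L
  raw$response_value[sel] <- (rec$response_value[sel] + 1) * 50
  raw$response_metric[sel] <- "percent_attraction"
  sel <- isBeh & bvar == 3L
  raw$response_value[sel] <- (1 - rec$response_value[sel]) * 50
  raw$response_metric[sel] <- "percent_repellency"

  ## de-normalize the EAG responses of a random subset of studies
  for (s in unique(rec$study_id[isEAG])) {
    if (stats::runif(1) < 0.5) next
    scale_s <- round(stats::runif(1, 0.5, 4), 3)
    rows <- isEAG & rec$study_id == s
    raw$response_value[rows] <- rec$response_value[rows] * scale_s
    raw$response_metric[rows] <- "eag_raw"
    raw$eag_reference[rows] <- NA_character_
  }

  ## re-add a per-study solvent background to half the spikes/s studies
  for (s in unique(rec$study_id[isSpk])) {
    if (stats::runif(1) < 0.5) next
    bg <- round(stats::runif(1, 5, 30), 2)
    rows <- isSpk & rec$study_id == s
    raw$response_value[rows] <- rec$response_value[rows] + bg
    raw$background_subtracted[rows] <- FALSE
    raw$solvent_response[rows] <- bg
  }
  raw
}
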