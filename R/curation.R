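## Scalar standardization operations: odorant name resolution, preference
## index arithmetic, concentration unit conversion, EAG normalization,
## background subtraction, decade rounding.

#' @include conditions.R
NULL

# Canonical reporting precision of standardized concentrations (significant
# decimal digits). Matches the precision at which converted concentrations
# are stored in the database, e.g. 1.11e-5 M of lactic acid (MW 90.08)
# -> 9.99888e-7 g/mL -> 1e-6 g/mL.
.CONC_SIGNIF <- 3L

# Reporting precision of standardized response values (decimal places):
# spikes/s and nA to 4, dimensionless indices and normalized EAG to 6.
.RESP_DECIMALS <- 4L
.INDEX_DECIMALS <- 6L

# Decimal rounding via text: sprintf and strtod are both correctly rounded,
# so the stored double is exactly the parse of its decimal rendering and a
# written-and-reread database is field-identical (base round()/signif() can
# land one ulp off the nearest double of the decimal).
.roundDec <- function(x, digits) {
  out <- x
  ok <- is.finite(x)
  out[ok] <- as.numeric(sprintf("%.*f", digits, x[ok]))
  out
}

.signifDec <- function(x, digits) {
  out <- x
  ok <- is.finite(x) & x != 0
  out[ok] <- as.numeric(sprintf("%.*e", digits - 1L, x[ok]))
  out
}

.normalizeName <- function(name) {
  name <- tolower(trimws(name))
  gsub("[[:space:]]+", " ", name)
}

#' Read a two-column odorant synonym table
#'
#' The file maps synonym to canonical name, one pair per line, tab- or
#' comma-separated, with a header `synonym<sep>canonical`. Matching is
#' case- and whitespace-insensitive; no fuzzy matching is performed.
#' Optional columns `compound_id` and `molecular_weight` annotate the
#' canonical odorant.
#'
#' @param path path to the mapping file.
#' @return A synonym table: data.frame with columns `synonym_key` (normalized),
#'   `canonical_name`, `compound_id`, `molecular_weight`.
#' @examples
#' tab <- readSynonymTable(system.file("extdata", "synonyms_example.tsv",
#'                                     package = "odorDB"))
#' canonicalizeOdorant("Isopentanol", tab)$canonical_name
#' @export
readSynonymTable <- function(path) {
  sep <- if (grepl("\\.csv$", path)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "\"",
                           comment.char = "")
  if (!all(c("synonym", "canonical") %in% names(tab)))
    odorStop("odorDB_schema", "synonym table needs columns 'synonym' and 'canonical'")
  data.frame(
    synonym_key = .normalizeName(tab$synonym),
    canonical_name = tab$canonical,
    compound_id = if ("compound_id" %in% names(tab))
      as.numeric(tab$compound_id) else NA_real_,
    molecular_weight = if ("molecular_weight" %in% names(tab))
      as.numeric(tab$molecular_weight) else NA_real_,
    stringsAsFactors = FALSE)
}

#' Build a synonym table from vectors
#'
#' @param synonym,canonical character vectors of equal length.
#' @param compound_id,molecular_weight optional annotation of the canonical
#'   odorant (recycled against `synonym`).
#' @return A synonym table as returned by [readSynonymTable()].
#' @export
synonymTable <- function(synonym, canonical, compound_id = NA_real_,
                         molecular_weight = NA_real_) {
  stopifnot(length(synonym) == length(canonical))
  data.frame(
    synonym_key = .normalizeName(synonym),
    canonical_name = canonical,
    compound_id = rep_len(as.numeric(compound_id), length(synonym)),
    molecular_weight = rep_len(as.numeric(molecular_weight), length(synonym)),
    stringsAsFactors = FALSE)
}

#' Resolve an odorant name to its canonical identity
#'
#' Different studies refer to the same compound under different common
#' names (isoamyl alcohol, isopentyl alcohol and isopentanol are all
#' 3-methyl-1-butanol); the database stores a single standard name per
#' odorant. Matching is case- and whitespace-insensitive. Unknown names
#' raise an error of class `odorDB_unmapped_odorant` — silent pass-through
#' would corrupt downstream joins.
#'
#' @param name reported odorant name.
#' @param synonym_table a table from [readSynonymTable()] or
#'   [synonymTable()].
#' @return list with `canonical_name`, `synonyms` (all synonyms mapping to
#'   the identity), `compound_id`, `molecular_weight`.
#' @examples
#' tab <- synonymTable(
#'   c("3-methyl-1-butanol", "isopentanol", "isoamyl alcohol"),
#'   rep("3-methyl-1-butanol", 3), molecular_weight = 88.15)
#' canonicalizeOdorant("Isopentanol ", tab)$canonical_name
#' @export
canonicalizeOdorant <- function(name, synonym_table) {
  key <- .normalizeName(name)
  hit <- match(key, synonym_table$synonym_key)
  if (is.na(hit))
    odorStop("odorDB_unmapped_odorant",
             sprintf("odorant name '%s' is not in the synonym table", name),
             odorant = name)
  canon <- synonym_table$canonical_name[hit]
  rows <- synonym_table$canonical_name == canon
  list(canonical_name = canon,
       synonyms = unique(c(canon, synonym_table$synonym_key[rows])),
       compound_id = synonym_table$compound_id[hit],
       molecular_weight = synonym_table$molecular_weight[hit])
}

#' Preference index of a two-choice assay
#'
#' The number of animals choosing the test odor minus the number choosing
#' the control, divided by their sum: +1 is full attraction, -1 full
#' aversion.
#'
#' @param n_test,n_control non-negative counts.
#' @return preference index in \eqn{[-1, 1]}.
#' @examples
#' computePreferenceIndex(75, 25)  # 0.5
#' @export
computePreferenceIndex <- function(n_test, n_control) {
  if (any(n_test < 0) || any(n_control < 0))
    odorStop("odorDB_range", "counts must be non-negative")
  tot <- n_test + n_control
  if (any(tot == 0))
    odorStop("odorDB_undefined_index",
             "preference index undefined when both counts are zero")
  (n_test - n_control) / tot
}

#' Convert percent attraction / repellency to a preference index
#'
#' Under the two-alternative interpretation, percent attraction \eqn{a}
#' maps to \eqn{2a/100 - 1} (so 75% attraction equals a preference index
#' of 0.5, consistent with 75 of 100 animals choosing the test arm) and
#' percent repellency \eqn{r} maps to \eqn{1 - 2r/100}. Protective-efficacy
#' values are imported through the repellency map by callers, which should
#' flag them as such.
#'
#' @param kind `"percent_attraction"` or `"percent_repellency"`.
#' @param value percentage in \eqn{[0, 100]}.
#' @return preference index in \eqn{[-1, 1]}.
#' @examples
#' convertPercentMetric("percent_attraction", 75)   # 0.5
#' convertPercentMetric("percent_repellency", 100)  # -1
#' @export
convertPercentMetric <- function(kind = c("percent_attraction",
                                          "percent_repellency"), value) {
  kind <- match.arg(kind)
  if (any(value < 0 | value > 100))
    odorStop("odorDB_range", "percent value must lie in [0, 100]")
  if (kind == "percent_attraction") 2 * value / 100 - 1 else 1 - 2 * value / 100
}

#' Standardize a reported concentration
#'
#' Converts the heterogeneous reporting formats to either a dimensionless
#' fraction (V/V or W/V), a W/V concentration in g/mL, or a flagged dry
#' amount in g:
#' \itemize{
#'   \item molarity \eqn{m} (mol/L) \eqn{\to m \times MW / 1000} g/mL
#'     (requires the odorant's molecular weight),
#'   \item ppm \eqn{p} \eqn{\to p} mg/L \eqn{= p \times 10^{-6}} g/mL,
#'   \item surface density \eqn{d} g/cm\eqn{^2} applied over area \eqn{A}
#'     cm\eqn{^2} dissolved in volume \eqn{V} mL \eqn{\to d A / V} g/mL,
#'   \item V/V and W/V fractions pass through,
#'   \item dry amounts (g) pass through flagged `dry_amount_g`; dry
#'     concentrations never compare equal to solution concentrations in
#'     matching operations.
#' }
#' Converted values are rounded to the database's reporting precision of
#' 3 significant digits (so 1.11e-5 M of lactic acid, MW 90.08, gives
#' 1e-6 g/mL).
#'
#' @param value reported numeric value (non-negative).
#' @param unit_kind one of `"vv_fraction"`, `"wv_g_per_ml"`, `"molar"`,
#'   `"ppm"`, `"dry_amount_g"`, `"mass_per_area_with_volume"`.
#' @param molecular_weight g/mol; required for `"molar"`.
#' @param area_cm2,volume_ml auxiliary values, required for
#'   `"mass_per_area_with_volume"`.
#' @param signif_digits reporting precision (significant digits).
#' @return list with `value` (standardized) and `unit_kind` (one of
#'   `"vv_fraction"`, `"wv_g_per_ml"`, `"dry_amount_g"`).
#' @examples
#' convertConcentration(1.11e-5, "molar", molecular_weight = 90.08)
#' convertConcentration(1, "ppm")
#' convertConcentration(1e-6, "mass_per_area_with_volume",
#'                      area_cm2 = 6.6, volume_ml = 0.025)
#' @export
convertConcentration <- function(value,
                                 unit_kind = c("vv_fraction", "wv_g_per_ml",
                                               "molar", "ppm", "dry_amount_g",
                                               "mass_per_area_with_volume"),
                                 molecular_weight = NA_real_,
                                 area_cm2 = NA_real_, volume_ml = NA_real_,
                                 signif_digits = .CONC_SIGNIF) {
  unit_kind <- match.arg(unit_kind)
  if (is.na(value) || value < 0)
    odorStop("odorDB_range", "concentration value must be non-negative")
  out <- switch(unit_kind,
    vv_fraction = list(value = value, unit_kind = "vv_fraction"),
    wv_g_per_ml = list(value = value, unit_kind = "wv_g_per_ml"),
    dry_amount_g = list(value = value, unit_kind = "dry_amount_g"),
    molar = {
      if (is.na(molecular_weight))
        odorStop("odorDB_missing_mw",
                 "molar conversion requires the odorant's molecular weight")
      list(value = value * molecular_weight / 1000, unit_kind = "wv_g_per_ml")
    },
    ppm = list(value = value * 1e-6, unit_kind = "wv_g_per_ml"),
    mass_per_area_with_volume = {
      if (is.na(area_cm2) || is.na(volume_ml))
        odorStop("odorDB_range",
                 "mass-per-area conversion requires area_cm2 and volume_ml")
      if (area_cm2 <= 0 || volume_ml <= 0)
        odorStop("odorDB_range", "area and volume must be positive")
      list(value = value * area_cm2 / volume_ml, unit_kind = "wv_g_per_ml")
    })
  out$value <- .signifDec(out$value, signif_digits)
  out
}

#' Subtract the solvent (background) response from an odor response
#'
#' OR electrophysiology datasets differ in whether the spontaneous /
#' solvent response has already been subtracted. Responses flagged as
#' already subtracted pass through unchanged; otherwise the solvent
#' response is subtracted, and the result may be negative (inhibition).
#'
#' @param odor_response,solvent_response spikes/s.
#' @param already_subtracted logical flag.
#' @return background-subtracted response, spikes/s.
#' @examples
#' subtractBackground(50, 10, FALSE)  # 40
#' subtractBackground(5, 10, FALSE)   # -5 (inhibition)
#' @export
subtractBackground <- function(odor_response, solvent_response,
                               already_subtracted = FALSE) {
  ifelse(already_subtracted, odor_response, odor_response - solvent_response)
}

#' Round a concentration to the nearest power of ten
#'
#' Concentrations are matched across studies on a log10 grid:
#' \eqn{10^{\mathrm{round}(\log_{10} c)}}. Exact half-cases
#' (\eqn{c = x \times 10^{k + 1/2}}) round toward the lower exponent.
#'
#' @param c positive concentration (g/mL or fraction).
#' @return power-of-ten concentration.
#' @examples
#' roundConcentrationDecade(3e-3)  # 1e-3
#' roundConcentrationDecade(9e-3)  # 1e-2
#' @export
roundConcentrationDecade <- function(c) {
  if (any(is.na(c)) || any(c <= 0))
    odorStop("odorDB_range", "concentration must be positive")
  e <- log10(c)
  k <- floor(e + 0.5)
  # half-case: log10(c) exactly k - 0.5 -> lower exponent wins
  half <- (e - floor(e)) == 0.5
  k[half] <- floor(e[half])
  10^k
}

#' The log10 decade of a concentration
#'
#' Integer exponent of [roundConcentrationDecade()]; `NA` for dry amounts,
#' which never match solution concentrations.
#'
#' @param value concentration value.
#' @param unit standardized concentration unit.
#' @return integer decade (e.g. -2 for 0.01).
#' @export
concentrationDecade <- function(value, unit) {
  dec <- rep(NA_real_, length(value))
  sol <- unit %in% c("vv_fraction", "wv_g_per_ml") & !is.na(value) & value > 0
  if (any(sol)) {
    e <- log10(value[sol])
    k <- floor(e + 0.5)
    half <- (e - floor(e)) == 0.5
    k[half] <- floor(e[half])
    dec[sol] <- k
  }
  dec
}

#' Normalize EAG responses to a reference odorant
#'
#' Electroantennogram amplitudes are comparable across studies only after
#' normalization to a reference odorant; 1-octen-3-ol is the default
#' reference when present. Within one study, every non-normalized response
#' is divided by the study's mean response to the reference odorant;
#' records already flagged as normalized are returned unchanged.
#'
#' @param rec data.frame of EAG records for one study (standardized
#'   schema). The `eag_reference` column marks already-normalized records
#'   (non-`NA`).
#' @param reference_odorant canonical name of the reference odorant; if
#'   `NULL`, 1-octen-3-ol is used when present, otherwise an error of class
#'   `odorDB_missing_reference` is raised.
#' @return the records with `response_value` normalized and
#'   `eag_reference` set to the reference odorant.
#' @export
normalizeEAG <- function(rec, reference_odorant = NULL) {
  if (length(unique(rec$study_id)) > 1L)
    odorStop("odorDB_schema", "normalizeEAG expects records from one study")
  todo <- is.na(rec$eag_reference)
  if (!any(todo)) return(rec)  # idempotent on flagged records
  if (is.null(reference_odorant)) {
    cand <- unique(rec$odorant_canonical[todo])
    reference_odorant <- if ("1-octen-3-ol" %in% cand) "1-octen-3-ol"
    else odorSkip("odorDB_missing_reference",
                  "no reference odorant available in unnormalized EAG study")
  }
  ref_rows <- todo & rec$odorant_canonical == reference_odorant
  if (!any(ref_rows))
    odorStop("odorDB_missing_reference",
             sprintf("no record of reference odorant '%s' in study '%s'",
                     reference_odorant, rec$study_id[1]))
  ref <- mean(rec$response_value[ref_rows])
  if (ref == 0)
    odorStop("odorDB_zero_reference",
             "mean reference response is zero; cannot normalize")
  rec$response_value[todo] <- .roundDec(rec$response_value[todo] / ref,
                                        .INDEX_DECIMALS)
  rec$response_unit[todo] <- "normalized"
  rec$eag_reference[todo] <- reference_odorant
  rec
}
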