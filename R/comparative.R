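## Cross-dataset comparisons over the standardized records: technique
## sensitivity cross-tabulation, assay-category pairing, preference vs
## oviposition, cross-species correlation, 10-fold concentration deltas,
## and OR-activation-count vs preference.

#' @include conditions.R AllClasses.R signrank.R
NULL

.withDecade <- function(rec) {
  rec$decade <- concentrationDecade(rec$concentration_value,
                                    rec$concentration_unit)
  rec
}

# Behavior records carrying a usable concentration decade. Oviposition
# records are excluded unless context == "oviposition"; records with an
# unannotated context count as host-seeking/foraging.
.behaviorRecords <- function(rec, context = "host_seeking_foraging") {
  rec <- rec[rec$data_type == "BEHAVIOR", , drop = FALSE]
  ctx <- ifelse(is.na(rec$behavioral_context), "host_seeking_foraging",
                rec$behavioral_context)
  rec <- rec[ctx == context, , drop = FALSE]
  rec <- .withDecade(rec)
  rec[!is.na(rec$decade), , drop = FALSE]
}

.meanBy <- function(df, value, keys) {
  if (nrow(df) == 0L) {
    out <- df[keys]
    out$x <- numeric(0)
    return(out)
  }
  stats::aggregate(df[[value]], df[keys], FUN = mean)
}

#' Cross-tabulate empty-neuron and oocyte OR responses
#'
#' Joins the two techniques' OR records on (receptor, odorant,
#' concentration decade), averaging duplicate measurements within each
#' technique, and counts the zero / non-zero response combinations. "Zero"
#' means a response of exactly 0 after standardization — oocyte
#' non-responses are recorded as literal zeros in source datasets, so no
#' epsilon band is applied. Among pairs with a negative empty-neuron
#' response, the mean and SD of the empty-neuron responses are reported
#' separately for zero and non-zero oocyte responses, to check whether
#' oocyte zeros simply reflect inhibition.
#'
#' @param en [ResponseDB-class] / record data.frame, or the empty-neuron
#'   OR records. When `oo` is `NULL`, `en` is taken as a full database and
#'   split by technique.
#' @param oo oocyte OR records (optional, see above).
#' @return a [TechniqueCrosstab-class].
#' @export
crosstabTechniques <- function(en, oo = NULL) {
  if (is.null(oo)) {
    rec <- .getRecords(en)
    rec <- rec[rec$data_type == "OR", , drop = FALSE]
    en <- rec[rec$technique == "empty_neuron", , drop = FALSE]
    oo <- rec[rec$technique == "oocyte", , drop = FALSE]
  } else {
    en <- .getRecords(en)
    oo <- .getRecords(oo)
  }
  keys <- c("receptor_or_sensillum", "odorant_canonical", "decade")
  enA <- .meanBy(.withDecade(en), "response_value", keys)
  ooA <- .meanBy(.withDecade(oo), "response_value", keys)
  names(enA)[names(enA) == "x"] <- "empty_neuron"
  names(ooA)[names(ooA) == "x"] <- "oocyte"
  pairs <- merge(enA, ooA, by = keys)
  pairs <- pairs[order(pairs$receptor_or_sensillum, pairs$odorant_canonical,
                       pairs$decade), , drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L)
    odorSkip("odorDB_empty_join",
             "no shared (receptor, odorant, decade) keys between techniques")
  enV <- pairs$empty_neuron; ooV <- pairs$oocyte
  ooZero <- ooV == 0
  breakdown <- c(en_positive = sum(ooZero & enV > 0),
                 en_zero = sum(ooZero & enV == 0),
                 en_negative = sum(ooZero & enV < 0))
  msd <- function(v) if (length(v)) c(mean = mean(v), sd = stats::sd(v))
  else c(mean = NA_real_, sd = NA_real_)
  new("TechniqueCrosstab",
      nPairs = nrow(pairs),
      enNonzeroOoZero = sum(enV != 0 & ooZero),
      enZeroOoNonzero = sum(enV == 0 & !ooZero),
      ooZeroBreakdown = as.integer(breakdown) |>
        stats::setNames(names(breakdown)),
      meanSdEnGivenOoZeroNegative = msd(enV[enV < 0 & ooZero]),
      meanSdEnGivenOoNonzeroNegative = msd(enV[enV < 0 & !ooZero]),
      pairs = pairs)
}

#' Built-in assay-category splits
#'
#' Mosquitoes: landing (arm-in-cage) assays vs dual-port and Y-tube choice
#' assays. Flies: T-maze vs dual-port and Y-maze.
#'
#' @return named list of `list(a = ..., b = ...)` category sets.
#' @export
assayCategoryPresets <- function() {
  list(mosquito = list(a = "landing", b = c("dual_port", "y_tube")),
       fly = list(a = "t_maze", b = c("dual_port", "y_maze")))
}

#' Compare preference indices between two assay-category sets
#'
#' For every (odorant, concentration decade, species) measured in both
#' category sets, the data points within each set are averaged into a
#' single value and one pair is emitted; pairs from all species are pooled
#' after the per-species pairing. The paired differences
#' `value_a - value_b` are tested against zero with a two-sided sign-rank
#' test.
#'
#' @param db [ResponseDB-class] or record data.frame.
#' @param split_a,split_b character vectors of assay categories (see
#'   [assayCategoryPresets()]).
#' @param species optional species filter.
#' @return a [PairedComparison-class]; `value_a` is the `split_a` average.
#' @export
pairByAssayCategory <- function(db, split_a, split_b, species = NULL) {
  rec <- .behaviorRecords(.getRecords(db))
  if (!is.null(species)) rec <- rec[rec$species %in% species, , drop = FALSE]
  rec <- rec[!is.na(rec$assay_category), , drop = FALSE]
  keys <- c("odorant_canonical", "decade", "species")
  a <- .meanBy(rec[rec$assay_category %in% split_a, , drop = FALSE],
               "response_value", keys)
  b <- .meanBy(rec[rec$assay_category %in% split_b, , drop = FALSE],
               "response_value", keys)
  names(a)[names(a) == "x"] <- "value_a"
  names(b)[names(b) == "x"] <- "value_b"
  pairs <- merge(a, b, by = keys)
  pairs <- pairs[order(pairs$species, pairs$odorant_canonical, pairs$decade), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  if (nrow(pairs) == 0L)
    odorSkip("odorDB_empty_comparison",
             "no (odorant, decade, species) measured in both category sets")
  delta <- pairs$value_a - pairs$value_b
  new("PairedComparison", pairs = pairs, n = nrow(pairs),
      pValue = signRankTest(delta)$p.value, meanDelta = mean(delta))
}

#' Correlate host-seeking/foraging preference with oviposition preference
#'
#' Matches, within one species, the preference index and the oviposition
#' index per (odorant, concentration decade); both indices must have been
#' measured at the same decade. Duplicates within a context are averaged.
#' Species with fewer than 5 matched items are skipped with a condition of
#' class `odorDB_species_skipped`.
#'
#' @param db [ResponseDB-class] or record data.frame.
#' @param species species code to analyze.
#' @return a [CorrelationResult-class].
#' @export
correlatePiOviposition <- function(db, species) {
  rec <- .getRecords(db)
  rec <- rec[rec$species == species, , drop = FALSE]
  pref <- .behaviorRecords(rec, "host_seeking_foraging")
  ovi <- .behaviorRecords(rec, "oviposition")
  keys <- c("odorant_canonical", "decade")
  p <- .meanBy(pref, "response_value", keys)
  o <- .meanBy(ovi, "response_value", keys)
  names(p)[names(p) == "x"] <- "preference_index"
  names(o)[names(o) == "x"] <- "oviposition_index"
  items <- merge(p, o, by = keys)
  items <- items[order(items$odorant_canonical, items$decade), , drop = FALSE]
  rownames(items) <- NULL
  if (nrow(items) < 5L)
    odorSkip("odorDB_species_skipped",
             sprintf("species '%s' has %d matched items (< 5); not analyzed",
                     species, nrow(items)))
  ct <- stats::cor.test(items$preference_index, items$oviposition_index,
                        method = "pearson")
  new("CorrelationResult", n = nrow(items),
      pearsonR = unname(ct$estimate), pValue = ct$p.value,
      matchedItems = items)
}

#' Correlate preference indices between two species
#'
#' For each odorant tested in both species, preference indices (duplicates
#' averaged per decade) are matched at the same concentration decade when
#' available; otherwise at the nearest decade within 10-fold (one decade).
#' When two decades are equally near, the lower decade wins. The pair of
#' species is skipped (condition class `odorDB_pair_skipped`) when fewer
#' than 10 common odorants can be matched.
#'
#' @param db [ResponseDB-class] or record data.frame.
#' @param species_a,species_b species codes.
#' @param min_common minimum number of matched odorants (default 10).
#' @return a [CorrelationResult-class].
#' @export
crossSpeciesCorrelation <- function(db, species_a, species_b,
                                    min_common = 10L) {
  rec <- .behaviorRecords(.getRecords(db))
  keys <- c("odorant_canonical", "decade")
  a <- .meanBy(rec[rec$species == species_a, , drop = FALSE],
               "response_value", keys)
  b <- .meanBy(rec[rec$species == species_b, , drop = FALSE],
               "response_value", keys)
  matchOdor <- function(da, db_) {
    common <- intersect(da, db_)
    if (length(common)) return(c(min(common), min(common)))
    cand <- expand.grid(da = da, db = db_)
    cand <- cand[abs(cand$da - cand$db) == 1, , drop = FALSE]
    if (!nrow(cand)) return(NULL)
    # lower decade wins on the a side, then on the b side
    cand <- cand[order(cand$da, cand$db), , drop = FALSE]
    c(cand$da[1], cand$db[1])
  }
  items <- NULL
  for (od in intersect(a$odorant_canonical, b$odorant_canonical)) {
    da <- a$decade[a$odorant_canonical == od]
    db_ <- b$decade[b$odorant_canonical == od]
    m <- matchOdor(da, db_)
    if (is.null(m)) next
    items <- rbind(items, data.frame(
      odorant_canonical = od, decade_a = m[1], decade_b = m[2],
      pi_a = a$x[a$odorant_canonical == od & a$decade == m[1]],
      pi_b = b$x[b$odorant_canonical == od & b$decade == m[2]],
      stringsAsFactors = FALSE))
  }
  if (is.null(items) || nrow(items) < min_common)
    odorSkip("odorDB_pair_skipped",
             sprintf("species pair (%s, %s): %d common odorants (< %d)",
                     species_a, species_b,
                     if (is.null(items)) 0L else nrow(items), min_common))
  items <- items[order(items$odorant_canonical), , drop = FALSE]
  rownames(items) <- NULL
  ct <- stats::cor.test(items$pi_a, items$pi_b, method = "pearson")
  new("CorrelationResult", n = nrow(items),
      pearsonR = unname(ct$estimate), pValue = ct$p.value,
      matchedItems = items)
}

#' Preference-index change across 10-fold concentration steps
#'
#' An (odorant, assay category, species, decade) cell is eligible when at
#' least `min_points` data points are available; they are averaged into a
#' single value. For every eligible pair of adjacent decades the delta
#' `PI(higher decade) - PI(lower decade)` is emitted and tested against
#' zero with a two-sided sign-rank test. `sign_filter` restricts the pairs
#' by the sign of the lower-decade preference index (for the sub-analyses
#' of initially-aversive and initially-attractive odors).
#'
#' @param db [ResponseDB-class] or record data.frame.
#' @param sign_filter `"all"`, `"negative"` or `"positive"`.
#' @param min_points minimum data points per cell (default 2).
#' @return a [PairedComparison-class] whose `pairs` carry
#'   `pi_low`, `pi_high` and `delta`; `meanDelta` is the mean delta.
#' @export
concentrationPairDeltas <- function(db, sign_filter = c("all", "negative",
                                                        "positive"),
                                    min_points = 2L) {
  sign_filter <- match.arg(sign_filter)
  rec <- .behaviorRecords(.getRecords(db))
  rec <- rec[!is.na(rec$assay_category), , drop = FALSE]
  keys <- c("odorant_canonical", "assay_category", "species", "decade")
  if (nrow(rec)) {
    cnt <- stats::aggregate(rec$response_value, rec[keys], FUN = length)
    avg <- stats::aggregate(rec$response_value, rec[keys], FUN = mean)
    cells <- avg[cnt$x >= min_points, , drop = FALSE]
  } else cells <- NULL
  pairs <- NULL
  if (!is.null(cells) && nrow(cells)) {
    grp <- interaction(cells$odorant_canonical, cells$assay_category,
                       cells$species, drop = TRUE)
    for (g in levels(grp)) {
      sub <- cells[grp == g, , drop = FALSE]
      sub <- sub[order(sub$decade), , drop = FALSE]
      for (i in seq_len(nrow(sub) - 1L)) {
        if (sub$decade[i + 1L] - sub$decade[i] != 1) next
        pairs <- rbind(pairs, data.frame(
          odorant_canonical = sub$odorant_canonical[i],
          assay_category = sub$assay_category[i],
          species = sub$species[i],
          decade_low = sub$decade[i], decade_high = sub$decade[i + 1L],
          pi_low = sub$x[i], pi_high = sub$x[i + 1L],
          delta = sub$x[i + 1L] - sub$x[i],
          stringsAsFactors = FALSE))
      }
    }
  }
  if (!is.null(pairs)) {
    pairs <- switch(sign_filter,
      all = pairs,
      negative = pairs[pairs$pi_low < 0, , drop = FALSE],
      positive = pairs[pairs$pi_low > 0, , drop = FALSE])
  }
  if (is.null(pairs) || nrow(pairs) == 0L)
    odorSkip("odorDB_empty_comparison", "no eligible 10-fold concentration pairs")
  pairs <- pairs[order(pairs$species, pairs$assay_category,
                       pairs$odorant_canonical, pairs$decade_low), ,
                 drop = FALSE]
  rownames(pairs) <- NULL
  new("PairedComparison", pairs = pairs, n = nrow(pairs),
      pValue = signRankTest(pairs$delta)$p.value,
      meanDelta = mean(pairs$delta))
}

#' Correlate the number of activated ORs with the preference index
#'
#' For each (odorant, concentration decade) the number of ORs whose
#' response is at least `threshold` spikes/s ("activated") is counted from
#' the OR records and correlated (Pearson) against the averaged preference
#' index of the same odorant at the same decade.
#'
#' @param db [ResponseDB-class] or record data.frame.
#' @param threshold activation threshold in spikes/s (default 10; a
#'   response of exactly 10 counts as activated).
#' @param technique OR technique to count from.
#' @param species_or,species_behavior optional species filters for the two
#'   sides of the join.
#' @return a [CorrelationResult-class]; matched items carry
#'   `n_activated` and `preference_index`.
#' @export
orActivationVsPi <- function(db, threshold = 10, technique = "empty_neuron",
                             species_or = NULL, species_behavior = NULL) {
  rec <- .getRecords(db)
  orr <- rec[rec$data_type == "OR" & rec$technique == technique, ,
             drop = FALSE]
  if (!is.null(species_or))
    orr <- orr[orr$species %in% species_or, , drop = FALSE]
  orr <- .withDecade(orr)
  orr <- orr[!is.na(orr$decade), , drop = FALSE]
  keys <- c("odorant_canonical", "decade")
  perRec <- .meanBy(orr, "response_value",
                    c("receptor_or_sensillum", keys))
  perRec$activated <- as.integer(perRec$x >= threshold)
  act <- stats::aggregate(perRec$activated, perRec[keys], FUN = sum)
  names(act)[names(act) == "x"] <- "n_activated"
  beh <- .behaviorRecords(rec)
  if (!is.null(species_behavior))
    beh <- beh[beh$species %in% species_behavior, , drop = FALSE]
  pi <- .meanBy(beh, "response_value", keys)
  names(pi)[names(pi) == "x"] <- "preference_index"
  items <- merge(act, pi, by = keys)
  items <- items[order(items$odorant_canonical, items$decade), , drop = FALSE]
  rownames(items) <- NULL
  if (nrow(items) < 3L)
    odorSkip("odorDB_undefined_correlation",
             "fewer than 3 odorants with both an activation count and a PI")
  ct <- stats::cor.test(items$n_activated, items$preference_index,
                        method = "pearson")
  new("CorrelationResult", n = nrow(items),
      pearsonR = unname(ct$estimate), pValue = ct$p.value,
      matchedItems = items)
}
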