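## Seeded generator of a synthetic odorant-response database with planted,
## recoverable effects: Gaussian property tuning of OR responses, a
## less-sensitive thresholded oocyte technique, assay-dependent preference
## offsets, a preference decline with log concentration, and a negative
## loading of preference on the number of activated ORs. Every analysis
## stage of the package can be validated closed-loop against the planted
## parameters without any external data.

#' @include conditions.R AllClasses.R curation.R
NULL

#' SyntheticConfig: planted-effect parameters of the synthetic database
#'
#' @slot seed master seed; identical seeds give identical databases.
#' @slot nOdorants,nORs,nSpecies,nStudies problem sizes.
#' @slot propertySpec data.frame (`name`, `mean`, `sd`) of Gaussian
#'   physicochemical property distributions.
#' @slot tuningProperty property that drives OR responses.
#' @slot tuningCenter,tuningWidth,tuningAmplitude planted Gaussian tuning
#'   \eqn{b^*}, \eqn{\sigma^*} (property units) and \eqn{a^*} (spikes/s).
#' @slot responseNoiseSD additive response noise SD (spikes/s).
#' @slot inhibFraction,inhibMax fraction of OR-odorant pairs receiving a
#'   negative (inhibitory) uniform offset, and its maximum size.
#' @slot oocyteThreshold,oocyteGain sensitivity threshold \eqn{\theta}
#'   (spikes/s) and gain (nA per spikes/s) of the oocyte technique:
#'   oocyte = gain * max(0, empty_neuron - theta).
#' @slot assayOffsets named numeric, preference offset \eqn{\delta} per
#'   assay category (PI units).
#' @slot concentrationSlope \eqn{\beta}: PI decline per 10-fold
#'   concentration increase.
#' @slot piNoiseSD behavioral noise SD (PI units).
#' @slot orCountLoading \eqn{\gamma}: PI units subtracted per activated OR.
#' @slot ovipositionMode `"independent"` or `"coupled"`.
#' @slot ovipositionRho coupling of oviposition to preference when
#'   `"coupled"`.
#' @slot missingPropertyRate fraction of property-table entries masked as
#'   missing.
#' @slot nBehaviorOdorants odorants with behavioral data.
#' @slot behaviorDecades integer log10 decades at which behavior is
#'   measured.
#' @slot referenceDecade decade at which the planted concentration effect
#'   is zero.
#' @slot nRepBehavior replicate behavioral data points (distinct studies)
#'   per (species, odorant, assay, decade) cell.
#' @export
setClass("SyntheticConfig", representation(
  seed = "integer", nOdorants = "integer", nORs = "integer",
  nSpecies = "integer", nStudies = "integer", propertySpec = "data.frame",
  tuningProperty = "character", tuningCenter = "numeric",
  tuningWidth = "numeric", tuningAmplitude = "numeric",
  responseNoiseSD = "numeric", inhibFraction = "numeric",
  inhibMax = "numeric", oocyteThreshold = "numeric", oocyteGain = "numeric",
  assayOffsets = "numeric", concentrationSlope = "numeric",
  piNoiseSD = "numeric", orCountLoading = "numeric",
  ovipositionMode = "character", ovipositionRho = "numeric",
  missingPropertyRate = "numeric", nBehaviorOdorants = "integer",
  behaviorDecades = "numeric", referenceDecade = "numeric",
  nRepBehavior = "integer"))

setValidity("SyntheticConfig", function(object) {
  msgs <- character()
  if (object@responseNoiseSD < 0 || object@piNoiseSD < 0)
    msgs <- c(msgs, "noise SDs must be non-negative")
  if (object@oocyteThreshold < 0) msgs <- c(msgs, "oocyteThreshold must be >= 0")
  if (object@tuningWidth <= 0) msgs <- c(msgs, "tuningWidth must be positive")
  if (object@inhibFraction < 0 || object@inhibFraction > 1 ||
      object@missingPropertyRate < 0 || object@missingPropertyRate > 1)
    msgs <- c(msgs, "fractions must lie in [0, 1]")
  if (!object@ovipositionMode %in% c("independent", "coupled"))
    msgs <- c(msgs, "ovipositionMode must be 'independent' or 'coupled'")
  if (object@nSpecies < 1L || object@nSpecies > 4L)
    msgs <- c(msgs, "nSpecies must be between 1 and 4")
  if (object@nBehaviorOdorants > object@nOdorants)
    msgs <- c(msgs, "nBehaviorOdorants cannot exceed nOdorants")
  if (!object@tuningProperty %in% object@propertySpec$name)
    msgs <- c(msgs, "tuningProperty must appear in propertySpec")
  if (length(msgs)) paste(msgs, collapse = "; ") else TRUE
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig: seed", object@seed, "\n")
  cat(sprintf("  %d odorants, %d ORs, %d species, %d behavior odorants\n",
              object@nOdorants, object@nORs, object@nSpecies,
              object@nBehaviorOdorants))
  cat(sprintf("  tuning %s: a* = %g, b* = %g, sigma* = %g, noise SD %g\n",
              object@tuningProperty, object@tuningAmplitude,
              object@tuningCenter, object@tuningWidth,
              object@responseNoiseSD))
  cat(sprintf("  oocyte theta = %g, beta = %g, gamma = %g\n",
              object@oocyteThreshold, object@concentrationSlope,
              object@orCountLoading))
})

#' Construct a SyntheticConfig
#'
#' Defaults describe the standard study conditions used throughout the
#' package's validation suite: 200 odorants, 30 ORs tuned to molecular
#' volume (center 100, width 30 in property units, amplitude 100 spikes/s,
#' noise SD 10 = 0.1 amplitude), an oocyte threshold of 15 spikes/s, a
#' landing/T-maze assay offset of -0.3 PI units, a preference decline of
#' 0.2 PI per 10-fold concentration increase, and a loading of -0.01 PI
#' per activated OR.
#'
#' @param seed master seed.
#' @param nOdorants,nORs,nSpecies,nStudies problem sizes.
#' @param propertySpec per-property Gaussian distribution table.
#' @param tuningProperty,tuningCenter,tuningWidth,tuningAmplitude,responseNoiseSD
#'   planted tuning parameters.
#' @param inhibFraction,inhibMax inhibitory-offset model.
#' @param oocyteThreshold,oocyteGain oocyte sensitivity model.
#' @param assayOffsets named preference offsets per assay category.
#' @param concentrationSlope,piNoiseSD,orCountLoading behavioral model.
#' @param ovipositionMode,ovipositionRho oviposition model.
#' @param missingPropertyRate property-table missingness.
#' @param nBehaviorOdorants,behaviorDecades,referenceDecade,nRepBehavior
#'   behavioral design.
#' @return a validated [SyntheticConfig-class].
#' @export
syntheticConfig <- function(seed = 1L, nOdorants = 200L, nORs = 30L,
                            nSpecies = 3L, nStudies = 20L,
                            propertySpec = data.frame(
                              name = c("molecular_volume", "log_p",
                                       "polar_surface_area", "complexity"),
                              mean = c(100, 2, 40, 150),
                              sd = c(40, 1.5, 20, 80),
                              stringsAsFactors = FALSE),
                            tuningProperty = "molecular_volume",
                            tuningCenter = 100, tuningWidth = 30,
                            tuningAmplitude = 100, responseNoiseSD = 10,
                            inhibFraction = 0.2, inhibMax = 20,
                            oocyteThreshold = 15, oocyteGain = 1,
                            assayOffsets = c(landing = -0.3, t_maze = -0.3,
                                             y_tube = 0, dual_port = 0,
                                             y_maze = 0),
                            concentrationSlope = 0.2, piNoiseSD = 0.05,
                            orCountLoading = 0.01,
                            ovipositionMode = "independent",
                            ovipositionRho = 0.5,
                            missingPropertyRate = 0.05,
                            nBehaviorOdorants = 60L,
                            behaviorDecades = c(-4, -3, -2, -1),
                            referenceDecade = -3, nRepBehavior = 2L) {
  new("SyntheticConfig", seed = as.integer(seed),
      nOdorants = as.integer(nOdorants), nORs = as.integer(nORs),
      nSpecies = as.integer(nSpecies), nStudies = as.integer(nStudies),
      propertySpec = propertySpec, tuningProperty = tuningProperty,
      tuningCenter = tuningCenter, tuningWidth = tuningWidth,
      tuningAmplitude = tuningAmplitude, responseNoiseSD = responseNoiseSD,
      inhibFraction = inhibFraction, inhibMax = inhibMax,
      oocyteThreshold = oocyteThreshold, oocyteGain = oocyteGain,
      assayOffsets = assayOffsets, concentrationSlope = concentrationSlope,
      piNoiseSD = piNoiseSD, orCountLoading = orCountLoading,
      ovipositionMode = ovipositionMode, ovipositionRho = ovipositionRho,
      missingPropertyRate = missingPropertyRate,
      nBehaviorOdorants = as.integer(nBehaviorOdorants),
      behaviorDecades = behaviorDecades, referenceDecade = referenceDecade,
      nRepBehavior = as.integer(nRepBehavior))
}

.clip <- function(x, lo = -1, hi = 1) pmin(hi, pmax(lo, x))

.speciesPool <- c("Aaeg", "Cqui", "Dmel", "Agam")

.assaysFor <- function(species) {
  if (species == "Dmel") c("t_maze", "dual_port", "y_maze")
  else c("y_tube", "dual_port", "landing")
}

.emptyRecord <- function(n) {
  data.frame(data_type = character(n), species = character(n),
             odorant_canonical = character(n), compound_id = numeric(n),
             concentration_value = numeric(n),
             concentration_unit = character(n), response_value = numeric(n),
             response_unit = character(n), technique = character(n),
             receptor_or_sensillum = NA_character_,
             assay_category = NA_character_,
             behavioral_context = NA_character_,
             age_days_min = NA_real_, age_days_max = NA_real_,
             sex = NA_character_, study_id = character(n),
             eag_reference = NA_character_, background_subtracted = NA,
             stringsAsFactors = FALSE)
}

# Total deterministic ordering of records; the standardization round-trip
# compares tables after applying this ordering on both sides.
.canonicalOrder <- function(rec) {
  order(rec$data_type, rec$technique, rec$species, rec$study_id,
        ifelse(is.na(rec$receptor_or_sensillum), "",
               rec$receptor_or_sensillum),
        rec$odorant_canonical,
        ifelse(is.na(rec$assay_category), "", rec$assay_category),
        ifelse(is.na(rec$behavioral_context), "", rec$behavioral_context),
        rec$concentration_unit, rec$concentration_value)
}

#' Generate a synthetic odorant-response database with planted effects
#'
#' Produces standardized records of all four data types (OR empty-neuron
#' and oocyte, SSR, EAG, behavior), a physicochemical property table, a
#' descriptor matrix for the prediction model (the tuning-relevant
#' property, near-duplicate and correlated nuisance descriptors that
#' exercise the filter cascade, pure-noise descriptors, a constant column
#' and a column with missing entries), and a `truth` record holding every
#' planted parameter. Identical configurations give identical databases.
#'
#' The planted structure is: empty-neuron response
#' \eqn{= a^* \exp(-(x - b^*)^2 / (2\sigma^{*2}))} + noise, with a
#' negative uniform offset on a configured fraction of OR-odorant pairs;
#' oocyte response \eqn{= gain \cdot \max(0, en - \theta)}; preference
#' index \eqn{= base(odor) - \beta (d - d_{ref}) + \delta(assay) -
#' \gamma \cdot n_{activated}(odor)} + noise, clipped to \eqn{[-1, 1]};
#' oviposition indices drawn independently or coupled to the preference
#' base.
#'
#' @param cfg a [SyntheticConfig-class].
#' @return list with elements `db` ([ResponseDB-class]), `properties`
#'   (data.frame), `descriptors` (matrix), `odorants` (identity table:
#'   canonical name, compound id, molecular weight), `synonyms` (synonym
#'   table usable with [canonicalizeOdorant()]), and `truth`.
#' @examples
#' sim <- generateDatabase(syntheticConfig(seed = 7, nOdorants = 40L,
#'                                         nORs = 5L, nBehaviorOdorants = 20L))
#' sim$db
#' @export
generateDatabase <- function(cfg) {
  stopifnot(methods::is(cfg, "SyntheticConfig"))
  methods::validObject(cfg)
  .withSeed(cfg@seed, .generateDatabaseImpl(cfg))
}

.generateDatabaseImpl <- function(cfg) {
  nOd <- cfg@nOdorants
  odorants <- sprintf("odorant-%03d", seq_len(nOd))
  allOd <- c(odorants, "1-octen-3-ol")
  mw <- c(round(stats::runif(nOd, 60, 200), 2), 128.21)
  cid <- c(10000 + seq_len(nOd), 911)
  odorTab <- data.frame(odorant_canonical = allOd, compound_id = cid,
                        molecular_weight = mw, stringsAsFactors = FALSE)

  ## properties (true values; the reported table gets missingness applied)
  propTrue <- data.frame(odorant_canonical = allOd, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cfg@propertySpec))) {
    propTrue[[cfg@propertySpec$name[i]]] <-
      round(stats::rnorm(nOd + 1L, cfg@propertySpec$mean[i],
                         cfg@propertySpec$sd[i]), 3)
  }
  propTrue$molecular_weight <- mw
  properties <- propTrue
  propCols <- setdiff(names(properties), "odorant_canonical")
  if (cfg@missingPropertyRate > 0) {
    for (p in propCols) {
      mask <- stats::runif(nOd + 1L) < cfg@missingPropertyRate
      properties[[p]][mask] <- NA_real_
    }
  }
  x <- propTrue[[cfg@tuningProperty]][seq_len(nOd)]  # tuning driver

  ## descriptors (for the prediction model)
  nNoise <- 15L
  desc <- matrix(stats::rnorm(nOd * nNoise), nrow = nOd)
  colnames(desc) <- sprintf("noise_%02d", seq_len(nNoise))
  near_dup <- x + stats::rnorm(nOd, 0, 0.02 * stats::sd(x))
  correlated <- 0.8 * scale(x)[, 1] + 0.6 * stats::rnorm(nOd)
  withNA <- stats::rnorm(nOd)
  withNA[stats::runif(nOd) < 0.1] <- NA_real_
  # real descriptor collections contain nonlinear transforms of shared
  # structural factors; the squared deviation makes the bell-shaped planted
  # signal reachable by regression models (the raw property has ~zero
  # linear correlation with a symmetric tuning curve)
  sq_dev <- round((x - mean(x))^2, 3)
  desc <- cbind(
    tuning_descriptor = x, tuning_squared_deviation = sq_dev,
    tuning_near_duplicate = near_dup,
    tuning_correlate = correlated,
    log_p = propTrue$log_p[seq_len(nOd)],
    polar_surface_area = propTrue$polar_surface_area[seq_len(nOd)],
    complexity = propTrue$complexity[seq_len(nOd)],
    constant_descriptor = rep(1, nOd), missing_descriptor = withNA, desc)
  rownames(desc) <- odorants

  ## OR responses (empty neuron), planted Gaussian tuning + inhibition
  g <- cfg@tuningAmplitude *
    exp(-(x - cfg@tuningCenter)^2 / (2 * cfg@tuningWidth^2))
  en <- matrix(0, cfg@nORs, nOd,
               dimnames = list(sprintf("OR%02d", seq_len(cfg@nORs)), odorants))
  for (i in seq_len(cfg@nORs)) {
    resp <- g + stats::rnorm(nOd, 0, cfg@responseNoiseSD)
    inhib <- stats::runif(nOd) < cfg@inhibFraction
    resp[inhib] <- resp[inhib] - stats::runif(sum(inhib), 0, cfg@inhibMax)
    en[i, ] <- .roundDec(resp, 4)
  }
  oo <- .roundDec(cfg@oocyteGain * pmax(0, en - cfg@oocyteThreshold), 4)
  activeCount <- colSums(en >= 10)

  enStudies <- sprintf("study-en-%02d", 1L + (seq_len(cfg@nORs) - 1L) %% 3L)
  recEN <- .emptyRecord(cfg@nORs * nOd)
  recEN$data_type <- "OR"; recEN$technique <- "empty_neuron"
  recEN$species <- "Agam"
  recEN$receptor_or_sensillum <- rep(rownames(en), times = nOd)
  recEN$odorant_canonical <- rep(odorants, each = cfg@nORs)
  recEN$compound_id <- rep(cid[seq_len(nOd)], each = cfg@nORs)
  recEN$concentration_value <- 0.01
  recEN$concentration_unit <- "vv_fraction"
  recEN$response_value <- as.vector(en)
  recEN$response_unit <- "spikes_s"
  recEN$study_id <- rep(enStudies, times = nOd)
  recEN$background_subtracted <- TRUE
  recEN$age_days_min <- 6; recEN$age_days_max <- 8
  recEN$sex <- "female"

  recOO <- recEN
  recOO$technique <- "oocyte"
  recOO$response_value <- as.vector(oo)
  recOO$response_unit <- "nA"
  recOO$study_id <- "study-oo-01"
  recOO$sex <- NA_character_
  recOO$age_days_min <- NA_real_; recOO$age_days_max <- NA_real_

  ## SSR: native-sensillum recordings on a small odorant panel
  nSSR <- min(40L, nOd)
  ssrOd <- odorants[seq_len(nSSR)]
  recSSR <- .emptyRecord(nSSR)
  recSSR$data_type <- "SSR"; recSSR$technique <- "ssr_native"
  recSSR$species <- "Aaeg"
  recSSR$receptor_or_sensillum <-
    rep(c("trichoid-A", "trichoid-B", "grooved-peg"), length.out = nSSR)
  recSSR$odorant_canonical <- ssrOd
  recSSR$compound_id <- cid[seq_len(nSSR)]
  recSSR$concentration_value <- 0.01
  recSSR$concentration_unit <- "vv_fraction"
  recSSR$response_value <- .roundDec(g[seq_len(nSSR)] +
                                   stats::rnorm(nSSR, 0,
                                                cfg@responseNoiseSD), 4)
  recSSR$response_unit <- "spikes_s"
  recSSR$study_id <- "study-ssr-01"
  recSSR$background_subtracted <- TRUE

  ## EAG: two studies, responses normalized to 1-octen-3-ol
  recEAG <- NULL
  for (s in 1:2) {
    eagOd <- c("1-octen-3-ol",
               odorants[unique(pmin(nOd, seq.int((s - 1L) * 15L + 1L,
                                                 length.out = 15L)))])
    r <- .emptyRecord(length(eagOd))
    r$data_type <- "EAG"; r$technique <- "eag"
    r$species <- "Aaeg"
    r$odorant_canonical <- eagOd
    r$compound_id <- cid[match(eagOd, allOd)]
    r$concentration_value <- 0.01
    r$concentration_unit <- "vv_fraction"
    r$response_value <- c(1, .roundDec(stats::runif(length(eagOd) - 1L, 0.1, 2),
                                   6))
    r$response_unit <- "normalized"
    r$study_id <- sprintf("study-eag-%02d", s)
    r$eag_reference <- "1-octen-3-ol"
    recEAG <- rbind(recEAG, r)
  }

  ## behavior: planted assay offsets, concentration slope, OR-count loading
  spp <- .speciesPool[seq_len(cfg@nSpecies)]
  behOd <- odorants[seq_len(cfg@nBehaviorOdorants)]
  base <- stats::runif(cfg@nBehaviorOdorants, -0.5, 0.5)
  names(base) <- behOd
  oviBase <- if (cfg@ovipositionMode == "independent")
    stats::runif(cfg@nBehaviorOdorants, -0.5, 0.5)
  else cfg@ovipositionRho * base +
    sqrt(1 - cfg@ovipositionRho^2) * stats::runif(cfg@nBehaviorOdorants,
                                                  -0.5, 0.5)
  names(oviBase) <- behOd
  counts <- activeCount[behOd]

  blocks <- list()
  for (sp in spp) {
    for (assay in .assaysFor(sp)) {
      delta <- if (assay %in% names(cfg@assayOffsets))
        cfg@assayOffsets[[assay]] else 0
      for (rep_i in seq_len(cfg@nRepBehavior)) {
        n <- cfg@nBehaviorOdorants * length(cfg@behaviorDecades)
        od <- rep(behOd, times = length(cfg@behaviorDecades))
        dd <- rep(cfg@behaviorDecades, each = cfg@nBehaviorOdorants)
        pi_raw <- base[od] - cfg@concentrationSlope * (dd - cfg@referenceDecade) +
          delta - cfg@orCountLoading * counts[od] +
          stats::rnorm(n, 0, cfg@piNoiseSD)
        r <- .emptyRecord(n)
        r$data_type <- "BEHAVIOR"; r$technique <- "behavior"
        r$species <- sp
        r$odorant_canonical <- od
        r$compound_id <- cid[match(od, allOd)]
        r$concentration_value <- 10^dd
        r$concentration_unit <- "wv_g_per_ml"
        r$response_value <- .roundDec(.clip(pi_raw), 6)
        r$response_unit <- "pi"
        r$assay_category <- assay
        r$behavioral_context <- "host_seeking_foraging"
        r$study_id <- sprintf("study-beh-%s-%s-%d", sp, assay, rep_i)
        r$age_days_min <- 6; r$age_days_max <- 8
        r$sex <- if (sp == "Dmel") "mixed" else "female"
        blocks[[length(blocks) + 1L]] <- r
      }
    }
    ## oviposition records at the reference decade
    oviOd <- behOd[seq_len(min(20L, cfg@nBehaviorOdorants))]
    for (rep_i in seq_len(cfg@nRepBehavior)) {
      n <- length(oviOd)
      r <- .emptyRecord(n)
      r$data_type <- "BEHAVIOR"; r$technique <- "behavior"
      r$species <- sp
      r$odorant_canonical <- oviOd
      r$compound_id <- cid[match(oviOd, allOd)]
      r$concentration_value <- 10^cfg@referenceDecade
      r$concentration_unit <- "wv_g_per_ml"
      r$response_value <- .roundDec(.clip(oviBase[oviOd] +
                                        stats::rnorm(n, 0, cfg@piNoiseSD)), 6)
      r$response_unit <- "pi"
      r$assay_category <- "dual_port"
      r$behavioral_context <- "oviposition"
      r$study_id <- sprintf("study-ovi-%s-%d", sp, rep_i)
      r$age_days_min <- 6; r$age_days_max <- 8
      r$sex <- "female"
      blocks[[length(blocks) + 1L]] <- r
    }
  }

  rec <- rbind(recEN, recOO, recSSR, recEAG,
               do.call(rbind, blocks))
  rec <- rec[.canonicalOrder(rec), , drop = FALSE]
  rownames(rec) <- NULL

  synonyms <- data.frame(
    synonym_key = c(.normalizeName(allOd), .normalizeName(toupper(allOd)),
                    .normalizeName(paste0("syn-", allOd))),
    canonical_name = rep(allOd, 3L),
    compound_id = rep(cid, 3L),
    molecular_weight = rep(mw, 3L),
    stringsAsFactors = FALSE)
  synonyms <- synonyms[!duplicated(synonyms$synonym_key), , drop = FALSE]

  truth <- list(seed = cfg@seed, tuningProperty = cfg@tuningProperty,
                a = cfg@tuningAmplitude, b = cfg@tuningCenter,
                sigma = cfg@tuningWidth, responseNoiseSD = cfg@responseNoiseSD,
                theta = cfg@oocyteThreshold, gain = cfg@oocyteGain,
                assayOffsets = cfg@assayOffsets,
                beta = cfg@concentrationSlope, gamma = cfg@orCountLoading,
                base = base, oviBase = oviBase, activeCount = activeCount,
                x = stats::setNames(x, odorants), emptyNeuron = en,
                oocyte = oo)

  list(db = ResponseDB(rec), properties = properties, descriptors = desc,
       odorants = odorTab, synonyms = synonyms, truth = truth)
}
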