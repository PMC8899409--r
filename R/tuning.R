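## Gaussian tuning of OR responses to physicochemical properties, with a
## shuffle-based permutation null on the fitted width sigma.

#' @include conditions.R AllClasses.R
NULL

#' Read an odorant property table
#'
#' CSV with an `odorant_canonical` key column and one numeric column per
#' physicochemical property; missing entries blank.
#'
#' @param path CSV path.
#' @return data.frame keyed by `odorant_canonical`.
#' @export
readPropertyTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"odorant_canonical" %in% names(tab))
    odorStop("odorDB_schema", "property table needs an 'odorant_canonical' column")
  if (anyDuplicated(tab$odorant_canonical))
    odorStop("odorDB_schema", "duplicate odorants in property table")
  tab
}

#' Properties with enough distinct values for reliable curve fitting
#'
#' A property is eligible when it takes at least `min_distinct` different
#' numeric values over the odorant set; binary or near-constant properties
#' cannot support a tuning-curve fit. Column order is preserved.
#'
#' @param properties property table (data.frame with `odorant_canonical`).
#' @param odorant_set character vector of odorants to consider.
#' @param min_distinct minimum number of distinct numeric values (default
#'   10).
#' @return character vector of eligible property names.
#' @export
eligibleProperties <- function(properties, odorant_set, min_distinct = 10L) {
  props <- setdiff(names(properties), "odorant_canonical")
  rows <- properties$odorant_canonical %in% odorant_set
  keep <- vapply(props, function(p) {
    v <- suppressWarnings(as.numeric(properties[[p]][rows]))
    length(unique(v[!is.na(v)])) >= min_distinct
  }, logical(1))
  props[keep]
}

#' Select (property value, response) pairs for a tuning fit
#'
#' One pair per OR-odorant measurement at the stated concentration decade
#' (default \eqn{10^{-2}} V/V or W/V, the most common concentration in
#' curated datasets). Pairs whose odorant lacks the property value are
#' dropped; dry-amount records never match a solution decade.
#'
#' @param db [ResponseDB-class] (or standardized record data.frame).
#' @param properties property table.
#' @param property_name property column to use.
#' @param decade target concentration decade (power of ten; default 1e-2).
#' @param species optional species filter.
#' @param technique OR technique whose responses are fitted (default the
#'   empty-neuron system, whose spikes/s scale the tuning amplitude).
#' @return data.frame with columns `odorant`, `receptor`, `x` (property
#'   value), `response`.
#' @export
selectTuningPairs <- function(db, properties, property_name, decade = 1e-2,
                              species = NULL, technique = "empty_neuron") {
  rec <- .getRecords(db)
  rec <- rec[rec$data_type == "OR" & rec$technique %in% technique, ,
             drop = FALSE]
  if (!is.null(species)) rec <- rec[rec$species %in% species, , drop = FALSE]
  if (!property_name %in% names(properties))
    odorStop("odorDB_schema",
             sprintf("property '%s' not in property table", property_name))
  dec <- concentrationDecade(rec$concentration_value, rec$concentration_unit)
  rec <- rec[!is.na(dec) & dec == round(log10(decade)), , drop = FALSE]
  x <- properties[[property_name]][
    match(rec$odorant_canonical, properties$odorant_canonical)]
  keep <- !is.na(x) & !is.na(rec$response_value)
  out <- data.frame(odorant = rec$odorant_canonical[keep],
                    receptor = rec$receptor_or_sensillum[keep],
                    x = as.numeric(x[keep]),
                    response = rec$response_value[keep],
                    stringsAsFactors = FALSE)
  if (nrow(out) == 0L)
    odorSkip("odorDB_empty_selection",
             sprintf("no OR-odorant pairs at decade %g with property '%s'",
                     decade, property_name))
  rownames(out) <- NULL
  out
}

.tuningInit <- function(x, r) {
  a0 <- max(r)
  b0 <- x[which.max(r)]
  s0 <- stats::IQR(x) / 2
  if (!is.finite(s0) || s0 <= 0) s0 <- stats::sd(x)
  if (!is.finite(s0) || s0 <= 0) s0 <- 1
  list(a0 = a0, b0 = b0, s0 = s0)
}

#' Fit a Gaussian tuning curve to (property, response) pairs
#'
#' Least-squares fit of \eqn{r = a \exp(-(x - b)^2 / (2\sigma^2))} by
#' Levenberg-Marquardt, parameterized directly in \eqn{\sigma}, the
#' standard deviation of the Gaussian. The fit is deterministic: the
#' initialization is \eqn{a_0 = \max r}, \eqn{b_0 = x} at the maximum
#' response, \eqn{\sigma_0 =} half the interquartile range of \eqn{x},
#' bounded positive. Negative (inhibitory) responses are retained.
#'
#' @param pairs data.frame with columns `x` and `response` (as from
#'   [selectTuningPairs()]), or a numeric vector of property values.
#' @param response numeric responses if `pairs` is a vector.
#' @return list with elements `a`, `b`, `sigma`, `sse`, `iterations`,
#'   `converged`.
#' @examples
#' x <- seq(40, 160, length.out = 30)
#' r <- 100 * exp(-(x - 100)^2 / (2 * 30^2))
#' fitGaussianTuning(x, r)[c("a", "b", "sigma")]
#' @export
fitGaussianTuning <- function(pairs, response = NULL) {
  if (is.null(response)) {
    x <- pairs$x
    r <- pairs$response
  } else {
    x <- as.numeric(pairs)
    r <- as.numeric(response)
  }
  if (length(x) != length(r))
    odorStop("odorDB_schema", "x and response must have equal length")
  if (length(x) < 4L)
    odorStop("odorDB_degenerate_fit",
             "at least 4 pairs are required to fit a 3-parameter Gaussian")
  if (any(!is.finite(x)) || any(!is.finite(r)))
    odorStop("odorDB_schema", "non-finite values in tuning pairs")
  if (length(unique(x)) == 1L)
    odorStop("odorDB_degenerate_fit",
             "all property values identical; tuning fit is degenerate")
  init <- .tuningInit(x, r)
  fit <- .cpp_fit_gaussian(x, r, init$a0, init$b0, init$s0)
  out <- list(a = unname(fit["a"]), b = unname(fit["b"]),
              sigma = unname(fit["sigma"]), sse = unname(fit["sse"]),
              iterations = as.integer(fit["iterations"]),
              converged = fit["converged"] == 1)
  if (!out$converged)
    odorStop("odorDB_fit_failure", "Gaussian fit failed to converge",
             diagnostics = out)
  out
}

# Per-property shuffle stream: one global seed, per-property sub-streams
# derived by hashing the property name, so properties can be analyzed in
# any order with identical results.
.propertySeed <- function(seed, property) {
  h <- 0
  for (ch in utf8ToInt(as.character(property)))
    h <- (h * 31 + ch) %% 2147483647
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

.allPermutations <- function(n) {
  permute <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v))
      for (p in permute(v[-i])) out[[length(out) + 1L]] <- c(v[i], p)
    out
  }
  do.call(cbind, permute(seq_len(n)))
}

#' Permutation test of Gaussian tuning width
#'
#' Shuffles the mapping between property values and responses `nShuffles`
#' times, refits the Gaussian to each shuffled dataset, and reports the
#' p-value as the fraction of shuffles whose fitted width satisfies
#' \eqn{\sigma_{shuffle} \le \sigma_{actual}}. A small p-value indicates
#' that the observed tuning is sharper than expected under no
#' property-response association. Shuffle fits that fail to converge
#' contribute \eqn{\sigma_{shuffle} = +\infty}; their count is recorded.
#' With `exhaustive = TRUE` all \eqn{n!} permutations are enumerated
#' instead of sampled (small \eqn{n} only).
#'
#' @inheritParams fitGaussianTuning
#' @param nShuffles number of shuffles (p-value resolution `1/nShuffles`).
#' @param seed integer seed of the shuffle stream.
#' @param property property name recorded in the result; also used to
#'   derive the per-property shuffle stream from `seed`.
#' @param exhaustive enumerate all permutations instead of sampling.
#' @return a [TuningFit-class].
#' @export
permutationTestSigma <- function(pairs, response = NULL, nShuffles = 1000L,
                                 seed = 1L, property = "property",
                                 exhaustive = FALSE) {
  if (is.null(response)) {
    x <- pairs$x
    r <- pairs$response
  } else {
    x <- as.numeric(pairs)
    r <- as.numeric(response)
  }
  fit <- fitGaussianTuning(x, r)  # propagates errors on the observed data
  n <- length(x)
  init <- .tuningInit(x, r)
  if (exhaustive) {
    if (n > 8L)
      odorStop("odorDB_range", "exhaustive enumeration supported for n <= 8")
    perms <- .allPermutations(n)
  } else {
    perms <- .withSeed(.propertySeed(seed, property),
                       matrix(unlist(lapply(seq_len(nShuffles),
                                            function(i) sample.int(n))),
                              nrow = n))
  }
  sig <- .cpp_perm_sigma(x, r, perms, init$s0)
  nFail <- sum(is.infinite(sig))
  p <- mean(sig <= fit$sigma)
  new("TuningFit", property = property, n = as.integer(n),
      a = fit$a, b = fit$b, sigma = fit$sigma, pValue = p,
      nShuffles = ncol(perms), nFailedShuffles = as.integer(nFail),
      seed = as.integer(seed))
}

# Evaluate expr under a private RNG state seeded with `seed`, restoring the
# caller's RNG state afterwards.
.withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gaussian tuning analysis over all eligible properties
#'
#' Runs [selectTuningPairs()], [fitGaussianTuning()] and
#' [permutationTestSigma()] for every property with enough distinct values,
#' deriving one shuffle stream per property from the global seed.
#'
#' @inheritParams selectTuningPairs
#' @param nShuffles,seed see [permutationTestSigma()].
#' @param min_pairs minimum number of pairs to attempt a fit.
#' @return named list of [TuningFit-class] objects (properties whose
#'   selection is empty or degenerate are omitted).
#' @export
tuningAnalysis <- function(db, properties, decade = 1e-2, species = NULL,
                           nShuffles = 1000L, seed = 1L, min_pairs = 10L) {
  rec <- .getRecords(db)
  odors <- unique(rec$odorant_canonical[rec$data_type == "OR"])
  out <- list()
  for (p in eligibleProperties(properties, odors)) {
    res <- tryCatch({
      pairs <- selectTuningPairs(db, properties, p, decade = decade,
                                 species = species)
      if (nrow(pairs) < min_pairs) NULL
      else permutationTestSigma(pairs, nShuffles = nShuffles, seed = seed,
                                property = p)
    }, odorDB_error = function(e) NULL)
    if (!is.null(res)) out[[p]] <- res
  }
  out
}

# Accept either a ResponseDB or a bare data.frame of standardized records.
.getRecords <- function(db) {
  if (methods::is(db, "ResponseDB")) db@records
  else if (is.data.frame(db)) db
  else odorStop("odorDB_schema", "expected a ResponseDB or data.frame")
}
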