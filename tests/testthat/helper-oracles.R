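# Independent oracles used across the suite.

# Exhaustive sign-rank p-value: enumerate all 2^n sign assignments of the
# (zero-dropped, tie-averaged) ranks.
enumSignRankP <- function(d) {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) return(1)
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  Wall <- as.vector(signs %*% rk)
  p_le <- mean(Wall <= W)
  p_ge <- mean(Wall >= W)
  min(1, 2 * min(p_le, p_ge))
}

# Gaussian tuning width via an independent solver (minpack.lm), same
# initialization rule as the package.
nlsSigma <- function(x, r) {
  a0 <- max(r)
  b0 <- x[which.max(r)]
  s0 <- stats::IQR(x) / 2
  if (s0 <= 0) s0 <- stats::sd(x)
  f <- tryCatch(suppressWarnings(
    minpack.lm::nlsLM(r ~ a * exp(-(x - b)^2 / (2 * s^2)),
                      start = list(a = a0, b = b0, s = s0),
                      control = minpack.lm::nls.lm.control(maxiter = 1000))),
    error = function(e) NULL)
  if (is.null(f)) Inf else abs(stats::coef(f)[["s"]])
}

# Exhaustive permutation p-value built on the independent fitter.
nlsExhaustiveP <- function(x, r) {
  sa <- nlsSigma(x, r)
  perms <- odorDB:::.allPermutations(length(x))
  sig <- apply(perms, 2, function(p) nlsSigma(x, r[p]))
  mean(sig <= sa)
}

# Small standardized behavioral record table for hand-built scenarios.
behaviorRecord <- function(odorant, pi, decade, species = "Aaeg",
                           assay = "y_tube", study = "s1",
                           context = "host_seeking_foraging") {
  df <- data.frame(data_type = "BEHAVIOR", species = species,
                   odorant_canonical = odorant,
                   concentration_value = 10^decade,
                   concentration_unit = "wv_g_per_ml",
                   response_value = pi, response_unit = "pi",
                   technique = "behavior", assay_category = assay,
                   behavioral_context = context, study_id = study,
                   stringsAsFactors = FALSE)
  records(ResponseDB(df))   # full schema, validated
}

orRecord <- function(odorant, receptor, response, technique = "empty_neuron",
                     decade = -2, species = "Agam", study = "s-or") {
  df <- data.frame(data_type = "OR", species = species,
                   odorant_canonical = odorant,
                   concentration_value = 10^decade,
                   concentration_unit = "vv_fraction",
                   response_value = response,
                   response_unit = if (technique == "oocyte") "nA"
                   else "spikes_s",
                   technique = technique, receptor_or_sensillum = receptor,
                   study_id = study, stringsAsFactors = FALSE)
  records(ResponseDB(df))
}

smallSim <- function(seed = 11) {
  generateDatabase(syntheticConfig(seed = seed, nOdorants = 60L, nORs = 8L,
                                   nBehaviorOdorants = 30L))
}
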