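## Two-sided paired Wilcoxon signed-rank test. Zero differences are
## dropped; ties in |d| get average ranks. For n <= 25 the null
## distribution is computed exactly by dynamic programming over the
## (doubled, hence integer) rank scores, which remains exact in the
## presence of ties; above that a normal approximation with continuity
## correction and the tie-adjusted variance sum(rank^2)/4 is used.

#' Paired Wilcoxon signed-rank test
#'
#' @param x numeric vector (differences, or first member of pairs).
#' @param y optional second member; the test is then on `x - y`.
#' @param exact_n_max exact enumeration is used for up to this many
#'   non-zero differences (default 25).
#' @return list with `statistic` (sum of positive-difference ranks), `n`
#'   (non-zero differences), `p.value` (two-sided), `method`
#'   (`"exact"`/`"normal"`).
#' @examples
#' signRankTest(c(1.2, 0.8, -0.3, 2.0, 0.5))
#' @export
signRankTest <- function(x, y = NULL, exact_n_max = 25L) {
  d <- if (is.null(y)) x else x - y
  d <- d[!is.na(d)]
  d <- d[d != 0]  # standard treatment: zeros dropped
  n <- length(d)
  if (n == 0L)
    return(list(statistic = NA_real_, n = 0L, p.value = 1, method = "exact"))
  rk <- rank(abs(d))
  W <- sum(rk[d > 0])
  if (n <= exact_n_max) {
    s <- as.integer(round(2 * rk))     # doubled ranks are integers
    total <- sum(s)
    # f[w + 1] = number of sign assignments with doubled statistic w
    f <- numeric(total + 1)
    f[1] <- 1
    for (si in s) {
      g <- f
      g[(si + 1):(total + 1)] <- g[(si + 1):(total + 1)] + f[1:(total + 1 - si)]
      f <- g
    }
    f <- f / 2^n
    w2 <- as.integer(round(2 * W))
    p_le <- sum(f[seq_len(w2 + 1)])
    p_ge <- sum(f[seq.int(w2 + 1, total + 1)])
    p <- min(1, 2 * min(p_le, p_ge))
    list(statistic = W, n = n, p.value = p, method = "exact")
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(sum(rk^2) / 4)
    z <- (abs(W - mu) - 0.5) / sigma
    z <- max(z, 0)
    p <- min(1, 2 * stats::pnorm(z, lower.tail = FALSE))
    list(statistic = W, n = n, p.value = p, method = "normal")
  }
}
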