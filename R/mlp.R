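## Minimal feedforward network regressor (tanh hidden layers, linear
## output) trained by full-batch Adam with early stopping on a validation
## set. Deliberately small and dependency-free: the architecture contract
## (three hidden layers of 50 units by default) and bitwise determinism
## given a seed matter more here than raw speed.

.mlpInit <- function(nIn, hidden, seed) {
  sizes <- c(nIn, hidden, 1L)
  .withSeed(seed, {
    W <- vector("list", length(sizes) - 1L)
    b <- vector("list", length(sizes) - 1L)
    for (l in seq_along(W)) {
      fanIn <- sizes[l]
      W[[l]] <- matrix(stats::rnorm(fanIn * sizes[l + 1L], sd = sqrt(1 / fanIn)),
                       nrow = fanIn)
      b[[l]] <- numeric(sizes[l + 1L])
    }
    list(W = W, b = b)
  })
}

.mlpForward <- function(net, X) {
  L <- length(net$W)
  acts <- vector("list", L + 1L)
  acts[[1L]] <- X
  for (l in seq_len(L)) {
    Z <- acts[[l]] %*% net$W[[l]]
    Z <- sweep(Z, 2L, net$b[[l]], "+")
    acts[[l + 1L]] <- if (l < L) tanh(Z) else Z
  }
  acts
}

.mlpPredict <- function(net, X) drop(.mlpForward(net, X)[[length(net$W) + 1L]])

.mlpTrain <- function(X, y, Xval, yval, hidden = c(50L, 50L, 50L),
                      lr = 0.01, maxEpochs = 400L, patience = 30L,
                      seed = 1L) {
  net <- .mlpInit(ncol(X), hidden, seed)
  L <- length(net$W)
  m1 <- lapply(net$W, function(w) w * 0); m1b <- lapply(net$b, function(v) v * 0)
  v1 <- m1; v1b <- m1b
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  n <- nrow(X)
  best <- list(net = net, val = Inf, epoch = 0L)
  bad <- 0L
  for (epoch in seq_len(maxEpochs)) {
    acts <- .mlpForward(net, X)
    pred <- acts[[L + 1L]]
    delta <- 2 * (pred - y) / n            # d(MSE)/d(output)
    for (l in rev(seq_len(L))) {
      gW <- crossprod(acts[[l]], delta)
      gb <- colSums(delta)
      if (l > 1L)
        delta <- (delta %*% t(net$W[[l]])) * (1 - acts[[l]]^2)
      m1[[l]] <- beta1 * m1[[l]] + (1 - beta1) * gW
      v1[[l]] <- beta2 * v1[[l]] + (1 - beta2) * gW^2
      m1b[[l]] <- beta1 * m1b[[l]] + (1 - beta1) * gb
      v1b[[l]] <- beta2 * v1b[[l]] + (1 - beta2) * gb^2
      mh <- m1[[l]] / (1 - beta1^epoch); vh <- v1[[l]] / (1 - beta2^epoch)
      mhb <- m1b[[l]] / (1 - beta1^epoch); vhb <- v1b[[l]] / (1 - beta2^epoch)
      net$W[[l]] <- net$W[[l]] - lr * mh / (sqrt(vh) + eps)
      net$b[[l]] <- net$b[[l]] - lr * mhb / (sqrt(vhb) + eps)
    }
    valMSE <- mean((.mlpPredict(net, Xval) - yval)^2)
    if (is.finite(valMSE) && valMSE < best$val - 1e-12) {
      best <- list(net = net, val = valMSE, epoch = epoch)
      bad <- 0L
    } else {
      bad <- bad + 1L
      if (bad >= patience) break
    }
  }
  best
}
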