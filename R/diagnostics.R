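# Split-Rhat and effective sample size, computed per parameter from an
# array of draws (iterations x chains).

split_chain_matrix <- function(x) {
  n <- nrow(x)
  h <- floor(n / 2)
  cbind(x[seq_len(h), , drop = FALSE],
        x[(n - h + 1):n, , drop = FALSE])
}

split_rhat_one <- function(x) {
  x <- split_chain_matrix(x)
  n <- nrow(x)
  if (n < 4) return(NA_real_)
  mns <- colMeans(x)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  Bv <- n * var(mns)
  if (W < 1e-12) return(1)
  sqrt(((n - 1) / n * W + Bv / n) / W)
}

ess_one <- function(x) {
  x <- split_chain_matrix(x)
  n <- nrow(x); m <- ncol(x)
  if (n < 4) return(NA_real_)
  vars <- apply(x, 2, var)
  W <- mean(vars)
  varp <- (n - 1) / n * W + n * var(colMeans(x)) / n
  if (varp < 1e-12) return(n * m)
  maxlag <- min(n - 1, 200)
  acov <- sapply(seq_len(m), function(j) {
    a <- acf(x[, j], lag.max = maxlag, plot = FALSE, type = "covariance",
             demean = TRUE)$acf[, 1, 1]
    a
  })
  rho <- 1 - (W - rowMeans(acov[-1, , drop = FALSE])) / varp
  # Geyer initial monotone positive sequence on paired sums
  npair <- floor(length(rho) / 2)
  if (npair == 0) return(n * m)
  psum <- rho[2 * seq_len(npair) - 1] + rho[2 * seq_len(npair)]
  keep <- which(psum <= 0)
  if (length(keep)) psum <- psum[seq_len(keep[1] - 1)]
  psum <- cummin(pmax(psum, 0))
  tau <- 1 + 2 * sum(psum)
  max(m, min(n * m, n * m / tau))
}

posterior_diagnostics <- function(draw_array) {
  # draw_array: iterations x chains x params
  np <- dim(draw_array)[3]
  rhat <- vapply(seq_len(np), function(p) split_rhat_one(draw_array[, , p]),
                 numeric(1))
  ess <- vapply(seq_len(np), function(p) ess_one(draw_array[, , p]),
                numeric(1))
  list(rhat = rhat, ess = ess)
}
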