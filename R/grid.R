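#' Brute-force grid posterior (numerical-integration oracle)
#'
#' Integrates `prior(theta) * likelihood(theta)` over the unit hypercube by
#' the midpoint rule, for theories with at most 6 free scalar parameters.
#' Serves as an independent oracle against which the MCMC sampler is
#' validated. (The midpoint rule is used because Beta(a < 1, .) prior
#' densities diverge at the endpoints; the singularity is integrable and
#' midpoint evaluation never touches it.)
#'
#' @param theory A [reactivity_theory()] with `n_free_params(theory) <= 6`.
#' @param log An [observation_log()] (may be empty: the marginal likelihood
#'   of no data is 1).
#' @param resolution Grid points per dimension; the total grid size
#'   `resolution^d` must not exceed `1e7`. Default picks close to `2e6`
#'   total points.
#' @param experiments Optional list of experiments for which grid-posterior
#'   predictive bit probabilities are also returned.
#' @return List with `means` (posterior mean per parameter),
#'   `marginal_likelihood`, `log_marginal`, `resolution`, and optionally
#'   `predictive` (`n_experiments x width` matrix).
#' @export
grid_posterior <- function(theory, log, resolution = NULL,
                           experiments = NULL) {
  d <- n_free_params(theory)
  if (d > 6L) {
    stop("capacity error: ", d,
         " free parameters; grid_posterior supports at most 6")
  }
  if (is.null(resolution)) resolution <- max(11L, floor((2e6)^(1 / d)))
  resolution <- as.integer(resolution)
  if (resolution^d > 1e7) {
    stop("capacity error: grid of ", resolution, "^", d, " points exceeds 1e7")
  }
  meta <- param_meta(theory)
  mids <- (seq_len(resolution) - 0.5) / resolution
  grid <- as.matrix(do.call(expand.grid, rep(list(mids), d)))
  colnames(grid) <- meta$names
  lp <- numeric(nrow(grid))
  for (j in seq_len(d)) {
    lp <- lp + dbeta(grid[, j], meta$a[j], meta$b[j], log = TRUE)
  }
  if (length(log) > 0L) {
    str <- model_structure(theory, log$experiments, log$outcomes)
    chunk <- 250000L
    for (lo in seq(1L, nrow(grid), by = chunk)) {
      hi <- min(lo + chunk - 1L, nrow(grid))
      lp[lo:hi] <- lp[lo:hi] +
        rowSums(cpp_obs_loglik(grid[lo:hi, , drop = FALSE], str))
    }
  }
  mx <- max(lp)
  w <- exp(lp - mx)
  Z <- mean(w) # cell volume = resolution^-d, cells = resolution^d
  log_marginal <- mx + log(Z)
  means <- colSums(grid * w) / sum(w)
  out <- list(means = means, marginal_likelihood = exp(log_marginal),
              log_marginal = log_marginal, resolution = resolution)
  if (!is.null(experiments)) {
    if (!is.list(experiments)) experiments <- list(experiments)
    str2 <- model_structure(theory, experiments)
    probs <- cpp_predict_bits(grid, str2)
    wn <- w / sum(w)
    out$predictive <- apply(probs, c(2, 3), function(v) sum(v * wn))
  }
  out
}
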