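#' MCMC sampler configuration
#'
#' @param seed Integer random seed (mandatory; there is no silent default).
#' @param chains Number of chains run sequentially from one RNG stream.
#' @param warmup Adaptation iterations per chain (discarded).
#' @param draws Kept iterations per chain.
#' @param target_accept Dual-averaging target acceptance probability.
#' @param max_leapfrog Upper bound of the jittered leapfrog path length.
#' @return An `mcmc_config` object.
#' @export
mcmc_config <- function(seed, chains = 4L, warmup = 1000L, draws = 1000L,
                        target_accept = 0.9, max_leapfrog = 32L) {
  if (missing(seed)) stop("an explicit integer seed is required")
  stopifnot(chains >= 1L, warmup >= 50L, draws >= 1L,
            target_accept > 0, target_accept < 1, max_leapfrog >= 1L)
  structure(list(seed = as.integer(seed), chains = as.integer(chains),
                 warmup = as.integer(warmup), draws = as.integer(draws),
                 target_accept = target_accept,
                 max_leapfrog = as.integer(max_leapfrog)),
            class = "mcmc_config")
}

# one HMC chain in the unconstrained parameterization; lpg(x) must return
# list(lp, grad). Returns constrained draws plus divergence/acceptance info.
run_hmc_chain <- function(lpg, x0, warmup, draws, target_accept,
                          max_leapfrog) {
  n <- length(x0)
  x <- x0
  cur <- lpg(x)
  if (!is.finite(cur$lp)) stop("non-finite log-posterior at initialization")
  minv <- rep(1, n)

  # reasonable starting step size: aim for ~50% acceptance of one leapfrog
  eps <- 0.1
  for (it in 1:40) {
    r <- rnorm(n) / sqrt(minv)
    H0 <- -cur$lp + 0.5 * sum(r^2 * minv)
    r1 <- r + 0.5 * eps * cur$grad
    x1 <- x + eps * minv * r1
    g1 <- lpg(x1)
    r1 <- r1 + 0.5 * eps * g1$grad
    H1 <- if (is.finite(g1$lp)) -g1$lp + 0.5 * sum(r1^2 * minv) else Inf
    a <- exp(H0 - H1)
    if (is.finite(a) && a > 0.9) eps <- eps * 2
    else if (!is.finite(a) || a < 0.2) eps <- eps / 2
    else break
  }

  # dual averaging state
  mu <- log(10 * eps); log_eps_bar <- 0; h_bar <- 0
  gamma <- 0.05; t0 <- 10; kappa <- 0.75
  adapt_count <- 0
  win_lo <- floor(warmup * 0.25); win_hi <- floor(warmup * 0.75)
  win_x <- matrix(0, win_hi - win_lo, n); win_i <- 0

  out <- matrix(0, draws, n)
  divergences <- 0L; acc_sum <- 0; acc_n <- 0

  total <- warmup + draws
  for (it in seq_len(total)) {
    L <- sample.int(max_leapfrog, 1L)
    r <- rnorm(n) / sqrt(minv)
    H0 <- -cur$lp + 0.5 * sum(r^2 * minv)
    xp <- x; gp <- cur$grad; lp_p <- cur$lp
    rp <- r + 0.5 * eps * gp
    diverged <- FALSE
    for (l in seq_len(L)) {
      xp <- xp + eps * minv * rp
      gnew <- lpg(xp)
      if (!is.finite(gnew$lp) || !all(is.finite(gnew$grad))) {
        diverged <- TRUE; break
      }
      lp_p <- gnew$lp; gp <- gnew$grad
      rp <- rp + (if (l < L) eps else 0.5 * eps) * gp
    }
    if (!diverged) {
      H1 <- -lp_p + 0.5 * sum(rp^2 * minv)
      dH <- H1 - H0
      if (!is.finite(dH) || dH > 1000) diverged <- TRUE
    }
    a <- if (diverged) 0 else min(1, exp(H0 - H1))
    if (!diverged && log(runif(1)) < (H0 - H1)) {
      x <- xp
      cur <- list(lp = lp_p, grad = gp)
    }
    if (diverged && it > warmup) divergences <- divergences + 1L
    if (it <= warmup) {
      adapt_count <- adapt_count + 1
      frac <- 1 / (adapt_count + t0)
      h_bar <- (1 - frac) * h_bar + frac * (target_accept - a)
      log_eps <- mu - sqrt(adapt_count) / gamma * h_bar
      wt <- adapt_count^(-kappa)
      log_eps_bar <- wt * log_eps + (1 - wt) * log_eps_bar
      eps <- exp(log_eps)
      if (it > win_lo && it <= win_hi) {
        win_i <- win_i + 1; win_x[win_i, ] <- x
      }
      if (it == win_hi && win_i > 10) {
        v <- apply(win_x[seq_len(win_i), , drop = FALSE], 2, var)
        minv <- pmax(v, 1e-3)
        # restart step-size adaptation under the new metric
        mu <- log(10 * exp(log_eps_bar)); adapt_count <- 0
        h_bar <- 0; log_eps_bar <- 0
      }
      if (it == warmup) eps <- exp(log_eps_bar)
    } else {
      out[it - warmup, ] <- x
      acc_sum <- acc_sum + a; acc_n <- acc_n + 1
    }
  }
  list(draws = out, divergences = divergences,
       accept = acc_sum / max(acc_n, 1), step_size = eps)
}

#' Fit the posterior of a theory by Hamiltonian Monte Carlo
#'
#' Samples the joint posterior over memberships, reactivity tensors and
#' emission entries, proportional to `prior(theta) * exp(log_likelihood)`.
#' Sampling runs in the unconstrained logit parameterization with analytic
#' gradients; chains are initialized from the prior. Identical
#' `(theory, log, config)` give bit-identical draws.
#'
#' A warning (never an error) is raised when any split-Rhat exceeds 1.05 or
#' when more than 10% of post-warmup transitions diverge. Note that raw
#' latent parameters are subject to label switching across chains; compare
#' posteriors only through label-invariant quantities such as predictive
#' probabilities.
#'
#' @param theory A [reactivity_theory()].
#' @param log A non-empty [observation_log()] with width matching the theory.
#' @param config An [mcmc_config()].
#' @return An object of class `reactivity_posterior`: equally-weighted
#'   constrained draws (`(chains*draws) x n_param` matrix), per-parameter
#'   split-Rhat and effective sample size, divergence counts, and the
#'   theory.
#' @export
fit_posterior <- function(theory, log, config) {
  stopifnot(inherits(theory, "reactivity_theory"),
            inherits(log, "observation_log"),
            inherits(config, "mcmc_config"))
  if (length(log) == 0L) stop("precondition error: empty observation log")
  if (log$width != theory$width) {
    stop("shape error: log width ", log$width, " vs theory width ",
         theory$width)
  }
  meta <- param_meta(theory)
  str <- model_structure(theory, log$experiments, log$outcomes)
  lpg <- function(x) cpp_lp_grad(x, str, meta$a, meta$b, TRUE)

  set.seed(config$seed)
  chains <- vector("list", config$chains)
  for (ch in seq_len(config$chains)) {
    p0 <- as.numeric(sample_prior(theory, 1L))
    p0 <- pmin(pmax(p0, 1e-4), 1 - 1e-4)
    x0 <- qlogis(p0)
    chains[[ch]] <- run_hmc_chain(lpg, x0, config$warmup, config$draws,
                                  config$target_accept, config$max_leapfrog)
  }
  arr <- array(0, c(config$draws, config$chains, meta$n))
  for (ch in seq_len(config$chains)) {
    arr[, ch, ] <- plogis(chains[[ch]]$draws)
  }
  diag <- posterior_diagnostics(arr)
  ndiv <- sum(vapply(chains, `[[`, integer(1), "divergences"))
  total_kept <- config$chains * config$draws
  if (ndiv / total_kept > 0.10) {
    warning("convergence warning: ", ndiv, " of ", total_kept,
            " post-warmup transitions diverged")
  }
  finite_rhat <- diag$rhat[is.finite(diag$rhat)]
  if (length(finite_rhat) && max(finite_rhat) > 1.05) {
    warning("convergence warning: max split-Rhat ",
            round(max(finite_rhat), 3), " > 1.05")
  }
  draws <- matrix(aperm(arr, c(1, 2, 3)), total_kept, meta$n)
  colnames(draws) <- meta$names
  structure(
    list(draws = draws, theory = theory,
         chains = config$chains, n_warmup = config$warmup,
         n_draws = config$draws, seed = config$seed,
         diagnostics = list(
           rhat = setNames(diag$rhat, meta$names),
           ess = setNames(diag$ess, meta$names),
           divergences = ndiv,
           accept = vapply(chains, `[[`, numeric(1), "accept"),
           step_size = vapply(chains, `[[`, numeric(1), "step_size"))),
    class = "reactivity_posterior"
  )
}

#' @export
print.reactivity_posterior <- function(x, ...) {
  cat("<reactivity_posterior> ", nrow(x$draws), " draws (", x$chains,
      " chains), ", ncol(x$draws), " parameters; max split-Rhat ",
      round(max(x$diagnostics$rhat, na.rm = TRUE), 3), ", ",
      x$diagnostics$divergences, " divergences\n", sep = "")
  invisible(x)
}

#' Posterior-predictive outcome probabilities for experiments
#'
#' Monte-Carlo average over posterior draws of the per-bit outcome
#' probability of each experiment.
#'
#' @param posterior A [fit_posterior()] result (or any list with `draws`
#'   and `theory`).
#' @param experiments A single id vector or a list of them.
#' @param draws Optional draw matrix overriding `posterior$draws`.
#' @param weights Optional draw weights (importance reweighting).
#' @return A `n_experiments x width` matrix of probabilities in `[0,1]`
#'   (a vector if a single experiment was given).
#' @export
posterior_predictive <- function(posterior, experiments, draws = NULL,
                                 weights = NULL) {
  single <- !is.list(experiments)
  if (single) experiments <- list(experiments)
  theory <- posterior$theory
  if (is.null(draws)) draws <- posterior$draws
  str <- model_structure(theory, experiments)
  probs <- cpp_predict_bits(draws, str) # n_draws x n_exp x B
  nd <- dim(probs)[1]
  if (is.null(weights)) weights <- rep(1, nd)
  w <- weights / sum(weights)
  out <- apply(probs, c(2, 3), function(v) sum(v * w))
  if (single) out[1, ] else out
}

#' Serialize a posterior to a directory
#'
#' Writes draws as CSV (columnar, one parameter per column) and a JSON
#' diagnostics manifest.
#'
#' @param posterior A `reactivity_posterior`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_posterior <- function(posterior, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(as.data.frame(posterior$draws),
            file.path(dir, "draws.csv"), row.names = FALSE)
  manifest <- list(
    chains = posterior$chains, warmup = posterior$n_warmup,
    draws = posterior$n_draws, seed = posterior$seed,
    rhat = as.list(round(posterior$diagnostics$rhat, 5)),
    ess = as.list(round(posterior$diagnostics$ess, 1)),
    divergences = posterior$diagnostics$divergences,
    accept = posterior$diagnostics$accept,
    theory = theory_definition(posterior$theory)
  )
  jsonlite::write_json(manifest, file.path(dir, "diagnostics.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}
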