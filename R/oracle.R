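# Surprise quantification, disruptive-experiment selection, anomaly
# shortlisting and exploration replay.

#' Default anomaly threshold
#'
#' The surprise of an outcome judged 5% likely: `-log(0.05)`.
#' @export
anomaly_threshold_default <- function() -log(0.05)

obs_predictive <- function(draws, theory, log, weights = NULL) {
  str <- model_structure(theory, log$experiments, log$outcomes)
  predictive_outcome_prob(draws, str, weights)
}

#' Per-observation surprise under prior, online and final posteriors
#'
#' Surprise is the negative log predictive likelihood of an observation's
#' recorded outcome vector. Three reference distributions are tracked:
#' `a_priori` (parameters drawn from the prior, before any data), `online`
#' (a posterior conditioned on observations `0..t-1`, i.e. at the point of
#' observation; refitted every `refit_every` steps with importance
#' reweighting in between, so with `refit_every = Inf` the online trace
#' telescopes exactly to the joint predictive likelihood), and
#' `a_posteriori` (the posterior conditioned on the full log).
#'
#' @param theory A [reactivity_theory()].
#' @param log An [observation_log()], processed in order-index order.
#' @param config An [mcmc_config()]; its seed governs prior draws and all
#'   refits.
#' @param components Subset of `c("prior", "online", "final")` to compute.
#' @param n_prior_draws Number of prior parameter draws.
#' @param refit_every Online refit cadence (`Inf` = reweighting only).
#' @param final_posterior Optional precomputed full-log posterior to reuse.
#' @return A `surprise_trace` data frame with columns `order`, `experiment`,
#'   `outcome`, `a_priori`, `online`, `a_posteriori` (NA where not
#'   requested); all surprise entries are `>= 0`.
#' @export
surprise_trace <- function(theory, log, config,
                           components = c("prior", "online", "final"),
                           n_prior_draws = 1000L, refit_every = 1L,
                           final_posterior = NULL) {
  components <- match.arg(components, several.ok = TRUE)
  n <- length(log)
  res <- data.frame(
    order = log$order,
    experiment = vapply(log$experiments, experiment_key, character(1)),
    outcome = apply(log$outcomes, 1L, bits_to_string),
    a_priori = NA_real_, online = NA_real_, a_posteriori = NA_real_
  )
  set.seed(config$seed)
  P0 <- sample_prior(theory, n_prior_draws)
  if ("prior" %in% components) {
    res$a_priori <- -log(pmax(obs_predictive(P0, theory, log), PROB_FLOOR))
  }
  if ("online" %in% components && n > 0L) {
    draws <- P0
    str <- model_structure(theory, log$experiments, log$outcomes)
    llmat <- cpp_obs_loglik(draws, str)
    logw <- numeric(nrow(draws))
    online <- numeric(n)
    for (t in seq_len(n)) {
      w <- exp(logw - max(logw))
      w <- w / sum(w)
      online[t] <- -log(max(sum(w * exp(llmat[, t])), PROB_FLOOR))
      logw <- logw + llmat[, t]
      if (is.finite(refit_every) && t %% refit_every == 0L && t < n) {
        cfg <- config
        cfg$seed <- config$seed + t
        post <- fit_posterior(theory, log_subset(log, seq_len(t)), cfg)
        draws <- post$draws
        llmat <- cpp_obs_loglik(draws, str)
        logw <- numeric(nrow(draws))
      }
    }
    res$online <- online
  }
  if ("final" %in% components && n > 0L) {
    post <- if (is.null(final_posterior)) {
      fit_posterior(theory, log, config)
    } else final_posterior
    res$a_posteriori <-
      -log(pmax(obs_predictive(post$draws, theory, log), PROB_FLOOR))
  }
  class(res) <- c("surprise_trace", class(res))
  res
}

#' Shortlist observations whose final surprise exceeds a threshold
#'
#' After full exploration, observations that the final posterior still finds
#' unlikely are flagged as anomalies for expert follow-up; an empty
#' shortlist means every outcome is explained by the fitted theory.
#'
#' @param trace A [surprise_trace()] with the `a_posteriori` column filled.
#' @param threshold Surprise cutoff; default `-log(0.05)`.
#' @return The trace rows with `a_posteriori > threshold`, sorted by
#'   descending surprise.
#' @export
anomaly_shortlist <- function(trace, threshold = anomaly_threshold_default()) {
  stopifnot(inherits(trace, "surprise_trace"))
  hits <- trace[!is.na(trace$a_posteriori) &
                  trace$a_posteriori > threshold, , drop = FALSE]
  hits[order(-hits$a_posteriori), , drop = FALSE]
}

collapse_any_bit <- function(probs_array) {
  # probs_array: n_draws x n_exp x B -> P(any bit fires) per draw/experiment
  nd <- dim(probs_array)[1]; ne <- dim(probs_array)[2]
  out <- matrix(0, nd, ne)
  lognot <- log1p(-pmin(probs_array, 1 - 1e-12))
  for (b in seq_len(dim(probs_array)[3])) out <- out + lognot[, , b]
  -expm1(out)
}

#' Rank candidate experiments by expected disruption
#'
#' The disruption score of a candidate is the expected total-variation
#' change of the predictive reactivity probabilities over the remaining
#' unexplored experiments, were the candidate's (binary-collapsed: any bit
#' set) outcome revealed. Posterior draws are importance-reweighted by each
#' outcome branch rather than refitted:
#' `score(e) = sum_o pbar(o) * sum_{e' != e} |phat(e' | o) - phat(e')|`.
#'
#' @param theory A [reactivity_theory()].
#' @param posterior A `reactivity_posterior` (or list with `draws`).
#' @param candidates List of experiments to score (must be a subset of
#'   `remaining`).
#' @param remaining List of unexplored experiments.
#' @param weights Optional draw weights.
#' @return A `disruption_ranking` data frame sorted by descending score,
#'   ties broken by canonical experiment order.
#' @export
select_disruptive <- function(theory, posterior, candidates, remaining,
                              weights = NULL) {
  rem_keys <- vapply(remaining, experiment_key, character(1))
  cand_keys <- vapply(candidates, experiment_key, character(1))
  if (!all(cand_keys %in% rem_keys)) {
    stop("candidates must be a subset of the remaining experiments")
  }
  draws <- posterior$draws
  nd <- nrow(draws)
  if (is.null(weights)) weights <- rep(1, nd)
  wn <- weights / sum(weights)
  str <- model_structure(theory, remaining)
  p_any <- collapse_any_bit(cpp_predict_bits(draws, str)) # nd x n_rem
  phat <- as.numeric(crossprod(wn, p_any))
  scores <- numeric(length(candidates))
  for (i in seq_along(candidates)) {
    ci <- match(cand_keys[i], rem_keys)
    others <- setdiff(seq_along(remaining), ci)
    sc <- 0
    for (o in c(1, 0)) {
      lik <- if (o == 1) p_any[, ci] else 1 - p_any[, ci]
      pbar <- sum(wn * lik)
      denom <- sum(wn * lik)
      if (denom < 1e-300) next # degenerate branch: no draw supports it
      wrw <- wn * lik / denom
      phat_rw <- as.numeric(crossprod(wrw, p_any[, others, drop = FALSE]))
      sc <- sc + pbar * sum(abs(phat_rw - phat[others]))
    }
    scores[i] <- sc
  }
  ord <- order(-scores, cand_keys, method = "radix")
  structure(
    data.frame(experiment = cand_keys[ord], score = scores[ord]),
    experiments = candidates[ord],
    class = c("disruption_ranking", "data.frame")
  )
}

#' Replay a closed-loop exploration of a chemical space
#'
#' Iterates choose-observe-update over the unexplored experiments of a
#' space: the next experiment is picked at random or as the top of the
#' disruption ranking; its outcome is obtained from `outcome_source`; the
#' online surprise at the point of observation is recorded; the posterior
#' is refitted every `refit_every` observations (importance reweighting in
#' between). An observation whose online surprise exceeds the anomaly
#' threshold is scheduled once more before being accepted (the
#' repeat-attempt policy); both attempts enter the log.
#'
#' @param theory A [reactivity_theory()].
#' @param space A [chemical_space()].
#' @param outcome_source Function mapping an id vector to a 0/1 outcome
#'   vector of the theory's width.
#' @param config An [mcmc_config()]; seeds the whole trajectory.
#' @param steps Number of observations to acquire (stops early, with a
#'   message, if the space is exhausted).
#' @param seed_log Optional [observation_log()] of prior knowledge.
#' @param strategy `"random"` or `"disruptive"`.
#' @param refit_every Refit cadence in observations.
#' @param anomaly_threshold Online-surprise threshold for repeat attempts.
#' @param include_self Include self-pairs of self-reactive compounds.
#' @param n_prior_draws Prior draws used before the first refit.
#' @param max_candidates Cap on candidates scored per disruptive step (a
#'   random subset is scored when exceeded).
#' @return List with `log` (final observation log), `events` (one row per
#'   step: experiment, outcome, online surprise, refit/repeat/discovery
#'   flags), `discoveries` (first reactive observation of each experiment)
#'   and `posterior` (the last fitted posterior, or `NULL` if never
#'   refitted).
#' @export
replay_exploration <- function(theory, space, outcome_source, config,
                               steps, seed_log = NULL,
                               strategy = c("random", "disruptive"),
                               refit_every = 1L,
                               anomaly_threshold = anomaly_threshold_default(),
                               include_self = FALSE,
                               n_prior_draws = 1000L,
                               max_candidates = Inf) {
  strategy <- match.arg(strategy)
  all_exps <- enumerate_experiments(space, include_self = include_self)
  all_keys <- vapply(all_exps, experiment_key, character(1))
  set.seed(config$seed)
  draws <- sample_prior(theory, n_prior_draws)
  logw <- numeric(nrow(draws))
  posterior <- NULL

  exps <- list(); outs <- NULL; orders <- integer(0)
  if (!is.null(seed_log) && length(seed_log) > 0L) {
    stopifnot(seed_log$width == theory$width)
    exps <- seed_log$experiments
    outs <- seed_log$outcomes
    orders <- seed_log$order
    cfg <- config; cfg$seed <- config$seed + 1000L
    posterior <- fit_posterior(theory, seed_log, cfg)
    draws <- posterior$draws
    logw <- numeric(nrow(draws))
  }
  observed <- vapply(exps, experiment_key, character(1))
  reactive_seen <- unique(observed[which(rowSums(
    if (is.null(outs)) matrix(0, 0, 1) else outs) > 0)])

  events <- list()
  pending <- NULL
  for (step in seq_len(steps)) {
    remaining <- all_exps[!(all_keys %in% observed)]
    if (length(remaining) == 0L && is.null(pending)) {
      message("space exhausted after ", step - 1L, " steps; stopping early")
      break
    }
    is_repeat <- FALSE
    if (!is.null(pending)) {
      e <- pending; pending <- NULL; is_repeat <- TRUE
    } else if (strategy == "random") {
      e <- remaining[[sample.int(length(remaining), 1L)]]
    } else {
      cands <- remaining
      if (length(cands) > max_candidates) {
        cands <- cands[sample.int(length(cands), max_candidates)]
      }
      w <- exp(logw - max(logw))
      rk <- select_disruptive(theory, list(draws = draws), cands, remaining,
                              weights = w)
      e <- attr(rk, "experiments")[[1L]]
    }
    y <- as.integer(outcome_source(e))
    stopifnot(length(y) == theory$width)
    ob_log <- observation_log(list(e), matrix(y, 1L))
    w <- exp(logw - max(logw))
    pred <- obs_predictive(draws, theory, ob_log, w)
    surprise <- -log(max(pred, PROB_FLOOR))

    key <- experiment_key(e)
    exps <- c(exps, list(e))
    outs <- rbind(outs, y)
    orders <- c(orders, if (length(orders)) max(orders) + 1L else 0L)
    discovery <- any(y == 1L) && !(key %in% reactive_seen)
    if (discovery) reactive_seen <- c(reactive_seen, key)
    if (surprise > anomaly_threshold && !is_repeat) pending <- e
    observed <- c(observed, key)

    # weight update, then periodic refit
    str1 <- model_structure(theory, list(e), matrix(y, 1L))
    logw <- logw + as.numeric(cpp_obs_loglik(draws, str1))
    refit <- length(exps) %% refit_every == 0L
    if (refit) {
      cfg <- config; cfg$seed <- config$seed + length(exps)
      posterior <- fit_posterior(theory,
                                 observation_log(exps, outs, orders), cfg)
      draws <- posterior$draws
      logw <- numeric(nrow(draws))
    }
    events[[length(events) + 1L]] <- data.frame(
      step = step, experiment = key, outcome = bits_to_string(y),
      online_surprise = surprise, strategy = strategy,
      refit = refit, repeated = is_repeat, discovery = discovery)
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(step = integer(0))
  final_log <- observation_log(exps, outs, orders)
  list(log = final_log, events = events,
       discoveries = events[which(events$discovery), , drop = FALSE],
       posterior = posterior)
}
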