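test_that("a certain outcome has zero surprise", {
  th <- toy_theory(noise = noise_model(0, 0))
  log <- observation_log(list(c("c1", "c2")), matrix(1L, 1, 1))
  sure <- matrix(1, 2, 3) # all memberships and reactivities at 1
  pred <- reactoracle:::obs_predictive(sure, th, log)
  expect_equal(-log(pred), 0, tolerance = 1e-8)
})

test_that("prior surprise ignores observation order", {
  th <- toy_theory(n = 3)
  exps <- list(c("c1", "c2"), c("c1", "c3"), c("c2", "c3"))
  log <- observation_log(exps, matrix(c(1L, 0L, 1L), 3))
  perm <- observation_log(exps[c(3, 1, 2)],
                          matrix(c(1L, 1L, 0L), 3))
  cfg <- quick_config(seed = 21)
  tr1 <- surprise_trace(th, log, cfg, components = "prior")
  tr2 <- surprise_trace(th, perm, cfg, components = "prior")
  m1 <- setNames(tr1$a_priori, paste(tr1$experiment, tr1$outcome))
  m2 <- setNames(tr2$a_priori, paste(tr2$experiment, tr2$outcome))
  expect_equal(m1[names(m2)], m2)
})

test_that("online surprise telescopes to the joint predictive likelihood", {
  th <- toy_theory(n = 3)
  log <- observation_log(list(c("c1", "c2"), c("c1", "c3"), c("c2", "c3")),
                         matrix(c(1L, 0L, 1L), 3))
  cfg <- quick_config(seed = 33)
  tr <- surprise_trace(th, log, cfg, components = "online",
                       refit_every = Inf, n_prior_draws = 500)
  set.seed(cfg$seed)
  draws <- sample_prior(th, 500)
  str <- reactoracle:::model_structure(th, log$experiments, log$outcomes)
  joint <- mean(exp(rowSums(reactoracle:::cpp_obs_loglik(draws, str))))
  expect_equal(sum(tr$online), -log(joint), tolerance = 1e-6)
})

test_that("disruption scores match a hand-enumerated two-draw oracle", {
  th <- toy_theory(n = 3, noise = noise_model(0, 0))
  # draws on (M[c1], M[c2], M[c3], R): reaction prob of a pair = m_a m_b R
  d1 <- c(0.9, 0.8, 0.1, 1)
  d2 <- c(0.2, 0.3, 0.9, 1)
  post <- list(draws = rbind(d1, d2), theory = th)
  remaining <- list(c("c1", "c2"), c("c1", "c3"), c("c2", "c3"))
  cands <- remaining[1:2]
  rk <- select_disruptive(th, post, cands, remaining)
  # independent arithmetic: p_any per draw/experiment
  p <- rbind(c(0.9 * 0.8, 0.9 * 0.1, 0.8 * 0.1),
             c(0.2 * 0.3, 0.2 * 0.9, 0.3 * 0.9))
  phat <- colMeans(p)
  oracle_score <- function(ci) {
    others <- setdiff(1:3, ci)
    sc <- 0
    for (o in c(1, 0)) {
      lik <- if (o == 1) p[, ci] else 1 - p[, ci]
      w <- lik / sum(lik)
      sc <- sc + mean(lik) * sum(abs(colSums(w * p[, others]) - phat[others]))
    }
    sc
  }
  want <- c(oracle_score(1), oracle_score(2))
  got <- setNames(rk$score, rk$experiment)
  expect_equal(unname(got[c("c1+c2", "c1+c3")]), want, tolerance = 1e-10)
})

test_that("degenerate disruption cases score zero", {
  th <- toy_theory(n = 3, noise = noise_model(0, 0))
  p <- c(0.5, 0.5, 0.5, 0.8)
  post <- list(draws = rbind(p, p), theory = th) # identical draws
  remaining <- list(c("c1", "c2"), c("c1", "c3"))
  rk <- select_disruptive(th, post, remaining[1], remaining)
  expect_equal(rk$score, 0)
  # no other remaining experiments to perturb
  rk2 <- select_disruptive(th, post, remaining[1], remaining[1])
  expect_equal(rk2$score, 0)
  expect_error(select_disruptive(th, post, remaining, remaining[1]),
               "subset")
})

test_that("anomaly shortlists respect the threshold and ordering", {
  tr <- data.frame(order = 0:2, experiment = c("a+b", "a+c", "b+c"),
                   outcome = "1", a_priori = 1,
                   online = 1, a_posteriori = c(0.5, 4, 2))
  class(tr) <- c("surprise_trace", class(tr))
  hits <- anomaly_shortlist(tr, threshold = -log(0.05))
  expect_identical(hits$experiment, c("a+c"))
  all_pos <- anomaly_shortlist(tr, threshold = 0)
  expect_identical(all_pos$experiment, c("a+c", "b+c", "a+b"))
  expect_identical(nrow(anomaly_shortlist(tr, threshold = 10)), 0L)
})

test_that("replay is reproducible and silent spaces yield no discoveries", {
  da <- make_diels_alder_space()
  th <- reactivity_theory(da$space, K = 2, width = 1)
  cfg <- quick_config(seed = 8, warmup = 200, draws = 150)
  r1 <- replay_exploration(th, da$space, function(ids) 0L, cfg, steps = 4,
                           refit_every = 2, n_prior_draws = 300)
  r2 <- replay_exploration(th, da$space, function(ids) 0L, cfg, steps = 4,
                           refit_every = 2, n_prior_draws = 300)
  expect_identical(r1$events, r2$events)
  expect_identical(nrow(r1$discoveries), 0L)
  expect_true(any(r1$events$refit))
})

test_that("surprising observations are scheduled once more before acceptance", {
  da <- make_diels_alder_space()
  # a theory convinced nothing reacts, fed a space where everything does
  skeptic <- reactivity_theory(
    da$space, K = 2, width = 1,
    priors = prior_config("conservative-v1", tensor = c(0.5, 60),
                          tensor_rep = c(0.5, 60)))
  cfg <- quick_config(seed = 12, warmup = 200, draws = 150)
  r <- replay_exploration(skeptic, da$space, function(ids) 1L, cfg,
                          steps = 3, refit_every = 50, n_prior_draws = 400)
  expect_gt(r$events$online_surprise[1], anomaly_threshold_default())
  expect_true(r$events$repeated[2])
  expect_identical(r$events$experiment[2], r$events$experiment[1])
})

test_that("replay stops early when the space is exhausted", {
  sp <- tiny_space(3)
  th <- reactivity_theory(sp, K = 1, width = 1)
  cfg <- quick_config(seed = 5, warmup = 200, draws = 100)
  expect_message(
    r <- replay_exploration(th, sp, function(ids) 0L, cfg, steps = 10,
                            refit_every = 100, n_prior_draws = 200),
    "exhausted")
  expect_identical(nrow(r$events), 3L)
})

test_that("disruptive replay runs end to end on a planted space", {
  da <- make_diels_alder_space()
  th <- reactivity_theory(da$space, K = 2, width = 1,
                          noise = noise_model(1e-3, 1e-3))
  cfg <- quick_config(seed = 14, warmup = 250, draws = 200)
  r <- replay_exploration(th, da$space, da$outcome_source, cfg, steps = 5,
                          strategy = "disruptive", refit_every = 2,
                          include_self = TRUE, n_prior_draws = 300)
  expect_identical(nrow(r$events), 5L)
  expect_true(all(r$events$online_surprise >= 0))
})
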