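test_that("component matrix combines memberships and reactivity elementwise", {
  K <- 3
  R <- reactivity_tensor(K, 2, 1)
  expect_equal(component_matrix(rep(0, K), rep(0, K), R),
               matrix(0, K, K))
  expect_equal(component_matrix(1, 1, reactivity_tensor(1, 2, 1)),
               matrix(1, 1, 1))
  expect_equal(component_matrix(0.5, 0.5, reactivity_tensor(1, 2, 0.8)),
               matrix(0.2, 1, 1))
  expect_error(component_matrix(c(0.5, 0.5), 0.5, R), "shape error")
})

test_that("reaction probability matches its worked examples", {
  expect_equal(reaction_probability(list(0.5, 0.5),
                                    reactivity_tensor(1, 2, 0.8)), 0.2)
  expect_equal(reaction_probability(list(c(0, 0), runif(2)),
                                    reactivity_tensor(2, 2, runif(3))), 0)
  # K = 2, only the cross pair reactive, sharp memberships
  R <- reactivity_tensor(2, 2, c(0, 1, 0)) # multisets {11},{12},{22}
  expect_equal(reaction_probability(list(c(1, 0), c(0, 1)), R), 1)
  expect_error(reaction_probability(list(c(1, 0), c(0, 1)),
                                    reactivity_tensor(2, 3, 0)),
               "shape error")
})

test_that("reaction probability equals the multiset-enumeration oracle", {
  set.seed(101)
  for (K in 1:2) {
    for (rep in 1:20) {
      m <- list(runif(K), runif(K))
      R <- reactivity_tensor(K, 2, runif(reactoracle:::n_multisets(K, 2)))
      expect_equal(reaction_probability(m, R),
                   brute_force_reaction_prob(m, R), tolerance = 1e-12)
    }
  }
  # and for a ternary case
  m <- list(runif(2), runif(2), runif(2))
  R <- reactivity_tensor(2, 3, runif(4))
  expect_equal(reaction_probability(m, R),
               brute_force_reaction_prob(m, R), tolerance = 1e-12)
})

test_that("reaction probability is monotone in every parameter", {
  set.seed(7)
  for (rep in 1:10) {
    K <- 3
    m <- list(runif(K), runif(K))
    vals <- runif(reactoracle:::n_multisets(K, 2))
    R <- reactivity_tensor(K, 2, vals)
    base <- reaction_probability(m, R)
    i <- sample.int(K, 1)
    m2 <- m
    m2[[1]][i] <- min(1, m2[[1]][i] + 0.1)
    expect_gte(reaction_probability(m2, R), base)
    vals2 <- pmin(1, vals + 0.05)
    expect_gte(reaction_probability(m, reactivity_tensor(K, 2, vals2)), base)
  }
})

test_that("probabilities are invariant under compound permutation", {
  set.seed(13)
  for (k in 2:4) {
    K <- 2
    m <- lapply(seq_len(k), function(i) runif(K))
    R <- reactivity_tensor(K, k, runif(reactoracle:::n_multisets(K, k)))
    p <- reaction_probability(m, R)
    for (rep in 1:5) {
      expect_equal(reaction_probability(m[sample(k)], R), p,
                   tolerance = 1e-12)
    }
  }
})

test_that("probabilities stay in [0,1] at extreme parameter values", {
  for (vals in list(c(0, 0, 0), c(1, 1, 1), c(1, 0, 1))) {
    R <- reactivity_tensor(2, 2, vals)
    for (m in list(list(c(0, 0), c(0, 0)), list(c(1, 1), c(1, 1)),
                   list(c(1, 0), c(0, 1)))) {
      p <- reaction_probability(m, R)
      expect_gte(p, 0); expect_lte(p, 1)
    }
  }
})

test_that("fingerprint-bit membership rows are per-property noisy-ORs", {
  M <- matrix(c(0.7, 0, 0.5, 0.5, 0.5, 0), 3, 2)
  expect_equal(compound_membership_from_bits(integer(0), M), c(0, 0))
  expect_equal(compound_membership_from_bits(1L, M), c(0.7, 0.5))
  M2 <- matrix(c(0.5, 0.5, 0, 0), 2, 2)
  expect_equal(compound_membership_from_bits(c(1L, 2L), M2), c(0.75, 0))
  expect_error(compound_membership_from_bits(9L, M), "basis error")
})

test_that("bit probability passes signal through emission and noise", {
  tensors <- list("2" = reactivity_tensor(1, 2, 0.5))
  noise <- noise_model(0.01, 0.01)
  E <- matrix(c(1, 0), 1, 2)
  # single mode with component 0.5, emission 1
  expect_equal(bit_probability(list(1, 1), tensors, E, noise, 1L),
               0.01 + 0.98 * 0.5)
  # no membership, eps_fp = 0: zero probability
  expect_equal(bit_probability(list(0, 0), tensors, E, noise_model(0, 0), 1L),
               0)
  # saturated signal, no noise
  expect_equal(bit_probability(list(1, 1),
                               list("2" = reactivity_tensor(1, 2, 1)),
                               matrix(1, 1, 1), noise_model(0, 0), 1L), 1)
  expect_error(bit_probability(list(1, 1), tensors, E, noise, 5L),
               "index error")
})

test_that("log-likelihood is additive, zero on empty logs, and clamps", {
  th <- toy_theory(noise = noise_model(0, 0))
  theta <- unpack_theta(th, c(1, 1, 0.5))
  empty <- observation_log(list(), matrix(integer(0), 0, 1))
  expect_identical(log_likelihood(empty, theta, th), 0)
  one <- observation_log(list(c("c1", "c2")), matrix(1L, 1, 1))
  expect_equal(log_likelihood(one, theta, th), log(0.5))
  two <- observation_log(list(c("c1", "c2"), c("c1", "c2")),
                         matrix(c(1L, 1L), 2, 1))
  expect_equal(log_likelihood(two, theta, th), 2 * log(0.5))
  contradictory <- unpack_theta(th, c(0, 0, 0))
  expect_warning(ll <- log_likelihood(one, contradictory, th), "clamped")
  expect_equal(ll, log(1e-9))
})

test_that("log-likelihood is invariant under property relabelling", {
  set.seed(31)
  sp <- tiny_space(4, arities = 2:3)
  th <- reactivity_theory(sp, K = 3, width = 2)
  log <- simulate_log(sp, function(ids) rbinom(2, 1, 0.5), seed = 5)
  theta <- random_theta(th)
  base <- log_likelihood(log, theta, th)
  for (rep in 1:5) {
    perm <- sample(th$K)
    theta2 <- theta
    theta2$M <- theta$M[, perm, drop = FALSE]
    for (k in names(theta$tensors)) {
      R <- theta$tensors[[k]]
      ar <- length(dim(R))
      idx <- as.matrix(do.call(expand.grid, rep(list(seq_len(th$K)), ar)))
      R2 <- array(0, dim(R))
      R2[idx] <- R[matrix(perm[idx], nrow(idx))]
      class(R2) <- class(R)
      theta2$tensors[[k]] <- R2
    }
    # emission rows follow the multiset order; remap by sorted permuted index
    for (k in th$arities) {
      ms <- reactoracle:::multisets(th$K, k)
      permuted <- t(apply(ms, 1, function(r) sort(match(r, perm))))
      newrow <- match(apply(permuted, 1, paste, collapse = ","),
                      apply(ms, 1, paste, collapse = ","))
      off <- reactoracle:::mode_offsets_by_arity(th$K, th$arities)[
        as.character(k)]
      theta2$emission[off + newrow, ] <- theta$emission[off + seq_len(nrow(ms)), ]
    }
    expect_equal(log_likelihood(log, theta2, th), base, tolerance = 1e-10)
  }
})

test_that("the compiled likelihood agrees with the reference implementation", {
  set.seed(77)
  cases <- list(
    list(sp = tiny_space(4, 2), K = 3, width = 1),
    list(sp = tiny_space(5, 2:3), K = 2, width = 1),
    list(sp = tiny_space(5, 2:4), K = 2, width = 3)
  )
  for (cs in cases) {
    th <- reactivity_theory(cs$sp, K = cs$K, width = cs$width)
    log <- simulate_log(cs$sp, function(ids) rbinom(cs$width, 1, 0.5),
                        seed = 11)
    str <- reactoracle:::model_structure(th, log$experiments, log$outcomes)
    for (rep in 1:5) {
      p <- runif(n_free_params(th), 0.02, 0.98)
      ll_cpp <- sum(reactoracle:::cpp_obs_loglik(matrix(p, 1), str))
      expect_equal(ll_cpp, log_likelihood(log, p, th), tolerance = 1e-10)
    }
  }
})

test_that("theta packing and unpacking are inverse bijections", {
  th <- reactivity_theory(tiny_space(4, 2:3), K = 3, width = 2)
  p <- runif(n_free_params(th))
  expect_equal(pack_theta(th, unpack_theta(th, p)), p)
})

test_that("prior configurations validate overrides and noise bounds", {
  pc <- prior_config("conservative-v1", membership = c(1, 4))
  expect_equal(pc$membership, c(1, 4))
  expect_equal(pc$tensor, c(0.5, 2.5))
  expect_error(prior_config("conservative-v1", nonsense = c(1, 1)))
  expect_error(noise_model(0.6, 0.01))
  expect_error(noise_model(-0.1, 0.01))
})
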