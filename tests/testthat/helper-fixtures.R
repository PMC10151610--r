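# Shared builders for small spaces, theories and logs used across the suite.

tiny_space <- function(n = 4L, arities = 2L) {
  chemical_space(lapply(seq_len(n), function(i) compound(paste0("c", i))),
                 arities = arities)
}

# smallest nontrivial theory: 2 compounds, K = 1, binary (3 free parameters)
toy_theory <- function(priors = "uniform", noise = noise_model(0.05, 0.05),
                       K = 1L, n = 2L) {
  reactivity_theory(tiny_space(n), K = K, width = 1L, priors = priors,
                    noise = noise)
}

quick_config <- function(seed, chains = 2L, warmup = 300L, draws = 300L) {
  mcmc_config(seed = seed, chains = chains, warmup = warmup, draws = draws)
}

# random parameter list for a theory (on the probability scale)
random_theta <- function(theory, lo = 0.02, hi = 0.98) {
  meta <- reactoracle:::param_meta(theory)
  unpack_theta(theory, runif(meta$n, lo, hi))
}

# independent multiset-enumeration oracle for the noisy-OR reaction
# probability: combine each unordered index multiset's distinct ordered
# assignments by noisy-OR, then noisy-OR across multisets
brute_force_reaction_prob <- function(memberships, R) {
  k <- length(memberships)
  K <- dim(R)[1]
  ms <- reactoracle:::multisets(K, k)
  p_not <- 1
  for (i in seq_len(nrow(ms))) {
    perms <- unique(perms_of(ms[i, ]))
    q <- 1
    for (pp in perms) {
      val <- R[matrix(ms[i, ], 1)]
      for (j in seq_len(k)) val <- val * memberships[[j]][pp[j]]
      q <- q * (1 - val)
    }
    p_not <- p_not * q
  }
  1 - p_not
}

perms_of <- function(v) {
  if (length(v) == 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (rest in perms_of(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
  }
  out
}
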