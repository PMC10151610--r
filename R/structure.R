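# Build the flattened model description consumed by the C++ core.
# `experiments` is a list of id vectors; `outcomes` an n x B matrix (dummy
# zeros when only predictions are needed).
model_structure <- function(theory, experiments, outcomes = NULL) {
  meta <- param_meta(theory)
  K <- theory$K
  B <- theory$width
  if (is.null(outcomes)) {
    outcomes <- matrix(0L, length(experiments), B)
  }
  stopifnot(nrow(outcomes) == length(experiments), ncol(outcomes) == B)
  ainfo <- lapply(seq_along(theory$arities), function(i) {
    k <- theory$arities[i]
    list(k = as.integer(k),
         tuples = ordered_tuples(K, k) - 1L,
         t2m = as.integer(tuple_to_multiset(K, k) - 1L),
         toff = as.integer(meta$offsets$R[[as.character(k)]]),
         moff = as.integer(mode_offsets_by_arity(K, theory$arities)[as.character(k)]),
         nm = as.integer(n_multisets(K, k)))
  })
  obs <- lapply(seq_along(experiments), function(i) {
    ids <- experiments[[i]]
    units <- match(ids, theory$compound_ids)
    if (anyNA(units)) {
      stop("reference error: unknown compound id(s): ",
           paste(ids[is.na(units)], collapse = ", "))
    }
    subs <- unit_subsets(length(units),
                         theory$arities[theory$arities <= length(units)])
    list(units = as.integer(units - 1L),
         subs = lapply(subs, function(s) as.integer(s - 1L)),
         y = as.integer(outcomes[i, ]))
  })
  list(K = as.integer(K), B = as.integer(B),
       n_ent = length(theory$entities),
       n_param = meta$n,
       n_modes = meta$n_modes,
       eps_fp = theory$noise$eps_fp, eps_fn = theory$noise$eps_fn,
       arities = ainfo,
       compound_bits = lapply(theory$compound_bits,
                              function(v) as.integer(v - 1L)),
       obs = obs)
}

# weighted per-observation predictive probability of the recorded outcomes:
# E_draws[ prod_b Bernoulli(y_b | p_b) ], one value per observation
predictive_outcome_prob <- function(draws, str, weights = NULL) {
  ll <- cpp_obs_loglik(draws, str)
  if (is.null(weights)) weights <- rep(1, nrow(draws))
  w <- weights / sum(weights)
  as.numeric(crossprod(w, exp(ll)))
}
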