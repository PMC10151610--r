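# Reference (pure-R) implementation of the generative probability model.
# The C++ core used by the sampler mirrors these definitions; tests hold the
# two routes together.

PROB_FLOOR <- 1e-9

clamp_prob <- function(p) pmin(pmax(p, PROB_FLOOR), 1 - PROB_FLOOR)

#' Probability component matrix of a compound pair
#'
#' Combines two membership rows with an arity-2 reactivity matrix into the
#' component matrix whose `[I, J]` entry is the probability that the first
#' compound reacts with the second by virtue of possessing property `I`
#' while the other possesses property `J`:
#' `P[I,J] = m_a[I] * m_b[J] * R[I,J]`.
#'
#' @param m_a,m_b Membership rows (length `K`, entries in `[0,1]`).
#' @param R Arity-2 [reactivity_tensor()] or `K x K` matrix.
#' @return A `K x K` matrix with entries in `[0,1]`.
#' @export
component_matrix <- function(m_a, m_b, R) {
  R <- as.matrix(R)
  K <- length(m_a)
  if (length(m_b) != K || !all(dim(R) == K)) {
    stop("shape error: membership rows and reactivity matrix disagree on K")
  }
  stopifnot(all(m_a >= 0 & m_a <= 1), all(m_b >= 0 & m_b <= 1),
            all(R >= 0 & R <= 1))
  outer(m_a, m_b) * R
}

#' Reaction probability of a single compound combination
#'
#' Noisy-OR aggregation over all property-index assignments: each ordered
#' assignment of properties to the participating compounds is an independent
#' potential cause with strength `prod_j m_j[I_j] * R[I_1..I_k]`, and the
#' combination reacts if any cause fires:
#' `p = 1 - prod(1 - cause)`. Equivalently (tested), a noisy-OR over
#' unordered index multisets where each multiset combines its distinct
#' ordered assignments by noisy-OR. The result is invariant under any
#' permutation of the membership rows.
#'
#' @param memberships List of 2-4 membership rows (length `K` each).
#' @param R A [reactivity_tensor()] of arity `length(memberships)`.
#' @return Reaction probability in `[0,1]`.
#' @export
reaction_probability <- function(memberships, R) {
  k <- length(memberships)
  stopifnot(k >= 2L, k <= 4L)
  if (tensor_arity(R) != k) {
    stop("shape error: tensor arity ", tensor_arity(R),
         " does not match ", k, " membership rows")
  }
  K <- dim(R)[1]
  if (!all(lengths(memberships) == K)) {
    stop("shape error: membership rows must have length K = ", K)
  }
  u <- memberships[[1]]
  for (j in 2:k) u <- outer(u, memberships[[j]])
  u <- u * as.numeric(R)
  1 - prod(1 - u)
}

#' Compound membership row from fingerprint-bit memberships
#'
#' In structural theories, properties attach to fingerprint bits; a compound
#' possesses property `I` if any of its set bits confers it (noisy-OR):
#' `row[I] = 1 - prod_b (1 - M[b, I])` over the compound's present bits.
#'
#' @param bit_set Integer indices of set bits (rows of `bit_memberships`);
#'   empty yields the all-zero row.
#' @param bit_memberships Bits x K membership matrix.
#' @return Membership row of length `K`.
#' @export
compound_membership_from_bits <- function(bit_set, bit_memberships) {
  K <- ncol(bit_memberships)
  if (length(bit_set) == 0L) return(numeric(K))
  bit_set <- as.integer(bit_set)
  if (any(bit_set < 1L | bit_set > nrow(bit_memberships))) {
    stop("basis error: bit index outside the fingerprint basis")
  }
  1 - apply(1 - bit_memberships[bit_set, , drop = FALSE], 2L, prod)
}

# all sub-combinations (as index vectors into `units`) with size in `arities`
unit_subsets <- function(n_units, arities) {
  out <- list()
  for (k in sort(arities)) {
    if (k <= n_units) out <- c(out, combn(n_units, k, simplify = FALSE))
  }
  out
}

# causes of one experiment: per (sub-combination, property multiset), the
# noisy-OR strength over the multiset's ordered assignments. Returns a list
# of vectors aligned with the global mode order (ascending arity, then
# multiset-lex).
experiment_causes <- function(rows, tensors, arities) {
  K <- length(rows[[1]])
  subs <- unit_subsets(length(rows), arities)
  causes <- list()
  for (s in subs) {
    k <- length(s)
    R <- tensors[[as.character(k)]]
    u <- rows[[s[1]]]
    for (j in s[-1]) u <- outer(u, rows[[j]])
    u <- pmin(as.numeric(u) * as.numeric(R), 1 - 1e-12)
    map <- tuple_to_multiset(K, k)
    # per-multiset noisy-OR over its ordered assignments
    logq <- vapply(split(log1p(-u), map), sum, numeric(1))
    causes[[length(causes) + 1L]] <-
      list(arity = k, comp = -expm1(logq))
  }
  causes
}

mode_offsets_by_arity <- function(K, arities) {
  offs <- integer(0); pos <- 0L
  for (k in sort(arities)) {
    offs[as.character(k)] <- pos
    pos <- pos + n_multisets(K, k)
  }
  offs
}

#' Per-bit outcome probability of an experiment
#'
#' Aggregates the experiment's reactivity causes - every property multiset
#' of every sub-combination whose size is among the modelled arities - into
#' the probability that outcome bit `bit` reads 1. Each cause `m` emits the
#' bit with probability `emission[m, bit]`; the signal is the noisy-OR
#' `s = 1 - prod_m (1 - comp(m) * emission[m, bit])`, observed through the
#' noise channel `p = eps_fp + (1 - eps_fp - eps_fn) * s`.
#'
#' @param memberships List of 2-4 membership rows.
#' @param tensors Named list of [reactivity_tensor()] keyed by arity
#'   (`"2"`, `"3"`, `"4"`).
#' @param emission Modes x B emission matrix (modes ordered by ascending
#'   arity, then lexicographically by property multiset).
#' @param noise A [noise_model()].
#' @param bit Bit index in `1..B`.
#' @return Probability in `[0,1]`.
#' @export
bit_probability <- function(memberships, tensors, emission, noise, bit) {
  if (bit < 1L || bit > ncol(emission)) {
    stop("index error: bit ", bit, " outside 1..", ncol(emission))
  }
  arities <- as.integer(names(tensors))
  K <- length(memberships[[1]])
  offs <- mode_offsets_by_arity(K, arities)
  causes <- experiment_causes(memberships, tensors, arities)
  log_s <- 0
  for (cs in causes) {
    rows <- offs[as.character(cs$arity)] + seq_along(cs$comp)
    log_s <- log_s + sum(log1p(-pmin(cs$comp * emission[rows, bit], 1 - 1e-12)))
  }
  s <- -expm1(log_s)
  noise$eps_fp + (1 - noise$eps_fp - noise$eps_fn) * s
}

# full outcome-probability vector for one experiment under a theory
experiment_bit_probs <- function(theory, theta, exp_ids) {
  units <- match(exp_ids, theory$compound_ids)
  if (anyNA(units)) {
    stop("reference error: unknown compound id(s): ",
         paste(exp_ids[is.na(units)], collapse = ", "))
  }
  rows <- lapply(units, function(u)
    compound_membership_from_bits(theory$compound_bits[[u]], theta$M))
  arities <- theory$arities[theory$arities <= length(rows)]
  if (length(arities) == 0L) {
    s <- rep(0, theory$width)
  } else if (theory$width == 1L) {
    causes <- experiment_causes(rows, theta$tensors, arities)
    log_s <- sum(vapply(causes, function(cs) sum(log1p(-cs$comp)), numeric(1)))
    s <- -expm1(log_s)
  } else {
    offs <- mode_offsets_by_arity(theory$K, theory$arities)
    causes <- experiment_causes(rows, theta$tensors, arities)
    log_s <- numeric(theory$width)
    for (cs in causes) {
      rws <- offs[as.character(cs$arity)] + seq_along(cs$comp)
      E <- theta$emission[rws, , drop = FALSE]
      log_s <- log_s + colSums(log1p(-pmin(cs$comp * E, 1 - 1e-12)))
    }
    s <- -expm1(log_s)
  }
  theory$noise$eps_fp + (1 - theory$noise$eps_fp - theory$noise$eps_fn) * s
}

#' Log-likelihood of an observation log under fixed parameters
#'
#' Sum over observations and outcome bits of the Bernoulli log-probability
#' of the recorded bit under the theory's generative model. Probabilities
#' exactly 0 or 1 that conflict with the data are clamped to the likelihood
#' floor `1e-9` with a warning.
#'
#' @param log An [observation_log()].
#' @param theta Parameter list as returned by [unpack_theta()] (or a flat
#'   vector, which is unpacked).
#' @param theory A [reactivity_theory()].
#' @return Scalar log-likelihood (`<= 0`; 0 for an empty log).
#' @export
log_likelihood <- function(log, theta, theory) {
  if (is.numeric(theta)) theta <- unpack_theta(theory, theta)
  if (log$width != theory$width) {
    stop("shape error: log width ", log$width,
         " does not match theory width ", theory$width)
  }
  total <- 0
  clamped <- FALSE
  for (i in seq_along(log$experiments)) {
    p <- experiment_bit_probs(theory, theta, log$experiments[[i]])
    y <- log$outcomes[i, ]
    conflict <- (p <= 0 & y == 1L) | (p >= 1 & y == 0L)
    if (any(conflict)) clamped <- TRUE
    p <- clamp_prob(p)
    total <- total + sum(y * log(p) + (1 - y) * log1p(-p))
  }
  if (clamped) {
    warning("probability 0/1 conflicting with data; clamped at ", PROB_FLOOR)
  }
  total
}
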