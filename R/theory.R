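# Multiset / tuple machinery over property indices -------------------------
#
# A reactivity tensor of arity k over K properties is parameterized by its
# symmetric-unique entries: the multisets of size k, enumerated as
# non-decreasing index tuples in lexicographic order.

multisets <- function(K, k) {
  grids <- do.call(expand.grid, rep(list(seq_len(K)), k))
  grids <- as.matrix(grids[, rev(seq_len(k)), drop = FALSE]) # lex order
  keep <- rep(TRUE, nrow(grids))
  if (k > 1L) {
    for (j in seq_len(k - 1L)) keep <- keep & grids[, j] <= grids[, j + 1L]
  }
  m <- grids[keep, , drop = FALSE]
  dimnames(m) <- NULL
  m
}

ordered_tuples <- function(K, k) {
  g <- do.call(expand.grid, rep(list(seq_len(K)), k))
  m <- as.matrix(g[, rev(seq_len(k)), drop = FALSE])
  dimnames(m) <- NULL
  m
}

tuple_key <- function(m) apply(m, 1L, function(r) paste(sort(r), collapse = ","))

# map each ordered tuple to the index of its multiset (sorted form)
tuple_to_multiset <- function(K, k) {
  ms <- multisets(K, k)
  tp <- ordered_tuples(K, k)
  match(tuple_key(tp), apply(ms, 1L, paste, collapse = ","))
}

n_multisets <- function(K, k) choose(K + k - 1L, k)

#' Build a symmetric reactivity tensor from its unique entries
#'
#' @param K Number of abstract properties.
#' @param arity Reaction arity (2-4).
#' @param values Entries in `[0,1]` for each size-`arity` multiset of
#'   property indices, in lexicographic order of the sorted index tuple
#'   (length `choose(K + arity - 1, arity)`), or a single value recycled.
#' @return A dense symmetric array of dimension `rep(K, arity)` with class
#'   `reactivity_tensor`.
#' @export
reactivity_tensor <- function(K, arity, values = 0) {
  arity <- as.integer(arity)
  stopifnot(arity %in% 2:4, K >= 1)
  nm <- n_multisets(K, arity)
  if (length(values) == 1L) values <- rep(values, nm)
  stopifnot(length(values) == nm, all(values >= 0 & values <= 1))
  tens <- array(0, dim = rep(K, arity))
  map <- tuple_to_multiset(K, arity)
  tens[] <- values[map]
  class(tens) <- c("reactivity_tensor", class(tens))
  tens
}

tensor_arity <- function(R) length(dim(R))

tensor_unique_values <- function(R) {
  K <- dim(R)[1]
  k <- tensor_arity(R)
  ms <- multisets(K, k)
  R[ms]
}

# Prior configurations ------------------------------------------------------

#' Named prior configurations
#'
#' `"conservative-v1"` places sparse Beta(0.5, 2.5) priors on memberships,
#' heterotypic tensor entries and emission entries, encoding the Occam
#' preference for few active properties, and a more skeptical Beta(0.5, 10)
#' on homotypic (repeated-index) tensor entries, encoding the chemical
#' expectation that reactivity arises between complementary roles
#' (nucleophile/electrophile, diene/dienophile, acid/base) rather than
#' between a property and itself. `"uniform"` is flat Beta(1,1) everywhere.
#'
#' @param name Configuration name.
#' @param ... Named overrides, each a length-2 numeric `c(shape1, shape2)`;
#'   recognized names: `membership`, `tensor`, `tensor_rep`, `emission`.
#' @return A named list of Beta shape pairs.
#' @export
prior_config <- function(name = c("conservative-v1", "uniform"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "conservative-v1" = list(membership = c(0.5, 2.5),
                             tensor     = c(0.5, 2.5),
                             tensor_rep = c(0.5, 10),
                             emission   = c(0.5, 2.5)),
    "uniform" = list(membership = c(1, 1), tensor = c(1, 1),
                     tensor_rep = c(1, 1), emission = c(1, 1))
  )
  overrides <- list(...)
  if (length(overrides)) {
    stopifnot(all(names(overrides) %in% names(base)))
    base <- modifyList(base, overrides)
  }
  base$name <- name
  base
}

#' Observation noise model
#'
#' @param eps_fp False-positive rate (a bit reads 1 with no signal).
#' @param eps_fn False-negative rate (a bit reads 0 despite signal).
#' @return A `noise_model` object.
#' @export
noise_model <- function(eps_fp = 0.01, eps_fn = 0.01) {
  stopifnot(eps_fp >= 0, eps_fn >= 0, eps_fp < 0.5, eps_fn < 0.5)
  structure(list(eps_fp = eps_fp, eps_fn = eps_fn), class = "noise_model")
}

# Theory ---------------------------------------------------------------------

#' Define a generative reactivity theory over a chemical space
#'
#' A theory fixes the entity basis (compounds, or fingerprint bits for
#' structural theories), the number `K` of abstract latent properties, the
#' reaction arities modelled by symmetric reactivity tensors, the outcome
#' width (1 for binary reactive/nonreactive; `B > 1` for bit-vector outcomes
#' generated through an emission map from reactivity modes to bits), the
#' prior configuration and the observation noise rates.
#'
#' The likelihood of an experiment aggregates, by noisy-OR, the causes of
#' every sub-combination of its compounds whose size is among the modelled
#' arities, so that e.g. a reactive pair also explains reactivity of triples
#' containing it.
#'
#' @param space A [chemical_space()].
#' @param K Number of latent properties (fixed truncation; sparsity comes
#'   from the prior).
#' @param arities Modelled reaction arities, subset of `{2,3,4}`.
#' @param width Outcome vector width `B` (1 = binary).
#' @param basis `"compound"` or `"fingerprint_bit"`.
#' @param priors A [prior_config()] list or a configuration name.
#' @param noise A [noise_model()].
#' @param scheme A [fingerprint_scheme()]; required when
#'   `basis = "fingerprint_bit"`.
#' @param label Optional human-readable identifier token.
#' @param outcome_coding `"location"` (bits are chromatogram regions) or
#'   `"count"` (bits thermometer-encode the number of new peaks); purely
#'   metadata used by [reinterpret()] to transform logs.
#' @return An object of class `reactivity_theory`.
#' @export
reactivity_theory <- function(space, K = 8L, arities = space$arities,
                              width = 1L,
                              basis = c("compound", "fingerprint_bit"),
                              priors = "conservative-v1",
                              noise = noise_model(),
                              scheme = NULL, label = NULL,
                              outcome_coding = c("location", "count")) {
  basis <- match.arg(basis)
  outcome_coding <- match.arg(outcome_coding)
  if (is.character(priors)) priors <- prior_config(priors)
  arities <- check_arities(arities)
  K <- as.integer(K)
  width <- as.integer(width)
  stopifnot(K >= 1L, width >= 1L, inherits(noise, "noise_model"))
  ids <- space_ids(space)
  if (basis == "compound") {
    entities <- ids
    compound_bits <- lapply(seq_along(ids), function(i) i)
    names(compound_bits) <- ids
    fp <- NULL
  } else {
    if (is.null(scheme)) scheme <- fingerprint_scheme("morgan", 2L)
    fp <- fingerprint_basis(space, scheme)
    entities <- fp$entities
    compound_bits <- fp$compound_bits
  }
  th <- structure(
    list(label = if (is.null(label)) paste0(basis, "-K", K) else label,
         basis = basis, K = K, arities = arities, width = width,
         priors = priors, noise = noise,
         entities = entities, compound_ids = ids,
         compound_bits = compound_bits,
         scheme = if (basis == "fingerprint_bit") fp$scheme else NULL,
         fingerprint_bits = if (basis == "fingerprint_bit") fp$bits else NULL,
         outcome_coding = outcome_coding),
    class = "reactivity_theory"
  )
  th
}

#' @export
print.reactivity_theory <- function(x, ...) {
  cat("<reactivity_theory> '", x$label, "': ", length(x$entities), " ",
      x$basis, " entities, K=", x$K, ", arities {",
      paste(x$arities, collapse = ","), "}, width ", x$width, ", ",
      n_free_params(x), " free parameters\n", sep = "")
  invisible(x)
}

n_modes <- function(theory) sum(vapply(theory$arities, function(k)
  n_multisets(theory$K, k), numeric(1)))

#' Number of free scalar parameters of a theory
#' @param theory A [reactivity_theory()].
#' @return Integer count of latent scalars (memberships, unique tensor
#'   entries, emission entries).
#' @export
n_free_params <- function(theory) {
  n <- length(theory$entities) * theory$K + n_modes(theory)
  if (theory$width > 1L) n <- n + n_modes(theory) * theory$width
  as.integer(n)
}

# layout: M (entities x K, column-major) | tensors by ascending arity
# (multiset-lex) | emission (modes x B, column-major, modes ordered by
# ascending arity then multiset-lex)
param_meta <- function(theory) {
  K <- theory$K
  ne <- length(theory$entities)
  nm_k <- vapply(theory$arities, function(k) n_multisets(K, k), numeric(1))
  nmode <- sum(nm_k)
  nM <- ne * K
  offs <- list(M = 0L)
  pos <- nM
  offs$R <- list()
  rep_mask <- logical(0)
  for (i in seq_along(theory$arities)) {
    k <- theory$arities[i]
    offs$R[[as.character(k)]] <- pos
    ms <- multisets(K, k)
    rep_mask <- c(rep_mask, apply(ms, 1L, anyDuplicated) > 0)
    pos <- pos + nm_k[i]
  }
  offs$E <- if (theory$width > 1L) pos else NA_integer_
  ntot <- nM + nmode + if (theory$width > 1L) nmode * theory$width else 0L
  pr <- theory$priors
  a <- c(rep(pr$membership[1], nM),
         ifelse(rep_mask, pr$tensor_rep[1], pr$tensor[1]))
  b <- c(rep(pr$membership[2], nM),
         ifelse(rep_mask, pr$tensor_rep[2], pr$tensor[2]))
  if (theory$width > 1L) {
    a <- c(a, rep(pr$emission[1], nmode * theory$width))
    b <- c(b, rep(pr$emission[2], nmode * theory$width))
  }
  nm_names <- character(0)
  for (k in theory$arities) {
    ms <- multisets(K, k)
    nm_names <- c(nm_names,
                  paste0("R", k, "[", apply(ms, 1L, paste, collapse = ","), "]"))
  }
  pnames <- c(paste0("M[", rep(theory$entities, K), ",",
                     rep(seq_len(K), each = ne), "]"),
              nm_names)
  if (theory$width > 1L) {
    pnames <- c(pnames, paste0("E[", rep(seq_len(nmode), theory$width), ",",
                               rep(seq_len(theory$width), each = nmode), "]"))
  }
  list(n = as.integer(ntot), offsets = offs, a = a, b = b, names = pnames,
       n_modes = as.integer(nmode), nm_k = as.integer(nm_k))
}

#' Unpack a flat parameter vector into named components
#'
#' @param theory A [reactivity_theory()].
#' @param p Numeric vector of length [n_free_params()], entries in `[0,1]`.
#' @return List with `M` (entities x K matrix), `tensors` (named list of
#'   dense symmetric arrays keyed by arity) and `emission` (modes x B matrix
#'   or `NULL`).
#' @export
unpack_theta <- function(theory, p) {
  meta <- param_meta(theory)
  stopifnot(length(p) == meta$n)
  K <- theory$K; ne <- length(theory$entities)
  M <- matrix(p[seq_len(ne * K)], ne, K,
              dimnames = list(theory$entities, NULL))
  tensors <- list()
  for (i in seq_along(theory$arities)) {
    k <- theory$arities[i]
    off <- meta$offsets$R[[as.character(k)]]
    tensors[[as.character(k)]] <-
      reactivity_tensor(K, k, p[off + seq_len(meta$nm_k[i])])
  }
  emission <- NULL
  if (theory$width > 1L) {
    emission <- matrix(p[meta$offsets$E + seq_len(meta$n_modes * theory$width)],
                       meta$n_modes, theory$width)
  }
  list(M = M, tensors = tensors, emission = emission)
}

#' Pack named components into a flat parameter vector
#'
#' Inverse of [unpack_theta()].
#' @param theory A [reactivity_theory()].
#' @param theta List with `M`, `tensors`, and optionally `emission`.
#' @return Numeric vector of length [n_free_params()].
#' @export
pack_theta <- function(theory, theta) {
  p <- as.numeric(theta$M)
  for (k in theory$arities) {
    R <- theta$tensors[[as.character(k)]]
    stopifnot(!is.null(R))
    p <- c(p, tensor_unique_values(R))
  }
  if (theory$width > 1L) p <- c(p, as.numeric(theta$emission))
  p
}

#' Draw parameter vectors from a theory's prior
#'
#' @param theory A [reactivity_theory()].
#' @param n Number of draws.
#' @return An `n` x [n_free_params()] matrix on the probability scale.
#'   Uses the current R random seed.
#' @export
sample_prior <- function(theory, n) {
  meta <- param_meta(theory)
  m <- matrix(rbeta(n * meta$n, rep(meta$a, each = n), rep(meta$b, each = n)),
              n, meta$n)
  colnames(m) <- meta$names
  m
}

# canonical serializable definition (content-addressing, persistence)
theory_definition <- function(theory) {
  list(
    label = theory$label,
    basis = theory$basis,
    K = theory$K,
    arities = as.integer(theory$arities),
    width = theory$width,
    priors = theory$priors[sort(names(theory$priors))],
    noise = list(eps_fp = theory$noise$eps_fp, eps_fn = theory$noise$eps_fn),
    entities = theory$entities,
    compound_ids = theory$compound_ids,
    compound_bits = theory$compound_bits[sort(names(theory$compound_bits))],
    scheme = if (is.null(theory$scheme)) NULL else
      list(name = theory$scheme$name, radius = theory$scheme$radius,
           nbits = theory$scheme$nbits),
    outcome_coding = theory$outcome_coding
  )
}
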