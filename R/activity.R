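#' Count the abstract properties used to explain observed reactivity
#'
#' Implements the minimal-explanation readout for binary pairwise
#' posteriors: per posterior draw, each reactive observation is attributed
#' to its maximal cause, the ordered property pair `(I, J)` maximizing
#' `M[a, I] * M[b, J] * R[I, J]`, provided that cause exceeds a small
#' relevance floor. The properties participating in at least one maximal
#' cause are the draw's active set; properties occupying a slot held by
#' `compound` are "on" that compound (e.g. the diene and dienophile
#' characters of cyclopentadiene). Counting per draw and summarizing by the
#' median keeps the statistic invariant under label switching.
#'
#' @param posterior A `reactivity_posterior` of a binary arity-2 theory.
#' @param log The fitted [observation_log()]; only its reactive rows enter
#'   the count.
#' @param compound Optional compound id whose carried properties are also
#'   counted.
#' @param floor Relevance floor on the maximal cause (default 0.01); draws
#'   in which an observation has no cause above the floor skip it.
#' @param max_draws Subsample cap on draws for speed.
#' @return List with `total` (median count over draws), `per_draw`, and
#'   when `compound` is given `on_compound` / `on_compound_per_draw`.
#' @export
active_properties <- function(posterior, log, compound = NULL, floor = 0.01,
                              max_draws = 1000L) {
  theory <- posterior$theory
  stopifnot(theory$width == 1L, 2L %in% theory$arities)
  K <- theory$K
  ne <- length(theory$entities)
  draws <- posterior$draws
  if (nrow(draws) > max_draws) {
    draws <- draws[seq(1L, nrow(draws), length.out = max_draws), ,
                   drop = FALSE]
  }
  meta <- param_meta(theory)
  roff <- meta$offsets$R[["2"]]
  ms2 <- multisets(K, 2L)
  reactive <- which(rowSums(log$outcomes) > 0)
  pairs <- lapply(log$experiments[reactive],
                  function(e) match(e, theory$compound_ids))
  cidx <- if (!is.null(compound)) match(compound, theory$compound_ids) else NA
  n_total <- integer(nrow(draws))
  n_on <- integer(nrow(draws))
  for (d in seq_len(nrow(draws))) {
    M <- matrix(draws[d, seq_len(ne * K)], ne, K)
    R <- matrix(0, K, K)
    R[ms2] <- draws[d, roff + seq_len(nrow(ms2))]
    R[ms2[, c(2, 1), drop = FALSE]] <- draws[d, roff + seq_len(nrow(ms2))]
    props <- integer(0); props_on <- integer(0)
    for (pr in pairs) {
      C1 <- outer(M[pr[1], ], M[pr[2], ]) * R # slot 1 carries I, slot 2 J
      if (max(C1) < floor) next
      ij <- arrayInd(which.max(C1), dim(C1))
      props <- union(props, c(ij[1], ij[2]))
      if (!is.na(cidx)) {
        if (pr[1] == cidx) props_on <- union(props_on, ij[1])
        if (pr[2] == cidx) props_on <- union(props_on, ij[2])
      }
    }
    n_total[d] <- length(props)
    n_on[d] <- length(props_on)
  }
  out <- list(total = as.integer(median(n_total)), per_draw = n_total)
  if (!is.na(cidx)) {
    out$on_compound <- as.integer(median(n_on))
    out$on_compound_per_draw <- n_on
  }
  out
}
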