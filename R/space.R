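#' Define a compound
#'
#' A compound is the atomic unit of a chemical space: a short unique id,
#' a human-readable name, and optionally a SMILES structure from which
#' molecular fingerprints can be derived.
#'
#' @param id Short unique token identifying the compound within a space.
#' @param name Free-text name; defaults to the id.
#' @param smiles Optional SMILES string.
#' @param self_reactive Logical; if `TRUE` the compound may be combined with
#'   itself (a size-2 multiset experiment), e.g. a diene capable of
#'   dimerization. Default `FALSE`.
#' @return An object of class `compound`.
#' @export
compound <- function(id, name = id, smiles = NULL, self_reactive = FALSE) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  if (!is.null(smiles)) stopifnot(is.character(smiles), length(smiles) == 1L)
  structure(
    list(id = id, name = name, smiles = smiles,
         self_reactive = isTRUE(self_reactive), fingerprint = NULL),
    class = "compound"
  )
}

#' Define a chemical space
#'
#' A chemical space is a roster of compounds together with the reaction
#' arities (2 to 4 components) considered when enumerating candidate
#' experiments.
#'
#' @param compounds List of [compound()] objects (at least two, unique ids).
#' @param arities Integer vector, a non-empty subset of `2:4`.
#' @return An object of class `chemical_space`.
#' @export
chemical_space <- function(compounds, arities = 2L) {
  stopifnot(is.list(compounds), length(compounds) >= 2L)
  ok <- vapply(compounds, inherits, logical(1), "compound")
  if (!all(ok)) stop("all elements of `compounds` must be compound objects")
  ids <- vapply(compounds, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate compound id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  arities <- check_arities(arities)
  names(compounds) <- ids
  structure(list(compounds = compounds, arities = arities),
            class = "chemical_space")
}

#' @export
print.chemical_space <- function(x, ...) {
  cat("<chemical_space> ", length(x$compounds), " compounds, arities {",
      paste(x$arities, collapse = ","), "}\n", sep = "")
  invisible(x)
}

space_ids <- function(space) names(space$compounds)

check_arities <- function(arities) {
  arities <- sort(unique(as.integer(arities)))
  if (length(arities) == 0L || !all(arities %in% 2:4)) {
    stop("invalid arity: arities must be a non-empty subset of {2,3,4}")
  }
  arities
}

#' Canonical key of an experiment
#'
#' Experiments are unordered (multi)sets of compound ids; the canonical form
#' is the lexicographically sorted id tuple joined by `+`. Two experiments
#' with equal sets share a key regardless of listing order.
#'
#' @param ids Character vector of compound ids (duplicates only for
#'   self-combinations).
#' @return A single string key.
#' @export
experiment_key <- function(ids) {
  paste(sort_c(ids), collapse = "+")
}

# locale-independent sort so canonical order is platform-stable
sort_c <- function(x) sort(x, method = "radix")

#' Enumerate the combinatorial experiment space
#'
#' Returns all unordered compound subsets of each requested size in a
#' deterministic canonical order (by arity, then lexicographically by the
#' sorted id tuple). Self-combinations (a compound with itself) are excluded
#' by default and included as size-2 multisets only for compounds flagged
#' `self_reactive` when `include_self = TRUE`.
#'
#' @param space A [chemical_space()].
#' @param arities Subset of `{2,3,4}`; defaults to the space's arities.
#' @param include_self Include size-2 self-pairs for self-reactive compounds.
#' @return A list of experiments, each a sorted character vector of ids.
#' @export
enumerate_experiments <- function(space, arities = space$arities,
                                  include_self = FALSE) {
  arities <- check_arities(arities)
  ids <- sort_c(space_ids(space))
  out <- list()
  for (k in arities) {
    if (length(ids) >= k) {
      sets <- combn(ids, k, simplify = FALSE)
      out <- c(out, sets)
    } # arity exceeding the roster contributes nothing
  }
  if (include_self && 2L %in% arities) {
    selfs <- ids[vapply(space$compounds[ids], `[[`, logical(1),
                        "self_reactive")]
    out <- c(out, lapply(selfs, function(id) c(id, id)))
  }
  keys <- vapply(out, experiment_key, character(1))
  out[order(lengths(out), keys, method = "radix")]
}

#' Assemble an observation log
#'
#' An observation log pairs experiments with fixed-width reactivity
#' vectors and a unique exploration-order index.
#'
#' @param experiments List of character vectors of compound ids.
#' @param outcomes Integer matrix (`n x width`) of 0/1 entries, or a vector
#'   for binary (width-1) logs.
#' @param order Non-negative integer exploration indices; defaults to
#'   `0:(n-1)`.
#' @return An object of class `observation_log`.
#' @export
observation_log <- function(experiments, outcomes,
                            order = seq_along(experiments) - 1L) {
  if (!is.matrix(outcomes)) outcomes <- matrix(as.integer(outcomes), ncol = 1L)
  storage.mode(outcomes) <- "integer"
  n <- length(experiments)
  stopifnot(nrow(outcomes) == n, length(order) == n)
  if (n > 0 && !all(outcomes %in% c(0L, 1L))) {
    stop("format error: outcome entries must be 0 or 1")
  }
  order <- as.integer(order)
  if (anyDuplicated(order)) stop("order indices must be unique within a log")
  if (n > 0 && any(order < 0L)) stop("order indices must be non-negative")
  experiments <- lapply(experiments, function(e) sort_c(as.character(e)))
  o <- base::order(order)
  structure(
    list(experiments = experiments[o],
         outcomes = outcomes[o, , drop = FALSE],
         order = order[o],
         width = ncol(outcomes)),
    class = "observation_log"
  )
}

#' @export
print.observation_log <- function(x, ...) {
  cat("<observation_log> ", length(x$experiments), " observations, width ",
      x$width, "\n", sep = "")
  invisible(x)
}

#' @export
length.observation_log <- function(x) length(x$experiments)

log_subset <- function(log, idx) {
  observation_log(log$experiments[idx],
                  log$outcomes[idx, , drop = FALSE],
                  log$order[idx])
}

bits_to_string <- function(bits) paste(as.integer(bits), collapse = "")

string_to_bits <- function(s) {
  v <- suppressWarnings(as.integer(strsplit(s, "")[[1]]))
  if (any(is.na(v)) || !all(v %in% c(0L, 1L))) {
    stop("format error: outcome strings must consist of 0/1 digits")
  }
  v
}

validate_log_against_space <- function(log, space) {
  known <- space_ids(space)
  for (e in log$experiments) {
    bad <- setdiff(unique(e), known)
    if (length(bad)) {
      stop("reference error: unknown compound id(s): ",
           paste(bad, collapse = ", "))
    }
  }
  invisible(TRUE)
}

#' Read an observation log from CSV or JSON
#'
#' The CSV dialect has a header row with columns `order`, `compound_ids`
#' (ids joined by `;`) and `outcome` (a contiguous 0/1 string such as
#' `"00000010"`). The JSON form is an array of objects with the same fields
#' (with `compound_ids` an array). All referenced compound ids must be
#' declared in `space` and all outcome strings must share one width.
#'
#' @param path File path.
#' @param space A [chemical_space()] used for id validation, or `NULL` to
#'   skip validation.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return An [observation_log()].
#' @export
load_observations <- function(path, space = NULL, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "csv") {
    df <- read.csv(path, colClasses = "character")
    need <- c("order", "compound_ids", "outcome")
    if (!all(need %in% names(df))) {
      stop("format error: CSV must have columns ",
           paste(need, collapse = ", "))
    }
    exps <- strsplit(df$compound_ids, ";", fixed = TRUE)
    outs <- df$outcome
    ords <- as.integer(df$order)
  } else {
    rows <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    exps <- lapply(rows, function(r) unlist(r$compound_ids))
    outs <- vapply(rows, function(r) as.character(r$outcome), character(1))
    ords <- vapply(rows, function(r) as.integer(r$order), integer(1))
  }
  widths <- nchar(outs)
  if (length(unique(widths)) > 1L) {
    stop("format error: inconsistent outcome widths: ",
         paste(unique(widths), collapse = ", "))
  }
  outcomes <- if (length(outs)) {
    do.call(rbind, lapply(outs, string_to_bits))
  } else matrix(integer(0), 0, 1)
  log <- observation_log(exps, outcomes, ords)
  if (!is.null(space)) validate_log_against_space(log, space)
  log
}

#' Write an observation log to CSV or JSON
#'
#' Inverse of [load_observations()]; the round-trip is bit-exact.
#'
#' @param log An [observation_log()].
#' @param path Destination path.
#' @param format `"csv"`, `"json"`, or `"auto"` (by extension).
#' @return `path`, invisibly.
#' @export
write_observations <- function(log, path, format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "csv") {
    df <- data.frame(
      order = log$order,
      compound_ids = vapply(log$experiments, paste, character(1),
                            collapse = ";"),
      outcome = apply(log$outcomes, 1L, bits_to_string)
    )
    write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    rows <- lapply(seq_along(log$experiments), function(i) {
      list(order = log$order[i],
           compound_ids = as.list(log$experiments[[i]]),
           outcome = bits_to_string(log$outcomes[i, ]))
    })
    jsonlite::write_json(rows, path, auto_unbox = TRUE)
  }
  invisible(path)
}

#' Write a chemical space definition to JSON
#'
#' @param space A [chemical_space()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_space <- function(space, path) {
  obj <- list(
    compounds = lapply(space$compounds, function(cp) {
      out <- list(id = cp$id, name = cp$name)
      if (!is.null(cp$smiles)) out$smiles <- cp$smiles
      if (cp$self_reactive) out$self_reactive <- TRUE
      out
    }),
    arities = as.list(space$arities)
  )
  names(obj$compounds) <- NULL
  jsonlite::write_json(obj, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read a chemical space definition from JSON
#'
#' @param path File path.
#' @return A [chemical_space()].
#' @export
load_space <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  comps <- lapply(obj$compounds, function(cp) {
    compound(id = cp$id,
             name = if (is.null(cp$name)) cp$id else cp$name,
             smiles = cp$smiles,
             self_reactive = isTRUE(cp$self_reactive))
  })
  chemical_space(comps, arities = unlist(obj$arities))
}
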