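#' Fingerprint scheme specification
#'
#' @param name `"maccs"` (166-key substructure patterns, stored in a 256-bit
#'   block) or `"morgan"` (extended-connectivity / circular fingerprint).
#' @param radius Morgan radius (ignored for MACCS). OpenBabel's ECFP
#'   implementation provides radii 1-3 (ECFP2/4/6).
#' @param nbits Fold the bit-set into this many bits (`NULL` = native width).
#' @return A `fingerprint_scheme` object.
#' @export
fingerprint_scheme <- function(name = c("maccs", "morgan"), radius = 2L,
                               nbits = NULL) {
  name <- match.arg(name)
  if (name == "morgan" && !radius %in% 1:3) {
    stop("morgan radius must be 1, 2 or 3")
  }
  structure(list(name = name, radius = as.integer(radius), nbits = nbits),
            class = "fingerprint_scheme")
}

ob_fp_name <- function(scheme) {
  if (scheme$name == "maccs") "MACCS" else paste0("ECFP", 2L * scheme$radius)
}

fold_bits <- function(bits, nbits) {
  if (is.null(nbits)) return(bits)
  sort(unique(((bits - 1L) %% as.integer(nbits)) + 1L))
}

#' Compute molecular fingerprints for a set of compounds
#'
#' Annotates each compound with the set bit indices (1-based) of its
#' fingerprint under the requested scheme, computed with OpenBabel through
#' the ChemmineOB package. The union of set bits over a space defines the
#' fingerprint-bit entity basis of structural theories.
#'
#' @param compounds List of [compound()] objects, each with a parseable
#'   SMILES structure.
#' @param scheme A [fingerprint_scheme()].
#' @return The list of compounds with `$fingerprint` (integer vector of set
#'   bit indices) and `$fingerprint_scheme` filled in.
#' @export
compute_fingerprints <- function(compounds, scheme = fingerprint_scheme("maccs")) {
  if (!requireNamespace("ChemmineOB", quietly = TRUE)) {
    stop("compute_fingerprints requires the ChemmineOB package")
  }
  stopifnot(inherits(scheme, "fingerprint_scheme"))
  fpname <- ob_fp_name(scheme)
  lapply(compounds, function(cp) {
    if (is.null(cp$smiles) || !nzchar(cp$smiles)) {
      stop("structure error: compound '", cp$id, "' has no structure")
    }
    bits <- tryCatch({
      mol <- ChemmineOB::forEachMol("SMILES", cp$smiles, identity)
      v <- ChemmineOB::fingerprint_OB(mol, fpname)
      which(v != 0)
    }, error = function(e) {
      stop("structure error: compound '", cp$id,
           "' has unparseable structure: ", conditionMessage(e),
           call. = FALSE)
    })
    cp$fingerprint <- fold_bits(as.integer(bits), scheme$nbits)
    cp$fingerprint_scheme <- scheme
    cp
  })
}

#' Fingerprint-bit entity basis of a space
#'
#' Computes fingerprints for every compound in the space and returns the
#' basis: the sorted union of set bits, plus the per-compound bit sets
#' expressed as indices into that basis.
#'
#' @param space A [chemical_space()] whose compounds carry SMILES.
#' @param scheme A [fingerprint_scheme()].
#' @return List with `bits` (sorted integer vector of raw bit indices),
#'   `entities` (character tokens naming each basis bit) and
#'   `compound_bits` (named list: compound id -> indices into `entities`).
#' @export
fingerprint_basis <- function(space, scheme = fingerprint_scheme("morgan", 2L)) {
  comps <- compute_fingerprints(space$compounds, scheme)
  all_bits <- sort(unique(unlist(lapply(comps, `[[`, "fingerprint"))))
  entities <- paste0("bit", all_bits)
  compound_bits <- lapply(comps, function(cp) match(cp$fingerprint, all_bits))
  names(compound_bits) <- vapply(comps, `[[`, character(1), "id")
  list(bits = all_bits, entities = entities, compound_bits = compound_bits,
       scheme = scheme)
}
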