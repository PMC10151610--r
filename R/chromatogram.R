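#' A chromatogram peak list
#'
#' @param rt Retention times in minutes, non-negative and strictly
#'   increasing.
#' @param intensity Relative intensities in `(0, 1]`.
#' @return A `peak_list` data frame.
#' @export
peak_list <- function(rt, intensity = rep(1, length(rt))) {
  rt <- as.numeric(rt); intensity <- as.numeric(intensity)
  stopifnot(length(rt) == length(intensity))
  if (length(rt)) {
    if (any(rt < 0)) stop("retention times must be non-negative")
    if (any(diff(rt) <= 0)) stop("retention times must be strictly increasing")
    if (any(intensity <= 0) || any(intensity > 1)) {
      stop("intensities must lie in (0, 1]")
    }
  }
  structure(data.frame(rt = rt, intensity = intensity),
            class = c("peak_list", "data.frame"))
}

#' Default retention-time bin edges
#'
#' Eight equal-width regions spanning the chromatogram window, matching the
#' 8-digit reactivity vectors of the named-reaction panel.
#'
#' @param window Length-2 numeric window in minutes.
#' @param n Number of regions.
#' @return Numeric vector of `n + 1` strictly increasing edges.
#' @export
default_bins <- function(window = c(0, 8), n = 8L) {
  seq(window[1], window[2], length.out = n + 1L)
}

#' Reactivity vector from reactant and product chromatograms
#'
#' Bins product retention times into regions and records, per region,
#' whether the product mixture shows at least one peak not present in any
#' reactant reference (no reactant peak within `match_tol` minutes of its
#' retention time). Peaks outside all bins are ignored; an empty product
#' peak list yields the all-zero vector.
#'
#' @param reactants List of [peak_list()]s (the pre-reaction references).
#' @param product A [peak_list()] of the final reaction mixture.
#' @param bins Strictly increasing bin edges; width = `length(bins) - 1`.
#' @param match_tol Retention-time matching tolerance in minutes.
#' @return Integer 0/1 vector of length `length(bins) - 1`.
#' @export
reactivity_vector_from_chromatograms <- function(reactants, product,
                                                 bins = default_bins(),
                                                 match_tol = 0.1) {
  stopifnot(all(diff(bins) > 0))
  width <- length(bins) - 1L
  v <- integer(width)
  if (nrow(product) == 0L) return(v)
  ref_rt <- unlist(lapply(reactants, function(p) p$rt))
  for (i in seq_len(nrow(product))) {
    rt <- product$rt[i]
    if (rt < bins[1] || rt > bins[width + 1L]) next
    b <- min(max(findInterval(rt, bins, rightmost.closed = TRUE), 1L), width)
    new_peak <- length(ref_rt) == 0L || min(abs(ref_rt - rt)) > match_tol
    if (new_peak) v[b] <- 1L
  }
  v
}

#' Write peak lists to CSV (time, intensity pairs)
#'
#' @param peaks A [peak_list()].
#' @param path Destination path.
#' @return `path`, invisibly.
#' @export
write_peaks <- function(peaks, path) {
  write.csv(as.data.frame(peaks), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a peak list from CSV
#'
#' @param path File with columns `rt` and `intensity`.
#' @return A [peak_list()].
#' @export
load_peaks <- function(path) {
  df <- read.csv(path)
  peak_list(df$rt, df$intensity)
}
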