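#' Geological stage bins
#'
#' A set of contiguous, non-overlapping time bins ordered from oldest to
#' youngest, used to discretise fossil ages, to place fixed rate shifts and
#' to define piecewise preservation rates. Ages are in Ma before present
#' (larger = older) throughout the package.
#'
#' @param boundaries Numeric vector of bin boundaries in Ma, strictly
#'   decreasing (oldest first). `length(boundaries) - 1` bins are created.
#' @param labels Optional character vector of bin labels, one per bin.
#' @return An object of class `stage_bins`: a data frame with columns
#'   `label`, `max_age`, `min_age` (one row per bin, oldest first).
#' @examples
#' stage_bins(c(260, 255, 250), c("older", "younger"))
#' @export
stage_bins <- function(boundaries, labels = NULL) {
  boundaries <- as.numeric(boundaries)
  if (length(boundaries) < 2L) stop("need at least two boundaries")
  if (any(!is.finite(boundaries)) || any(diff(boundaries) >= 0)) {
    stop("boundaries must be finite and strictly decreasing (Ma, oldest first)")
  }
  if (boundaries[length(boundaries)] < 0) stop("boundaries must be positive ages (Ma)")
  n <- length(boundaries) - 1L
  if (is.null(labels)) labels <- paste0("bin", seq_len(n))
  if (length(labels) != n) stop("need one label per bin")
  out <- data.frame(label = as.character(labels),
                    max_age = boundaries[-length(boundaries)],
                    min_age = boundaries[-1],
                    stringsAsFactors = FALSE)
  class(out) <- c("stage_bins", "data.frame")
  out
}

#' Permian and Triassic stage bins (ICS 2022/02)
#'
#' Boundary ages of the Permian and Triassic stages following the
#' International Chronostratigraphic Chart v2022/02, from the base of the
#' Asselian (298.9 Ma) to the top of the Rhaetian (201.36 Ma). Shipped as a
#' packaged default; any [stage_bins()] object can be supplied instead.
#'
#' @return A `stage_bins` object with 16 stages.
#' @export
permo_triassic_bins <- function() {
  stage_bins(
    boundaries = c(298.9, 293.52, 290.1, 283.5, 273.01, 266.9, 264.28,
                   259.51, 254.14, 251.902, 251.2, 247.2, 242.0, 237.0,
                   227.0, 208.5, 201.36),
    labels = c("Asselian", "Sakmarian", "Artinskian", "Kungurian", "Roadian",
               "Wordian", "Capitanian", "Wuchiapingian", "Changhsingian",
               "Induan", "Olenekian", "Anisian", "Ladinian", "Carnian",
               "Norian", "Rhaetian"))
}

# boundary vector (descending, length nbins+1) of a stage_bins object
bin_edges <- function(bins) c(bins$max_age, bins$min_age[nrow(bins)])

#' @export
print.stage_bins <- function(x, ...) {
  cat(sprintf("Stage bins: %d bins spanning %.3f-%.3f Ma\n",
              nrow(x), x$max_age[1], x$min_age[nrow(x)]))
  print.data.frame(x, ...)
  invisible(x)
}

# index of the bin containing age t (max_age >= t > min_age; the oldest bin
# is closed on both ends). NA outside coverage.
bin_of_age <- function(t, bins) {
  edges <- bin_edges(bins)
  idx <- findInterval(-t, -edges, left.open = TRUE)
  idx[t == edges[1]] <- 1L
  idx[idx < 1L | idx > nrow(bins)] <- NA_integer_
  idx
}

# overlap length of interval [lo_age, hi_age] (hi older) with each bin; rows
# = intervals, cols = bins
bin_overlap <- function(lo, hi, bins) {
  mx <- matrix(rep(bins$max_age, each = length(lo)), nrow = length(lo))
  mn <- matrix(rep(bins$min_age, each = length(lo)), nrow = length(lo))
  pmax(pmin(mx, hi) - pmax(mn, lo), 0)
}
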