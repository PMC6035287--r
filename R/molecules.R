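# Single-molecule intensity counting: spot intensities normalized by the
# mean single-molecule intensity measured in an adjacent chamber.

#' Count molecules from spot intensities
#'
#' Divides each spot intensity by the mean of the single-molecule reference
#' intensities and bins the resulting molecule counts into a histogram.
#'
#' @param spot_intensities spot intensities (a.u.).
#' @param reference_intensities single-molecule reference intensities
#'   (a.u.); their mean must be positive.
#' @param bin_width histogram bin width in molecules (default 1).
#' @return a `molecule_counts` list: `counts` (per spot), `mean_reference`,
#'   `histogram` (`hist` object), `mode` (modal bin center).
#' @export
count_molecules <- function(spot_intensities, reference_intensities,
                            bin_width = 1) {
  stopifnot(length(reference_intensities) > 0, length(spot_intensities) > 0,
            bin_width > 0)
  mref <- mean(reference_intensities)
  if (!is.finite(mref) || mref <= 0)
    stop("mean reference intensity must be positive")
  counts <- spot_intensities / mref
  breaks <- seq(0, (floor(max(counts) / bin_width) + 1) * bin_width,
                by = bin_width)
  h <- graphics::hist(counts, breaks = breaks, plot = FALSE)
  structure(list(counts = counts, mean_reference = mref, histogram = h,
                 mode = h$mids[which.max(h$counts)]),
            class = "molecule_counts")
}

#' @export
print.molecule_counts <- function(x, ...) {
  cat(sprintf(
    "molecule_counts: %d spots, mean %.2f molecules, modal bin %.2g\n",
    length(x$counts), mean(x$counts), x$mode))
  invisible(x)
}

#' @export
plot.molecule_counts <- function(x, ...) {
  graphics::plot(x$histogram, xlab = "molecules per spot", main = "", ...)
  invisible(x)
}
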