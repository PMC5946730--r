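#' Evaluation grid in stimulus-size x retinotopic-offset space
#'
#' The model describes every cell class by a population rate surface
#' f(s, r): s is the drifting-grating diameter (degrees of visual angle,
#' covering 0--60), r the radial distance between a cell's receptive-field
#' center and the stimulus center.  Circular symmetry is assumed throughout,
#' so only the radial offset axis is represented.
#'
#' @param sizes strictly increasing stimulus diameters (degrees); must span
#'   0 to at least 60.
#' @param offsets strictly increasing radial offsets (degrees), starting at 0
#'   and reaching at least 33 (the outer edge of the fitting domain).
#' @param step quadrature step (degrees) used when convolving fields with
#'   retinotopic kernels.
#' @return an object of class `space_grid`.
#' @export
space_grid <- function(sizes = c(0, 5, 10, 15, 20, 25, 30, 36, 42, 50, 60),
                       offsets = seq(0, 60, by = 3),
                       step = 1) {
  sizes <- as.numeric(sizes); offsets <- as.numeric(offsets)
  if (any(diff(sizes) <= 0) || any(diff(offsets) <= 0))
    stop_nf("space_grid: axes must be strictly increasing")
  if (min(sizes) > 0 || max(sizes) < 60)
    stop_nf("space_grid: sizes must cover [0, 60] degrees")
  if (min(offsets) > 0 || max(offsets) < 33)
    stop_nf("space_grid: offsets must cover [0, 33] degrees")
  if (step <= 0) stop_nf("space_grid: step must be positive")
  structure(list(sizes = sizes, offsets = offsets, step = step),
            class = "space_grid")
}

#' @export
print.space_grid <- function(x, ...) {
  cat(sprintf("space_grid: %d sizes in [%g, %g] deg, %d offsets in [%g, %g] deg, step %g deg\n",
              length(x$sizes), min(x$sizes), max(x$sizes),
              length(x$offsets), min(x$offsets), max(x$offsets), x$step))
  invisible(x)
}
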