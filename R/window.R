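#' Rectangular observation window
#'
#' A closed axis-aligned rectangle, in meters, holding a plant population.
#'
#' @param xmax,ymax Upper coordinates in meters.
#' @param xmin,ymin Lower coordinates in meters (default 0).
#' @return An object of class \code{pcqm_window}.
#' @examples
#' w <- pcqm_window(xmax = 100, ymax = 100)
#' window_area(w)  # 10000 m^2, i.e. one hectare
#' @export
pcqm_window <- function(xmax, ymax, xmin = 0, ymin = 0) {
  vals <- c(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax)
  if (!all(is.finite(vals))) {
    abort_pcqm("invalid_spec", "window coordinates must be finite numbers")
  }
  if (xmax <= xmin || ymax <= ymin) {
    abort_pcqm("invalid_spec",
               "window must satisfy xmax > xmin and ymax > ymin")
  }
  structure(list(xmin = xmin, xmax = xmax, ymin = ymin, ymax = ymax),
            class = "pcqm_window")
}

#' @rdname pcqm_window
#' @param window A \code{pcqm_window}.
#' @export
window_area <- function(window) {
  stopifnot(inherits(window, "pcqm_window"))
  (window$xmax - window$xmin) * (window$ymax - window$ymin)
}

#' @export
print.pcqm_window <- function(x, ...) {
  cat(sprintf("window: [%g, %g] x [%g, %g] m (area %g m^2)\n",
              x$xmin, x$xmax, x$ymin, x$ymax, window_area(x)))
  invisible(x)
}

# TRUE for coordinates inside or on the boundary (window is closed).
in_window <- function(window, x, y) {
  x >= window$xmin & x <= window$xmax & y >= window$ymin & y <= window$ymax
}

# Interior rectangle after trimming `fraction` of each dimension's extent
# from each of the four edges (fraction 0.10 keeps the central 80% x 80%).
shrink_window <- function(window, fraction) {
  if (!is.finite(fraction) || fraction < 0 || fraction >= 0.5) {
    abort_pcqm("invalid_spec",
               "boundary fraction must lie in [0, 0.5): the trimmed interior must have positive area")
  }
  dx <- (window$xmax - window$xmin) * fraction
  dy <- (window$ymax - window$ymin) * fraction
  pcqm_window(xmin = window$xmin + dx, xmax = window$xmax - dx,
              ymin = window$ymin + dy, ymax = window$ymax - dy)
}
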