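#' Point pattern of plant positions
#'
#' Bundles tree coordinates (meters) with their observation window. The
#' pattern's density, \code{true_density()}, is the quantity the PCQM
#' estimators target, reported in stems per hectare.
#'
#' @param x,y Numeric coordinate vectors of equal length, in meters.
#' @param window A \code{\link{pcqm_window}} containing every point.
#' @return An object of class \code{point_pattern} with elements \code{x},
#'   \code{y}, \code{n} and \code{window}.
#' @examples
#' w <- pcqm_window(10, 10)
#' p <- point_pattern(c(2, 5, 8), c(1, 5, 9), w)
#' true_density(p)  # 3 trees on 100 m^2 = 300 per hectare
#' @export
point_pattern <- function(x, y, window) {
  stopifnot(inherits(window, "pcqm_window"))
  x <- as.double(x); y <- as.double(y)
  if (length(x) != length(y)) {
    abort_pcqm("invalid_spec", "x and y must have equal length")
  }
  if (anyNA(x) || anyNA(y) || any(!is.finite(c(x, y)))) {
    abort_pcqm("invalid_spec", "coordinates must be finite and non-missing")
  }
  out <- !in_window(window, x, y)
  if (any(out)) {
    abort_pcqm("invalid_spec",
               sprintf("%d point(s) lie outside the window (first: #%d at (%g, %g))",
                       sum(out), which(out)[1], x[which(out)[1]], y[which(out)[1]]))
  }
  structure(list(x = x, y = y, n = length(x), window = window),
            class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern A \code{point_pattern}.
#' @return \code{true_density()}: stems per hectare (count / area * 10^4).
#' @export
true_density <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  pattern$n / window_area(pattern$window) * 1e4
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("point pattern: %d trees, %g stems/ha\n", x$n, true_density(x)))
  print(x$window)
  invisible(x)
}

#' Specification of a simulated plant assemblage
#'
#' Describes one virtual population: completely random (binomial process),
#' aggregated (a fraction of the stems placed in circular clusters, the rest
#' uniform), or regular (simple sequential inhibition with a hard minimum
#' spacing).
#'
#' @param kind One of \code{"random"}, \code{"aggregated"}, \code{"regular"}.
#' @param n Number of trees to place (>= 1).
#' @param window A \code{\link{pcqm_window}}.
#' @param cluster_radius Aggregated only: radius in meters of each cluster
#'   disc (> 0).
#' @param intensity Aggregated only: fraction in [0, 1] of the population
#'   that is placed inside clusters.
#' @param mean_cluster_size Aggregated only: expected number of trees per
#'   cluster; the cluster count is \code{max(1, round(intensity * n /
#'   mean_cluster_size))}. Default 10.
#' @param repulsion Regular only: minimum distance in meters allowed between
#'   any two trees (>= 0).
#' @param seed Optional RNG seed; identical spec + seed reproduces the
#'   pattern exactly.
#' @return An object of class \code{pattern_spec}.
#' @seealso \code{\link{generate_pattern}}
#' @export
pattern_spec <- function(kind = c("random", "aggregated", "regular"), n,
                         window, cluster_radius = NULL, intensity = NULL,
                         mean_cluster_size = 10, repulsion = NULL,
                         seed = NULL) {
  kind <- match.arg(kind)
  stopifnot(inherits(window, "pcqm_window"))
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1) {
    abort_pcqm("invalid_spec", "n must be a single number >= 1")
  }
  n <- as.integer(round(n))
  if (kind == "aggregated") {
    if (is.null(cluster_radius) || !is.finite(cluster_radius) ||
        cluster_radius <= 0) {
      abort_pcqm("invalid_spec",
                 "aggregated patterns need cluster_radius > 0 (meters)")
    }
    if (is.null(intensity) || !is.finite(intensity) ||
        intensity < 0 || intensity > 1) {
      abort_pcqm("invalid_spec",
                 "aggregated patterns need intensity in [0, 1]")
    }
    if (!is.finite(mean_cluster_size) || mean_cluster_size <= 0) {
      abort_pcqm("invalid_spec", "mean_cluster_size must be > 0")
    }
  } else if (!is.null(cluster_radius) || !is.null(intensity)) {
    abort_pcqm("invalid_spec",
               "cluster_radius/intensity apply only to kind = \"aggregated\"")
  }
  if (kind == "regular") {
    if (is.null(repulsion) || !is.finite(repulsion) || repulsion < 0) {
      abort_pcqm("invalid_spec",
                 "regular patterns need repulsion >= 0 (meters)")
    }
  } else if (!is.null(repulsion)) {
    abort_pcqm("invalid_spec", "repulsion applies only to kind = \"regular\"")
  }
  structure(list(kind = kind, n = n, window = window,
                 cluster_radius = cluster_radius, intensity = intensity,
                 mean_cluster_size = mean_cluster_size,
                 repulsion = repulsion, seed = seed),
            class = "pattern_spec")
}

#' Generate a simulated plant assemblage
#'
#' Realizes a \code{\link{pattern_spec}} as a \code{\link{point_pattern}}
#' with exactly \code{spec$n} trees. \code{generate_random()},
#' \code{generate_aggregated()} and \code{generate_regular()} are the
#' kind-specific entry points; \code{generate_pattern()} dispatches on
#' \code{spec$kind}.
#'
#' The aggregated generator places \code{round(intensity * n)} offspring
#' uniformly on discs of radius \code{cluster_radius} around uniformly
#' located cluster centres (offspring falling outside the window are
#' redrawn, not clipped) and the remaining trees uniformly over the window.
#' The regular generator uses simple sequential inhibition and fails with a
#' packing-failure error after \code{1000 * n} consecutive rejected
#' proposals.
#'
#' @param spec A \code{\link{pattern_spec}}.
#' @return A \code{\link{point_pattern}} with exactly \code{spec$n} points.
#' @examples
#' w <- pcqm_window(100, 100)
#' p <- generate_random(pattern_spec("random", 500, w, seed = 1))
#' clark_evans_index(p)
#' @export
generate_pattern <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  switch(spec$kind,
         random = generate_random(spec),
         aggregated = generate_aggregated(spec),
         regular = generate_regular(spec))
}

#' @rdname generate_pattern
#' @export
generate_random <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "random") {
    abort_pcqm("invalid_spec", "generate_random() needs kind = \"random\"")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$window
  point_pattern(runif(spec$n, w$xmin, w$xmax),
                runif(spec$n, w$ymin, w$ymax), w)
}

#' @rdname generate_pattern
#' @export
generate_aggregated <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "aggregated") {
    abort_pcqm("invalid_spec",
               "generate_aggregated() needs kind = \"aggregated\"")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$window
  n_clustered <- as.integer(round(spec$intensity * spec$n))
  xs <- ys <- numeric(0)
  if (n_clustered > 0) {
    n_clusters <- max(1L,
                      as.integer(round(n_clustered / spec$mean_cluster_size)))
    cx <- runif(n_clusters, w$xmin, w$xmax)
    cy <- runif(n_clusters, w$ymin, w$ymax)
    parent <- sample.int(n_clusters, n_clustered, replace = TRUE)
    xs <- ys <- rep(NA_real_, n_clustered)
    todo <- seq_len(n_clustered)
    while (length(todo) > 0) {
      theta <- runif(length(todo), 0, 2 * pi)
      # sqrt for a uniform distribution over the disc, not along the radius
      r <- spec$cluster_radius * sqrt(runif(length(todo)))
      px <- cx[parent[todo]] + r * cos(theta)
      py <- cy[parent[todo]] + r * sin(theta)
      ok <- in_window(w, px, py)
      xs[todo[ok]] <- px[ok]
      ys[todo[ok]] <- py[ok]
      todo <- todo[!ok]
    }
  }
  n_uniform <- spec$n - n_clustered
  point_pattern(c(xs, runif(n_uniform, w$xmin, w$xmax)),
                c(ys, runif(n_uniform, w$ymin, w$ymax)), w)
}

#' @rdname generate_pattern
#' @export
generate_regular <- function(spec) {
  stopifnot(inherits(spec, "pattern_spec"))
  if (spec$kind != "regular") {
    abort_pcqm("invalid_spec", "generate_regular() needs kind = \"regular\"")
  }
  if (!is.null(spec$seed)) set.seed(spec$seed)
  w <- spec$window
  res <- cpp_ssi(spec$n, w$xmin, w$xmax, w$ymin, w$ymax, spec$repulsion,
                 1000 * as.double(spec$n))
  if (!res$ok) {
    abort_pcqm("packing_failure",
               sprintf(paste("could not place %d points with repulsion %g m:",
                             "only %d placed after %.0f proposals",
                             "(%.0f consecutive rejections)"),
                       spec$n, spec$repulsion, res$placed, res$attempts,
                       1000 * as.double(spec$n)))
  }
  point_pattern(res$x, res$y, w)
}

#' Clark-Evans aggregation index
#'
#' Ratio of the observed mean nearest-neighbour distance to its expectation
#' \eqn{0.5/\sqrt{\lambda}} under complete spatial randomness, with
#' \eqn{\lambda} the observed intensity in points per m^2. No edge
#' correction is applied. Values near 1 indicate randomness, below 1
#' aggregation, above 1 regularity.
#'
#' @param pattern A \code{\link{point_pattern}} with at least 2 points.
#' @return The dimensionless index R.
#' @examples
#' w <- pcqm_window(1, 1)
#' corners <- point_pattern(c(0, 1, 0, 1), c(0, 0, 1, 1), w)
#' clark_evans_index(corners)  # 4: maximal regularity for 4 points
#' @export
clark_evans_index <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (pattern$n < 2) {
    abort_pcqm("insufficient_points",
               "Clark-Evans index needs at least 2 points")
  }
  lambda <- pattern$n / window_area(pattern$window)
  mean(cpp_nn_dist(pattern$x, pattern$y)) / (0.5 / sqrt(lambda))
}

#' Read and write tree-position tables
#'
#' Plain CSV with header \code{x,y}, one tree per row, coordinates in
#' meters. \code{write_pattern_csv()} writes coordinates at full double
#' precision so that a write/read round trip reproduces the pattern exactly.
#'
#' @param path File path.
#' @param window A \code{\link{pcqm_window}}; rows outside it are rejected.
#' @param pattern A \code{\link{point_pattern}}.
#' @return \code{read_pattern_csv()}: a \code{point_pattern}.
#' @export
read_pattern_csv <- function(path, window) {
  stopifnot(inherits(window, "pcqm_window"))
  tab <- tryCatch(read.csv(path, colClasses = "character"),
                  error = function(e) {
                    abort_pcqm("parse_error",
                               sprintf("cannot read '%s': %s", path,
                                       conditionMessage(e)))
                  })
  if (!all(c("x", "y") %in% names(tab))) {
    abort_pcqm("parse_error",
               sprintf("'%s' must have header columns x,y (found: %s)",
                       path, paste(names(tab), collapse = ",")))
  }
  if (nrow(tab) == 0) {
    abort_pcqm("empty_pattern",
               sprintf("'%s' contains a header but no tree positions", path))
  }
  x <- suppressWarnings(as.numeric(tab$x))
  y <- suppressWarnings(as.numeric(tab$y))
  bad <- which(is.na(x) | is.na(y))
  if (length(bad) > 0) {
    abort_pcqm("parse_error",
               sprintf("non-numeric coordinate in '%s' at data row %d",
                       path, bad[1]))
  }
  out <- which(!in_window(window, x, y))
  if (length(out) > 0) {
    abort_pcqm("parse_error",
               sprintf("point outside the window in '%s' at data row %d: (%g, %g)",
                       path, out[1], x[out[1]], y[out[1]]))
  }
  point_pattern(x, y, window)
}

#' @rdname read_pattern_csv
#' @export
write_pattern_csv <- function(pattern, path) {
  stopifnot(inherits(pattern, "point_pattern"))
  writeLines(c("x,y", sprintf("%.17g,%.17g", pattern$x, pattern$y)), path)
  invisible(path)
}
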