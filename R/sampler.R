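#' Draw PCQM sample points inside an edge-buffered sub-window
#'
#' Sample points are i.i.d. uniform over the interior rectangle obtained by
#' trimming \code{boundary_fraction} of each dimension's extent from each
#' edge of the window (the default 0.10 keeps the central 80% x 80%),
#' which removes the edge bias of quadrant distances measured near the plot
#' boundary.
#'
#' @param pattern A \code{\link{point_pattern}}.
#' @param n_points Number of sample points to draw (>= 1).
#' @param boundary_fraction Fraction in [0, 0.5) trimmed from each edge.
#' @param seed Optional RNG seed.
#' @return A data frame with columns \code{x}, \code{y}.
#' @export
draw_sample_points <- function(pattern, n_points, boundary_fraction = 0.10,
                               seed = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 1) {
    abort_pcqm("invalid_spec", "n_points must be a single number >= 1")
  }
  if (!is.null(seed)) set.seed(seed)
  inner <- shrink_window(pattern$window, boundary_fraction)
  data.frame(x = runif(n_points, inner$xmin, inner$xmax),
             y = runif(n_points, inner$ymin, inner$ymax))
}

#' Distances to the g-th nearest tree in each quadrant
#'
#' The plane around the sample point is divided into four axis-aligned
#' quadrants (half-open sectors from the +x axis: [0, 90), [90, 180),
#' [180, 270), [270, 360) degrees, so a tree exactly on an axis belongs to
#' exactly one quadrant). In each quadrant the Euclidean distance to the
#' g-th nearest tree is returned; for g > 1 the nearer trees are skipped,
#' not measured.
#'
#' @param pattern A \code{\link{point_pattern}}.
#' @param point Numeric length-2 vector (x, y), inside the window.
#' @param g Order: which nearest tree per quadrant to measure (>= 1).
#' @return Numeric length-4 vector of distances (meters), quadrants 1-4.
#' @examples
#' w <- pcqm_window(10, 10, -10, -10)
#' p <- point_pattern(c(1, -2, -1, 3), c(1, 1, -1, -4), w)
#' quadrant_distances(p, c(0, 0), g = 1)  # sqrt(2), sqrt(5), sqrt(2), 5
#' @export
quadrant_distances <- function(pattern, point, g = 1) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (length(point) != 2 || anyNA(point)) {
    abort_pcqm("invalid_spec", "point must be a length-2 (x, y) vector")
  }
  if (!in_window(pattern$window, point[1], point[2])) {
    abort_pcqm("invalid_spec", "sample point lies outside the window")
  }
  g <- check_order(g)
  arr <- cpp_quadrant_distances(pattern$x, pattern$y,
                                point[1], point[2], g)
  d <- arr[1, , g]
  if (anyNA(d)) {
    abort_pcqm("vacant_quadrant",
               sprintf("quadrant %d at sample point (%g, %g) holds fewer than g = %d trees",
                       which(is.na(d))[1], point[1], point[2], g),
               point = point, quadrant = which(is.na(d)))
  }
  d
}

check_order <- function(g) {
  if (!is.numeric(g) || length(g) != 1 || !is.finite(g) || g < 1 ||
      g != round(g)) {
    abort_pcqm("invalid_spec", "order g must be a single integer >= 1")
  }
  as.integer(g)
}

#' PCQM survey of a point pattern
#'
#' Draws \code{n_points} sample points in the edge-buffered interior (see
#' \code{\link{draw_sample_points}}) and measures the g-th nearest tree in
#' each of the four quadrants at every point. Sample points coinciding
#' exactly with a tree are rejected and redrawn, so all recorded distances
#' are positive. A quadrant with fewer than \code{g} trees raises a
#' vacant-quadrant error by default; with \code{vacancy_policy = "redraw"}
#' the offending point is replaced by a fresh draw, up to a total of
#' \code{100 * n_points} draws.
#'
#' @inheritParams draw_sample_points
#' @param g Order: which nearest tree per quadrant is measured.
#' @param vacancy_policy \code{"error"} (default) or \code{"redraw"}.
#' @return An object of class \code{pcqm_sample}: list with \code{g},
#'   \code{k = 4}, \code{n_points}, \code{points} (data frame) and
#'   \code{distances} (\code{n_points} x 4 matrix, meters).
#' @examples
#' p <- generate_random(pattern_spec("random", 2000, pcqm_window(100, 100),
#'                                   seed = 7))
#' s <- collect_sample(p, n_points = 30, g = 1, seed = 11)
#' density_corrected(s)
#' @export
collect_sample <- function(pattern, n_points, g = 1,
                           boundary_fraction = 0.10, seed = NULL,
                           vacancy_policy = c("error", "redraw")) {
  stopifnot(inherits(pattern, "point_pattern"))
  vacancy_policy <- match.arg(vacancy_policy)
  g <- check_order(g)
  if (!is.numeric(n_points) || length(n_points) != 1 || n_points < 1) {
    abort_pcqm("invalid_spec", "n_points must be a single number >= 1")
  }
  n_points <- as.integer(n_points)
  if (!is.null(seed)) set.seed(seed)
  inner <- shrink_window(pattern$window, boundary_fraction)

  pts <- matrix(NA_real_, n_points, 2)
  dmat <- matrix(NA_real_, n_points, 4)
  filled <- 0L
  draws <- 0L
  cap <- 100L * n_points
  while (filled < n_points) {
    need <- min(n_points - filled, cap - draws)
    if (need <= 0L) {
      abort_pcqm("sampling_failure",
                 sprintf("draw cap of %d sample points exhausted: only %d of %d valid points found",
                         cap, filled, n_points))
    }
    cx <- runif(need, inner$xmin, inner$xmax)
    cy <- runif(need, inner$ymin, inner$ymax)
    draws <- draws + need
    arr <- cpp_quadrant_distances(pattern$x, pattern$y, cx, cy, g)
    d <- matrix(arr[, , g], ncol = 4)
    vacant <- rowSums(is.na(d)) > 0
    if (any(vacant) && vacancy_policy == "error") {
      i <- which(vacant)[1]
      q <- which(is.na(d[i, ]))[1]
      abort_pcqm("vacant_quadrant",
                 sprintf("quadrant %d at sample point (%g, %g) holds fewer than g = %d trees",
                         q, cx[i], cy[i], g),
                 point = c(cx[i], cy[i]), quadrant = q)
    }
    # zero distance = sample point on top of a tree: always redrawn so that
    # the sum of squared distances stays positive
    ok <- !vacant & rowSums(d == 0, na.rm = TRUE) == 0
    n_ok <- sum(ok)
    if (n_ok > 0) {
      idx <- filled + seq_len(n_ok)
      pts[idx, 1] <- cx[ok]
      pts[idx, 2] <- cy[ok]
      dmat[idx, ] <- d[ok, , drop = FALSE]
      filled <- filled + n_ok
    }
  }
  new_pcqm_sample(g, data.frame(x = pts[, 1], y = pts[, 2]), dmat)
}

new_pcqm_sample <- function(g, points, distances) {
  structure(list(g = as.integer(g), k = 4L, n_points = nrow(distances),
                 points = points, distances = distances),
            class = "pcqm_sample")
}

#' Assemble a PCQM sample from measured distances
#'
#' Constructor for field data: an N x 4 matrix of distances (meters) from
#' each sample point to the g-th nearest tree in each quadrant.
#'
#' @param distances Numeric N x 4 matrix, all entries finite and > 0.
#' @param g Order of the survey (>= 1).
#' @param points Optional data frame of sample-point coordinates.
#' @return A \code{pcqm_sample}.
#' @export
pcqm_sample <- function(distances, g = 1, points = NULL) {
  g <- check_order(g)
  distances <- as.matrix(distances)
  if (ncol(distances) != 4 || nrow(distances) < 1) {
    abort_pcqm("invalid_spec", "distances must be an N x 4 matrix with N >= 1")
  }
  storage.mode(distances) <- "double"
  if (anyNA(distances) || any(!is.finite(distances)) || any(distances <= 0)) {
    abort_pcqm("invalid_spec", "all distances must be finite and > 0")
  }
  if (is.null(points)) {
    points <- data.frame(x = rep(NA_real_, nrow(distances)),
                         y = rep(NA_real_, nrow(distances)))
  }
  new_pcqm_sample(g, points, unname(distances))
}

#' @export
print.pcqm_sample <- function(x, ...) {
  cat(sprintf("PCQM%d sample: N = %d points, k = 4 quadrants, sum R^2 = %.4g m^2\n",
              x$g, x$n_points, sum(x$distances^2)))
  invisible(x)
}

#' Read and write PCQM sample files
#'
#' CSV with two comment header lines recording the order g and N, then
#' columns \code{point_id,x,y,q1,q2,q3,q4} (distances in meters).
#'
#' @param sample A \code{pcqm_sample}.
#' @param path File path.
#' @return \code{read_sample_csv()}: a \code{pcqm_sample}.
#' @export
write_sample_csv <- function(sample, path) {
  stopifnot(inherits(sample, "pcqm_sample"))
  d <- sample$distances
  lines <- c(sprintf("# g: %d", sample$g),
             sprintf("# n_points: %d", sample$n_points),
             "point_id,x,y,q1,q2,q3,q4",
             sprintf("%d,%.17g,%.17g,%.17g,%.17g,%.17g,%.17g",
                     seq_len(sample$n_points),
                     sample$points$x, sample$points$y,
                     d[, 1], d[, 2], d[, 3], d[, 4]))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_sample_csv
#' @export
read_sample_csv <- function(path) {
  lines <- readLines(path)
  meta <- grep("^# ", lines, value = TRUE)
  gline <- grep("^# g:", meta, value = TRUE)
  if (length(gline) != 1) {
    abort_pcqm("parse_error",
               sprintf("'%s' is missing the '# g:' metadata line", path))
  }
  g <- suppressWarnings(as.integer(sub("^# g:\\s*", "", gline)))
  if (is.na(g)) {
    abort_pcqm("parse_error", sprintf("unreadable order in '%s'", path))
  }
  tab <- read.csv(text = lines[!startsWith(lines, "# ")])
  need <- c("x", "y", "q1", "q2", "q3", "q4")
  if (!all(need %in% names(tab))) {
    abort_pcqm("parse_error",
               sprintf("'%s' must have columns %s", path,
                       paste(need, collapse = ",")))
  }
  if (nrow(tab) == 0) {
    abort_pcqm("parse_error", sprintf("'%s' holds no sample points", path))
  }
  pcqm_sample(as.matrix(tab[, c("q1", "q2", "q3", "q4")]), g = g,
              points = tab[, c("x", "y")])
}
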