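#' Relative root mean square error and relative bias
#'
#' Accuracy metrics for a set of Monte Carlo density estimates against the
#' known true density \eqn{\rho}:
#' \deqn{\mathrm{RRMSE} = \sqrt{\sum_i (\hat\rho_i - \rho)^2 / (I \rho^2)},
#'       \qquad \mathrm{RBIAS} = (\bar{\hat\rho} - \rho) / \rho,}
#' with I the number of estimates. RBIAS is signed; negative values mean
#' underestimation. Computed from the same estimate set,
#' \code{RRMSE >= |RBIAS|} always holds.
#'
#' @param estimates Numeric vector of density estimates (stems/ha), or a
#'   list of \code{\link{pcqm_density}} results.
#' @param true_density True density \eqn{\rho} (stems/ha), > 0.
#' @return A single dimensionless number.
#' @examples
#' rrmse(c(5000, 10000), 5000)  # sqrt(0.5)
#' rbias(c(2500, 7500), 5000)   # 0
#' @export
rrmse <- function(estimates, true_density) {
  est <- as_density_values(estimates)
  rho <- check_true_density(true_density)
  sqrt(sum((est - rho)^2) / (length(est) * rho^2))
}

#' @rdname rrmse
#' @export
rbias <- function(estimates, true_density) {
  est <- as_density_values(estimates)
  rho <- check_true_density(true_density)
  (mean(est) - rho) / rho
}

as_density_values <- function(estimates) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "density_estimate")) e$value else as.double(e)
    }, numeric(1))
  }
  est <- as.double(estimates)
  if (length(est) < 1 || anyNA(est)) {
    abort_pcqm("invalid_spec",
               "estimates must be a nonempty numeric vector without NA")
  }
  est
}

check_true_density <- function(true_density) {
  if (!is.numeric(true_density) || length(true_density) != 1 ||
      !is.finite(true_density) || true_density <= 0) {
    abort_pcqm("invalid_true_density", "true density must be a single value > 0")
  }
  as.double(true_density)
}

#' Monte Carlo scenario definition
#'
#' One cell grid of the simulation experiment: a population (a
#' \code{\link{pattern_spec}} to be realized once, or an existing
#' \code{\link{point_pattern}}) crossed with sample sizes, PCQM orders and
#' estimator families, surveyed \code{replicates} times per sample size.
#'
#' @param pattern A \code{pattern_spec} or \code{point_pattern}. A spec is
#'   realized afresh for every replicate (the population is re-established
#'   each simulation run, as in an individual-based model); a supplied
#'   \code{point_pattern} - e.g. a mapped field stand - stays fixed and
#'   only the sample points are redrawn.
#' @param sample_sizes Vector of sample-point counts N (default the survey
#'   grid 10, 15, 20, 25, 30, 50, 100).
#' @param orders PCQM orders g, subset of \code{1:3} by default.
#' @param estimators Character subset of \code{c("corrected", "published")}.
#' @param replicates Simulations per sample size (default 1000).
#' @param boundary_fraction Edge buffer passed to the sampler.
#' @param seed Master seed; every replicate derives its own child seed from
#'   it, so a rerun reproduces each estimate exactly.
#' @param scenario_id Identifier used in output tables (default derived
#'   from the pattern kind).
#' @return An object of class \code{scenario_config}.
#' @seealso \code{\link{run_scenario}}
#' @export
scenario_config <- function(pattern,
                            sample_sizes = c(10, 15, 20, 25, 30, 50, 100),
                            orders = 1:3,
                            estimators = c("corrected", "published"),
                            replicates = 1000,
                            boundary_fraction = 0.10,
                            seed = 1,
                            scenario_id = NULL) {
  if (!inherits(pattern, "pattern_spec") &&
      !inherits(pattern, "point_pattern")) {
    abort_pcqm("invalid_spec",
               "pattern must be a pattern_spec or a point_pattern")
  }
  sample_sizes <- as.integer(sample_sizes)
  if (length(sample_sizes) < 1 || any(sample_sizes < 1)) {
    abort_pcqm("invalid_spec", "sample_sizes must all be >= 1")
  }
  orders <- vapply(orders, check_order, integer(1))
  estimators <- match.arg(estimators, several.ok = TRUE)
  if (!is.numeric(replicates) || replicates < 1) {
    abort_pcqm("invalid_spec", "replicates must be >= 1")
  }
  if (is.null(scenario_id)) {
    kind <- if (inherits(pattern, "pattern_spec")) pattern$kind else "pattern"
    scenario_id <- paste0(kind, "_", format(seed))
  }
  structure(list(pattern = pattern, sample_sizes = sample_sizes,
                 orders = orders, estimators = estimators,
                 replicates = as.integer(replicates),
                 boundary_fraction = boundary_fraction,
                 seed = as.integer(seed),
                 scenario_id = as.character(scenario_id)),
            class = "scenario_config")
}

#' Run a Monte Carlo PCQM scenario
#'
#' Every (sample size, order) cell runs \code{replicates} independent
#' simulations: each establishes the population (for a
#' \code{\link{pattern_spec}}), draws fresh sample points in the
#' edge-buffered interior, measures the quadrant distances, and applies
#' every requested estimator family to the same distance data. Seeds are
#' derived deterministically from the master seed, the scenario id, N, the
#' order and the replicate index, so cells are independent and every
#' estimate is exactly reproducible. A replicate that fails (vacant
#' quadrant or packing failure on an infeasible spec) is recorded with
#' status \code{"failed"}, never dropped silently.
#'
#' @param config A \code{\link{scenario_config}}.
#' @return An object of class \code{pcqm_mc}: list with
#'   \itemize{
#'     \item \code{metrics}: one row per (N, estimator, order) cell with
#'       RRMSE, RBIAS and the number of successful/failed replicates
#'       (the machine twin of the published scenario tables);
#'     \item \code{raw}: one row per replicate and cell with the estimate
#'       in stems/ha;
#'     \item \code{pattern}, \code{true_density}, \code{config}.
#'   }
#' @examples
#' cfg <- scenario_config(pattern_spec("random", 1000, pcqm_window(100, 100)),
#'                        sample_sizes = c(10, 20), orders = 1,
#'                        replicates = 50, seed = 3)
#' res <- run_scenario(cfg)
#' res$metrics
#' @export
run_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  spec <- config$pattern
  regenerate <- inherits(spec, "pattern_spec")
  if (regenerate) {
    # the population is re-established for every simulation run; the target
    # density is a property of the spec (count is fixed), not a realization
    rho <- spec$n / window_area(spec$window) * 1e4
    kind <- spec$kind
    spec$seed <- NULL
    exemplar_spec <- spec
    exemplar_spec$seed <- derive_seed(config$seed, config$scenario_id,
                                      "pattern")
    exemplar <- generate_pattern(exemplar_spec)
  } else {
    exemplar <- spec
    rho <- true_density(spec)
    kind <- "supplied"
  }
  reps <- config$replicates
  raw <- NULL
  metrics <- NULL
  for (n_pts in config$sample_sizes) {
    dens <- array(NA_real_,
                  c(reps, length(config$orders), length(config$estimators)))
    status <- matrix("ok", reps, length(config$orders))
    for (gi in seq_along(config$orders)) {
      g <- config$orders[gi]
      for (r in seq_len(reps)) {
        # every (N, order) cell draws its own populations and surveys; the
        # estimator families are two formulas applied to the same distance
        # data
        set.seed(derive_seed(config$seed, config$scenario_id, n_pts, g, r))
        arr <- tryCatch({
          pattern <- if (regenerate) generate_pattern(spec) else exemplar
          survey_distances(pattern, n_pts, g, config$boundary_fraction)
        }, pcqm_error = function(e) e)
        if (inherits(arr, "pcqm_error")) {
          status[r, gi] <- "failed"
          next
        }
        sum_sq <- sum(arr[, , g]^2)
        for (ei in seq_along(config$estimators)) {
          num <- pcqm_numerator(config$estimators[ei], g, n_pts)
          dens[r, gi, ei] <- num / (pi * sum_sq) * 1e4
        }
      }
    }
    for (ei in seq_along(config$estimators)) {
      for (gi in seq_along(config$orders)) {
        est <- dens[, gi, ei]
        ok <- !is.na(est)
        metrics <- rbind(metrics, data.frame(
          scenario_id = config$scenario_id, pattern_kind = kind,
          true_density = rho, samples = n_pts,
          pcqm_eqn = config$estimators[ei], pcqm_type = config$orders[gi],
          rrmse = if (any(ok)) rrmse(est[ok], rho) else NA_real_,
          rbias = if (any(ok)) rbias(est[ok], rho) else NA_real_,
          n_ok = sum(ok), n_failed = sum(!ok),
          stringsAsFactors = FALSE))
        raw <- rbind(raw, data.frame(
          scenario_id = config$scenario_id, pattern_kind = kind,
          true_density = rho, samples = n_pts,
          pcqm_eqn = config$estimators[ei], pcqm_type = config$orders[gi],
          replicate = seq_len(reps), density_ha = est,
          status = status[, gi], stringsAsFactors = FALSE))
      }
    }
  }
  structure(list(metrics = metrics, raw = raw, pattern = exemplar,
                 true_density = rho, config = config),
            class = "pcqm_mc")
}

# One survey: n_pts sample points in the buffered interior, distances to the
# 1..gmax nearest trees per quadrant. Mirrors collect_sample() (zero
# distances redrawn, vacancy is an error) but keeps all orders at once.
survey_distances <- function(pattern, n_pts, gmax, boundary_fraction) {
  inner <- shrink_window(pattern$window, boundary_fraction)
  out <- array(NA_real_, c(n_pts, 4, gmax))
  filled <- 0L
  draws <- 0L
  cap <- 100L * n_pts
  while (filled < n_pts) {
    need <- min(n_pts - filled, cap - draws)
    if (need <= 0L) {
      abort_pcqm("sampling_failure",
                 sprintf("draw cap exhausted: %d of %d valid sample points",
                         filled, n_pts))
    }
    cx <- runif(need, inner$xmin, inner$xmax)
    cy <- runif(need, inner$ymin, inner$ymax)
    draws <- draws + need
    arr <- cpp_quadrant_distances(pattern$x, pattern$y, cx, cy, gmax)
    flat <- matrix(arr, nrow = need)
    vacant <- rowSums(is.na(flat)) > 0
    if (any(vacant)) {
      i <- which(vacant)[1]
      abort_pcqm("vacant_quadrant",
                 sprintf("a quadrant at sample point (%g, %g) holds fewer than g = %d trees",
                         cx[i], cy[i], gmax))
    }
    ok <- rowSums(flat == 0) == 0
    n_ok <- sum(ok)
    if (n_ok > 0) {
      out[filled + seq_len(n_ok), , ] <- arr[ok, , , drop = FALSE]
      filled <- filled + n_ok
    }
  }
  out
}

#' @export
print.pcqm_mc <- function(x, ...) {
  cat(sprintf("PCQM Monte Carlo run '%s': %d replicates, true density %g stems/ha\n",
              x$config$scenario_id, x$config$replicates, x$true_density))
  print(x$metrics, row.names = FALSE)
  invisible(x)
}

#' Compare the corrected and published estimator families
#'
#' Two-sided Wilcoxon rank-sum test (Mann-Whitney U) on two sets of
#' per-replicate density estimates.
#'
#' @param raw_a,raw_b Numeric vectors of density estimates (stems/ha).
#' @return An object of class \code{htest} from \code{\link[stats]{wilcox.test}}.
#' @export
compare_estimator_families <- function(raw_a, raw_b) {
  a <- as_density_values(raw_a)
  b <- as_density_values(raw_b)
  wilcox.test(a, b, alternative = "two.sided", exact = FALSE)
}

#' Compare PCQM orders
#'
#' Kruskal-Wallis omnibus test across the per-replicate estimates of PCQM1,
#' PCQM2 and PCQM3, followed by Dunn's pairwise rank comparison (normal
#' approximation with tie correction), Holm-adjusted by default.
#'
#' @param raw_1,raw_2,raw_3 Numeric vectors of density estimates for orders
#'   1, 2, 3.
#' @param p_adjust Adjustment method for the pairwise p-values, passed to
#'   \code{\link[stats]{p.adjust}} (default \code{"holm"}; use
#'   \code{"none"} for unadjusted).
#' @return A list of class \code{pcqm_order_comparison}: \code{omnibus}
#'   (the Kruskal-Wallis \code{htest}) and \code{posthoc} (data frame with
#'   columns comparison, z, p_value, p_adjusted).
#' @export
compare_orders <- function(raw_1, raw_2, raw_3, p_adjust = "holm") {
  groups <- list(as_density_values(raw_1), as_density_values(raw_2),
                 as_density_values(raw_3))
  omnibus <- kruskal.test(groups)
  posthoc <- dunn_posthoc(groups, labels = paste0("PCQM", 1:3),
                          p_adjust = p_adjust)
  structure(list(omnibus = omnibus, posthoc = posthoc),
            class = "pcqm_order_comparison")
}

# Dunn's z statistic on pooled ranks with tie correction.
dunn_posthoc <- function(groups, labels, p_adjust = "holm") {
  x <- unlist(groups)
  gid <- rep(seq_along(groups), lengths(groups))
  n <- length(x)
  rk <- rank(x)
  mean_rk <- tapply(rk, gid, mean)
  sizes <- lengths(groups)
  ties <- table(rk)
  tie_corr <- sum(ties^3 - ties) / (12 * (n - 1))
  pairs <- utils::combn(length(groups), 2)
  z <- p <- numeric(ncol(pairs))
  cmp <- character(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt((n * (n + 1) / 12 - tie_corr) * (1 / sizes[a] + 1 / sizes[b]))
    z[j] <- (mean_rk[a] - mean_rk[b]) / se
    p[j] <- 2 * pnorm(-abs(z[j]))
    cmp[j] <- paste(labels[a], "-", labels[b])
  }
  data.frame(comparison = cmp, z = z, p_value = p,
             p_adjusted = p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' @export
print.pcqm_order_comparison <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: chi-squared = %.3f, df = %d, p = %.4g\n",
              unname(x$omnibus$statistic), unname(x$omnibus$parameter),
              x$omnibus$p.value))
  print(x$posthoc, row.names = FALSE)
  invisible(x)
}

#' Read and write per-replicate results tables
#'
#' Long-format CSV, one row per replicate and cell, with columns
#' \code{scenario_id, pattern_kind, true_density, samples, pcqm_eqn,
#' pcqm_type, replicate, density_ha, status}. Densities are written with 10
#' significant digits.
#'
#' @param raw The \code{raw} data frame of a \code{\link{run_scenario}}
#'   result (or a compatible data frame).
#' @param path File path.
#' @return \code{read_results_csv()}: the data frame.
#' @export
write_results_csv <- function(raw, path) {
  cols <- c("scenario_id", "pattern_kind", "true_density", "samples",
            "pcqm_eqn", "pcqm_type", "replicate", "density_ha", "status")
  if (!all(cols %in% names(raw))) {
    abort_pcqm("invalid_spec",
               sprintf("raw results need columns %s", paste(cols, collapse = ",")))
  }
  raw <- raw[, cols]
  body <- sprintf("%s,%s,%.10g,%d,%s,%d,%d,%s,%s",
                  raw$scenario_id, raw$pattern_kind, raw$true_density,
                  raw$samples, raw$pcqm_eqn, raw$pcqm_type, raw$replicate,
                  ifelse(is.na(raw$density_ha), "NA",
                         sprintf("%.10g", raw$density_ha)),
                  raw$status)
  writeLines(c(paste(cols, collapse = ","), body), path)
  invisible(path)
}

#' @rdname write_results_csv
#' @export
read_results_csv <- function(path) {
  tab <- tryCatch(read.csv(path, stringsAsFactors = FALSE),
                  error = function(e) {
                    abort_pcqm("parse_error",
                               sprintf("cannot read '%s': %s", path,
                                       conditionMessage(e)))
                  })
  cols <- c("scenario_id", "pattern_kind", "true_density", "samples",
            "pcqm_eqn", "pcqm_type", "replicate", "density_ha", "status")
  if (!all(cols %in% names(tab))) {
    abort_pcqm("parse_error",
               sprintf("'%s' must have columns %s", path,
                       paste(cols, collapse = ",")))
  }
  for (col in c("true_density", "samples", "pcqm_type", "replicate",
                "density_ha")) {
    v <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(is.na(v) & !(tab[[col]] %in% c("NA", NA)))
    if (length(bad) > 0) {
      abort_pcqm("parse_error",
                 sprintf("non-numeric value in column %s of '%s' at data row %d",
                         col, path, bad[1]))
    }
    tab[[col]] <- v
  }
  tab
}

#' Write a metrics table (the machine twin of the scenario tables)
#'
#' @param metrics The \code{metrics} data frame of a
#'   \code{\link{run_scenario}} result.
#' @param path File path.
#' @export
write_metrics_csv <- function(metrics, path) {
  utils::write.csv(metrics, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
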