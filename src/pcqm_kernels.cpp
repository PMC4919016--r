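#include <Rcpp.h>
using namespace Rcpp;

// Distances from each sample point to the 1..gmax nearest trees in each of
// the four axis-aligned quadrants around it. Quadrants are half-open sectors
// measured from the +x axis: Q1 [0,90), Q2 [90,180), Q3 [180,270),
// Q4 [270,360), so a tree lying exactly on an axis belongs to exactly one
// quadrant. A tree coincident with the sample point is reported in Q1 at
// distance 0 (callers reject such sample points).
//
// Returns an np x 4 x gmax array; NA where a quadrant holds fewer than g
// trees.
// [[Rcpp::export]]
NumericVector cpp_quadrant_distances(NumericVector tx, NumericVector ty,
                                     NumericVector px, NumericVector py,
                                     int gmax) {
  const int nt = tx.size(), np = px.size();
  if (gmax < 1) stop("gmax must be >= 1");
  NumericVector out(static_cast<R_xlen_t>(np) * 4 * gmax, NA_REAL);
  out.attr("dim") = Dimension(np, 4, gmax);
  std::vector<double> best(4 * gmax);

  for (int i = 0; i < np; ++i) {
    std::fill(best.begin(), best.end(), R_PosInf);
    const double x0 = px[i], y0 = py[i];
    for (int t = 0; t < nt; ++t) {
      const double dx = tx[t] - x0, dy = ty[t] - y0;
      int q;
      if (dx > 0 && dy >= 0) q = 0;
      else if (dx <= 0 && dy > 0) q = 1;
      else if (dx < 0 && dy <= 0) q = 2;
      else if (dx >= 0 && dy < 0) q = 3;
      else q = 0;  // dx == 0 && dy == 0
      const double d2 = dx * dx + dy * dy;
      double* b = &best[q * gmax];
      if (d2 < b[gmax - 1]) {  // insertion sort into the gmax smallest
        int j = gmax - 1;
        while (j > 0 && b[j - 1] > d2) { b[j] = b[j - 1]; --j; }
        b[j] = d2;
      }
    }
    for (int q = 0; q < 4; ++q)
      for (int g = 0; g < gmax; ++g) {
        const double v = best[q * gmax + g];
        if (R_FINITE(v))
          out[i + static_cast<R_xlen_t>(np) * (q + 4 * g)] = std::sqrt(v);
      }
  }
  return out;
}

// Nearest-neighbour distance for every point of a pattern (all-pairs scan).
// [[Rcpp::export]]
NumericVector cpp_nn_dist(NumericVector x, NumericVector y) {
  const int n = x.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    double best = R_PosInf;
    const double xi = x[i], yi = y[i];
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      const double dx = x[j] - xi, dy = y[j] - yi;
      const double d2 = dx * dx + dy * dy;
      if (d2 < best) best = d2;
    }
    out[i] = std::sqrt(best);
  }
  return out;
}

// Simple sequential inhibition: uniform proposals over the window, accepted
// only if at least `repulsion` away from every previously accepted point.
// Gives up after `max_rejects` consecutive rejected proposals. Uses R's RNG
// so results are reproducible under set.seed().
// [[Rcpp::export]]
List cpp_ssi(int n, double xmin, double xmax, double ymin, double ymax,
             double repulsion, double max_rejects) {
  NumericVector x(n), y(n);
  const double r2 = repulsion * repulsion;
  int placed = 0;
  double rejects = 0, attempts = 0;
  while (placed < n) {
    const double px = R::runif(xmin, xmax);
    const double py = R::runif(ymin, ymax);
    attempts += 1;
    bool ok = true;
    for (int j = 0; j < placed; ++j) {
      const double dx = x[j] - px, dy = y[j] - py;
      if (dx * dx + dy * dy < r2) { ok = false; break; }
    }
    if (ok) {
      x[placed] = px; y[placed] = py; ++placed;
      rejects = 0;
    } else {
      rejects += 1;
      if (rejects >= max_rejects) break;
    }
  }
  return List::create(_["x"] = x, _["y"] = y, _["placed"] = placed,
                      _["attempts"] = attempts,
                      _["ok"] = (placed == n));
}
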