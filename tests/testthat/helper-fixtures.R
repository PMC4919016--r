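# Shared fixture builders and independent oracles.

ha_window <- function() pcqm_window(100, 100)

mk_random_pattern <- function(n, window = ha_window(), seed = 1) {
  generate_random(pattern_spec("random", n, window, seed = seed))
}

# Independent brute-force oracle for the quadrant search: classify every
# tree into its half-open sector and sort distances per quadrant.
brute_quadrant <- function(pattern, point, g) {
  dx <- pattern$x - point[1]
  dy <- pattern$y - point[2]
  d <- sqrt(dx * dx + dy * dy)
  q <- ifelse(dx > 0 & dy >= 0, 1L,
       ifelse(dx <= 0 & dy > 0, 2L,
       ifelse(dx < 0 & dy <= 0, 3L, 4L)))
  q[dx == 0 & dy == 0] <- 1L
  vapply(1:4, function(qq) {
    dq <- sort(d[q == qq])
    if (length(dq) >= g) dq[g] else NA_real_
  }, numeric(1))
}

# Minimum pairwise distance of a pattern (oracle for the hard-core check).
min_pairwise_dist <- function(pattern) {
  min(dist(cbind(pattern$x, pattern$y)))
}
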