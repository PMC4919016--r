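---
title: "PCQM density estimation: models, simulators and evaluation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PCQM density estimation: models, simulators and evaluation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The estimation problem

The point-centred quarter method (PCQM) estimates stem density from
point-to-tree distances instead of plot counts. At each of $N$ random
sample points the plane is split into $k = 4$ axis-aligned quadrants, and
in each quadrant the distance $R_{(g)ij}$ to the $g$-th nearest tree is
measured (order $g = 1$: the nearest; $g = 2, 3$: the second- and
third-nearest, with nearer trees skipped, not measured). The motivating
geometry is Pollard's: under complete spatial randomness with intensity
$\lambda$, the disc around a sample point reaching the $g$-th nearest tree
of one quadrant contains a Gamma-distributed amount of "tree-free area", so
$\frac{\pi}{4}\sum_{ij} R_{(g)ij}^2 \sim \mathrm{Gamma}(gNk,\ \lambda)$ and

$$\hat\lambda = \frac{gNk - 1}{\frac{\pi}{4}\sum_{ij} R_{(g)ij}^2}
             = \frac{k\,(gNk - 1)}{\pi \sum_{ij} R_{(g)ij}^2}$$

is exactly unbiased ($E[1/\mathrm{Gamma}(a,\lambda)] = \lambda/(a-1)$).
This is the **corrected** family implemented by `density_corrected()`, with
numerators $4(4N-1)$, $4(8N-1)$, $4(12N-1)$ for $g = 1, 2, 3$.

A second family is widespread in the literature and implemented by
`density_published()` for comparison:
$\hat\rho = Nk(gk-1) / (\pi\sum R^2)$, numerators $12N$, $28N$, $44N$. It
replaces the $-1$ correction *inside* $gNk$ by one applied per sample
point, and converges to $(gk-1)/(gk)$ times the corrected value as $N$
grows. Its negative bias — about $-25\%$, $-12.5\%$, $-8.5\%$ for
$g = 1, 2, 3$ — is the central quantitative fact this package's evaluation
framework reproduces. Within one survey the two families differ only by
their numerators, so their ratio is deterministic: $N(gk-1)/(gNk-1)$.

Distances are in meters; estimates are returned in stems per hectare
($\times 10^4$ from m$^{-2}$). The denominator is $\pi$ times the *sum of
squared distances* — not a sum of inverse squares, a misreading the test
suite explicitly guards against.

## Synthetic populations

Three generators produce the study populations inside a rectangular,
closed window (default $100 \times 100$ m):

* **random** — exactly $n$ points i.i.d. uniform (a binomial process, the
  count is fixed rather than Poisson);
* **aggregated** — a fraction `intensity` of the $n$ stems is placed in
  clusters: cluster centres uniform, offspring uniform on a disc of radius
  `cluster_radius` around their centre, redrawn (not clipped) until inside
  the window; the remainder uniform. The number of clusters is
  `max(1, round(intensity * n / mean_cluster_size))`;
* **regular** — simple sequential inhibition: uniform proposals accepted
  only when at least `repulsion` meters from every accepted point. After
  $1000\,n$ consecutive rejections the spec is declared infeasible with a
  packing-failure error (a hectare holds at most about $1.15/d^2 \times
  10^4$ discs of hard-core distance $d$, so e.g. 3,000 stems with $d = 10$
  m can never complete).

Patterns are characterized by the Clark–Evans aggregation index
$R = \bar r_{\mathrm{NN}} / (0.5/\sqrt{\hat\lambda})$, computed without
edge correction: at the densities used here (thousands of stems per
hectare) the edge term is negligible, and the uncorrected form reproduces
the reference values — $R \approx 1.00$ for random 5,000-stem patterns,
$1.03 \to 1.40$ for repulsion $0.25 \to 1.0$ m, $0.95 \to 0.79$ for
aggregation intensity $10\% \to 50\%$ at radius 1 m.

Two generator internals are genuinely open choices and are therefore
exposed as parameters:

* `mean_cluster_size` (default 10). The reference scenario descriptions
  fix only cluster radius and aggregation intensity; with an average of 10
  offspring per cluster the generated patterns land on the reference
  aggregation indices (about 0.98 / 0.90 / 0.81 measured here for
  intensities 10/30/50% at radius 1 m), so 10 is the default and the knob
  remains available.
* `boundary_fraction` (default 0.10): "a boundary strip of 10% of the
  length and width" is read as trimming 10% of each dimension from *each*
  edge, leaving the central $80\% \times 80\%$ for sample points. The
  alternative (5% per side) changes only the sampled sub-region, not any
  estimator; with a ~2.5 m expected PCQM3 search radius against a 10 m
  buffer, either choice keeps quadrant searches comfortably away from the
  window edge at these densities.

## The virtual survey

Quadrants have fixed, window-axis-aligned orientation (standard compass
practice in the field; orientation is not randomized per point). The four
sectors are half-open in angle — $[0°, 90°)$, $[90°, 180°)$, $[180°,
270°)$, $[270°, 360°)$ from the $+x$ axis — so a tree lying exactly on an
axis belongs to exactly one quadrant. The search itself is a compiled
exhaustive scan over all trees, maintaining the $g$ smallest squared
distances per quadrant; the test suite checks it bit-for-bit against an
independent R implementation. Equidistant trees cannot change the returned
$g$-th *distance*, so no further tie-breaking is needed; coordinates are
continuous doubles and exact ties are measure-zero anyway.

A sample point falling exactly on a tree would contribute a zero distance;
such points are rejected and redrawn so that $\sum R^2 > 0$ always holds.
A quadrant holding fewer than $g$ trees (possible on sparse field data,
not in the simulated scenarios) raises a vacant-quadrant error by default;
`vacancy_policy = "redraw"` replaces the point instead, up to $100N$ total
draws. Vacant-quadrant *corrections* (the PCQM+ protocol) are out of
scope.

## The Monte Carlo design

`run_scenario()` crosses sample sizes $N \in \{10, 15, 20, 25, 30, 50,
100\}$ (the default survey grid) with orders, estimator families and
$I = 1000$ replicates. Design choices worth stating:

* **The population is re-established every replicate** when the scenario
  is given a `pattern_spec`. The evaluation follows an individual-based
  simulation design in which tree establishment is part of each run, so
  the metrics measure unconditional estimator error, not error conditional
  on one realized map. This matters more than it may seem: a single fixed
  5,000-point realization carries a realization-specific density
  fluctuation of order 1% in the sampled sub-region, which at $I = 1000$
  is large enough to make cross-order rank tests flip significance
  depending on the realization. A user-supplied `point_pattern` (a mapped
  field stand) is, by contrast, fixed — there the conditional error is
  the quantity of interest.
* **Seeds**: every (sample size, order, replicate) triple derives its own
  child seed from the master seed and the scenario id via a Lehmer-style
  integer hash, so cells are mutually independent, any single estimate can
  be replayed exactly, and reruns are bit-identical.
* **Both estimator families are applied to the same distance data** within
  a replicate: they are two formulas for one survey, which is also how
  their numerator-ratio relationship is exact per replicate.
* **Failures are marked, never dropped**: a replicate whose survey cannot
  be completed is recorded with status `failed` and the cell's
  `n_failed` count is reported.

Accuracy is summarized per cell by
$\mathrm{RRMSE} = \sqrt{\sum_i(\hat\rho_i - \rho)^2 / (I\rho^2)}$ and
$\mathrm{RBIAS} = (\overline{\hat\rho} - \rho)/\rho$ (negative =
underestimation). Computed from the same replicate set,
$\mathrm{RRMSE} \ge |\mathrm{RBIAS}|$ always (Jensen); the suite asserts
this on every produced table.

Family differences are tested with the two-sided Wilcoxon rank-sum test on
per-replicate estimates; order differences with a Kruskal–Wallis omnibus
test followed by Dunn's pairwise rank comparison (normal approximation
with tie correction). The reference analysis names only a generic post-hoc
procedure, so Dunn-with-Holm is our choice, with unadjusted p-values
available via `p_adjust = "none"`; at these effect sizes the conclusions
consume only "significant at 0.05 or not". With 1,000 replicates per
group, even inconsequential shifts (a few tenths of a percent) are
detectable — a caveat the reference analysis itself makes.

## Problem sizes used in the shipped checks

The package's own test suite runs the full-scale scenarios it reports:
1,000 replicates per cell on 5,000-stem random, 3,000-stem regular
(repulsion 1.0 m) and 3,000-stem aggregated (radius 1 m, intensity 50%)
populations, which completes in a few minutes because the quadrant search
is compiled. Unit-level tests use smaller populations (hundreds of stems)
chosen so that each check still exercises the property it names; the
unbiasedness property uses 2,000 independent populations at $\lambda =
0.5$ m$^{-2}$ with $N = 30$, giving a Monte Carlo standard error of about
0.2% against which the corrected family's bias is indistinguishable from
zero and the published family's shrinkage factors are reproduced to three
decimals.

## What the simulations do and do not show

The generators emulate idealized stationary, isotropic patterns with
exactly known density: uniform placement, hard-core inhibition, and
uniform-disc clusters. Real stands violate these in ways the framework
does not model — inhomogeneous density gradients, anisotropy (rows,
contours), size-structured spacing, multi-stemmed individuals, and
measurement error in field distances. Passing the shipped checks
demonstrates that the estimator algebra and the samplers are right and
that the corrected family is unbiased *under the simulated conditions*;
it does not by itself certify accuracy on any particular field stand.
Known limitations, deliberately out of scope: vacant-quadrant corrections
(PCQM+), variance or confidence-interval formulas for PCQM, other plotless
estimators, torus wrapping / edge-corrected indices, and inhomogeneous
point processes.
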