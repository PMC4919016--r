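# pcqm

Plotless plant-density estimation with the point-centred quarter method
(PCQM), and the Monte Carlo machinery to evaluate how accurate its
estimators are on populations with known density.

## The problem

In dense or hard-to-access vegetation (mangroves are the classic case),
laying out fixed-area quadrats is slow and error-prone. The PCQM instead
visits N random sample points; at each point the plane is divided into four
quadrants and the distance R_ij from the point to a designated nearest tree
in each quadrant j is measured. First-order PCQM (PCQM1) measures the
nearest tree per quadrant; PCQM2 and PCQM3 measure the second- and
third-nearest, skipping the nearer ones. The distances are pooled into a
density estimate.

Two incompatible estimator families are in circulation for orders g = 1, 2,
3 (k = 4 quadrants throughout):

* **published** form: rho = N k (g k − 1) / (pi Σ R²), i.e. numerators
  12N, 28N, 44N for g = 1, 2, 3;
* **corrected** form: rho = k (g N k − 1) / (pi Σ R²), i.e. numerators
  4(4N − 1), 4(8N − 1), 4(12N − 1), the family consistent with Pollard's
  unbiased first-order estimator.

The two coincide at N = 1 and diverge by the factor (gk − 1)/(gk) as N
grows: the published family systematically underestimates density by about
25% (PCQM1), 12.5% (PCQM2) and 8.5% (PCQM3). This package implements both
families, simulators for random, aggregated (clustered) and regular
(hard-core) tree populations, a virtual PCQM sampler with edge buffering,
and the relative-RMSE / relative-bias evaluation framework that
demonstrates the difference.

## Worked example

```r
library(pcqm)

# a one-hectare random population of 5,000 stems
w <- pcqm_window(100, 100)
pop <- generate_random(pattern_spec("random", 5000, w, seed = 7))
clark_evans_index(pop)
#> [1] 1.010464

# one virtual PCQM1 survey of 30 points (10% boundary strip excluded)
s <- collect_sample(pop, n_points = 30, g = 1, seed = 11)
density_corrected(s)
#> PCQM1 corrected estimate: 4750.9 stems/ha
#>   numerator 476 / (pi * sum R^2 = 318.918 m^2), N = 30
density_published(s)
#> PCQM1 published estimate: 3593.1 stems/ha
#>   numerator 360 / (pi * sum R^2 = 318.918 m^2), N = 30
```

The corrected estimate sits near the true 5,000 stems/ha (a single
30-point survey has a relative error of roughly 9%); the published one is
further depressed by exactly the numerator ratio 360/476 = 0.756.

A Monte Carlo scenario (the population is re-established every replicate,
as in the individual-based simulation design):

```r
cfg <- scenario_config(pattern_spec("random", 5000, w),
                       sample_sizes = c(15, 50, 100), orders = 1:3,
                       replicates = 1000, seed = 42,
                       scenario_id = "random5000")
res <- run_scenario(cfg)
subset(res$metrics, pcqm_eqn == "corrected" & pcqm_type == 1,
       c(samples, rrmse, rbias))
#>   samples  rrmse     rbias
#>        15 0.1369  0.001033
#>        50 0.0712 -0.001078
#>       100 0.0530  0.001066
```

RRMSE falls from about 0.14 at 15 sample points to about 0.05 at 100, with
relative bias within a few tenths of a percent of zero — while the
published PCQM1 cells of the same run show RBIAS near −0.25 at every N.

There is also a thin command-line front end (`inst/cli/pcqm`) with
subcommands `generate-pattern`, `pcqm-sample`, `estimate`, `simulate`
(YAML run configs, see `?read_run_config`) and `compare`.

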