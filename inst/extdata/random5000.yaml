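# Example run configuration (config_version 1): the 5,000 stems/ha random
# population surveyed over the full sample-size grid with both estimator
# families and all three orders, 1,000 replicates per cell.
config_version: 1
output_dir: results
scenarios:
  - id: random5000
    pattern: {kind: random, n_trees: 5000, width: 100, height: 100}
    sample_sizes: [10, 15, 20, 25, 30, 50, 100]
    orders: [1, 2, 3]
    estimators: [corrected, published]
    replicates: 1000
    boundary_fraction: 0.10
    seed: 42
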