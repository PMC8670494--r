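# Default hyperparameters and tuning grids per learner family.
# These mirror the in-code defaults (see learner_spec()) and are provided so
# runs can be configured entirely from YAML. All values are overridable;
# mtry: null means sqrt(p), mtry: -1 means p/3, gamma: null means 1/p.
- family: forest
  params: {num_trees: 500, mtry: null, min_node_size: 5}
  grid: {mtry: [null, -1]}
- family: boosting
  params: {nrounds: 200, max_depth: 3, eta: 0.1, subsample: 1}
  grid: {max_depth: [3, 6]}
- family: svm
  params: {cost: 1, gamma: null, epsilon: 0.1}
  grid: {cost: [0.1, 1, 10]}
- family: knn
  params: {k: 5}
  grid: {k: [1, 3, 5, 11, 25]}
- family: nn
  params: {size: 64, decay: 0.01, maxit: 200}
  grid: {size: [64, 256]}
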