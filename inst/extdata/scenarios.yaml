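# Default study designs for the recovery experiments. Means and sds are on
# the unconstrained scale: learning rates are sigmoid-transformed, inverse
# temperatures and the Kalman observation noise exponential-transformed, the
# go/no-go bias is untransformed.
same_complexity:
  task: {kind: bandit2, n_trials: 100, walk_sd: 0.1, bounds: [0.2, 0.8]}
  groups:
    - {model: rl, n_subjects: 10, mean: [1.0986, -0.8473], sd: [0.5, 0.5]}
    - {model: kalman, n_subjects: 30, mean: [1.0986, 0.0], sd: [0.5, 0.5]}
  n_replications: 10
  methods: [hbi, nhi, hpe]
  seed: 1
nested:
  task: {kind: bandit2, n_trials: 100, walk_sd: 0.1, bounds: [0.2, 0.8]}
  groups:
    - {model: rl, n_subjects: 10, mean: [1.0986, -2.1972], sd: [0.5, 0.5]}
    - {model: dual_alpha, n_subjects: 30, mean: [1.0986, 1.3863, -0.4055], sd: [0.5, 0.5, 0.5]}
  n_replications: 10
  methods: [hbi, nhi, hpe]
  seed: 1
bias_null:
  task: {kind: gonogo, n_trials: 100, walk_sd: 0.1, bounds: [0.2, 0.8]}
  groups:
    - {model: biased_rl, n_subjects: 20, mean: [1.0986, -0.8473, 0.0], sd: [0.5, 0.5, 1.0]}
  n_replications: 10
  methods: [hbi]
  seed: 1
bias_null_skewed:
  task: {kind: gonogo, n_trials: 100, walk_sd: 0.1, bounds: [0.2, 0.8]}
  groups:
    - model: biased_rl
      n_subjects: 20
      mean: [1.0986, -0.8473, 0.0]
      sd: [0.5, 0.5, 1.0]
      skewness: [0.0, 0.0, -0.5]
      kurtosis: [3.0, 3.0, 3.0]
  n_replications: 10
  methods: [hbi]
  seed: 1
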