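mode: synthetic
sim:
  n_organisms: 100
  birth_rate: 5
  n_features: 300
  gain_rate: 1
  loss_rate: 1
  n_nutrients: 15
  p_alternative_route: 1
  n_class: 5
  n_genus: 15
  seed: 42
screen:
  uptake_limit: 10
  essentiality_cutoff: 0.05
ordination:
  axes: 2
  top_n: 200
  tsne_seed: 42
clustering:
  k: 5
regression:
  subsets: auto
  rmse_scale: log
  window_fraction: 0.05
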