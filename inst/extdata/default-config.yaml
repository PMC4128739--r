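# Default two-landscape experiment: a clumped natural reserve and an
# interspersed managed property at near-equal usable-habitat composition.
seed: 1
n_individuals:
  natural: 4
  managed: 6
fixes_per_individual: 50
n_nests: 60
min_dist_m: 50
h_m: 200
isopleth: 0.95
bootstrap_B: 10000
block_size_m: 100
abundance_weeks: 74
abundance_rates:
  natural: 1.1
  managed: 1.6
landscapes:
  natural:
    dims: [697, 697]          # 4,858 ha at 10-m cells
    cell_size_m: 10
    config: clumped
    composition:
      non-usable: 0.391
      breeding: 0.475
      roosting: 0.104
      foraging: 0.030
    patch_scale_m:
      non-usable: 2000
      roosting: 1000
      foraging: 1000
      breeding: 1000
  managed:
    dims: [454, 454]          # 2,061 ha at 10-m cells
    cell_size_m: 10
    config: interspersed
    composition:
      non-usable: 0.259
      breeding: 0.140
      roosting: 0.543
      foraging: 0.058
    patch_scale_m: 100
    cluster_parcels: 14
    road_depth_cells: 1
    road_share: 0.15
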