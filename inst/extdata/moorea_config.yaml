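# Reference pipeline configuration: Moorea north shore defaults.
# Every constant here is an assumption of the feasibility calculation and
# can be replaced for another shore.
seed: 1
habitats:
  - name: back_reef
    hard_bottom_area_km2: 4.58
    depth_range_m: [2, 5]
    shore_length_km: 16
  - name: outer_reef
    hard_bottom_area_km2: 3.15
    depth_range_m: [0, 17]
    shore_length_km: 16
sampler:
  tile_scoring_area_cm2: 225
  quadrat_area_m2: 0.25
  points_per_image: 200
  grid_cells: 25
reproduction:
  maturity_threshold_cm: 14
  polyp_density_cm2: 66
  fertilization:
    mean: 0.15
    sd: 0.21
    n_studies: 2
  allometry:
    coefficient_a: 2.493
    exponent_b: 2.312
    r_squared: 0.986
mc:
  n_draws: 20000
  truncate_negative: false
scenario:
  larval_loss_fraction: 0.999
  loss_grid: [0.9, 0.99, 0.999]
  year_matching: same
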