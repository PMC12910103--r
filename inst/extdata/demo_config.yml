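# Demonstration configuration: the standard processing constants.
# Absent keys fall back to the same defaults; unknown keys are rejected.
threshold_db: -70
surface_offset_m: 10
integration_distance_nmi: 0.1
depth_bin_m: 1
diel_altitude_deg: 18
k_range: [2, 8]
rng_seed: 7
cluster_unit: per_day
min_cells: 5
n_init: 20
jaccard_min: 0.25
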