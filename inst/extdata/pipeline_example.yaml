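# Example pipeline configuration for run_pipeline(). Unset fields keep
# their defaults (see ?pipeline_config). With `input` unset, a synthetic
# three-species decade is simulated with the given seed.
seed: 1
n_years: 10
log_offset: 0.05        # tons added before the log transform
lag_width: 2            # nm
n_sim_envelope: 1000
patch_d_along: 6        # nm
patch_d_across: 24      # nm
krige_radius_along: 12  # nm
krige_radius_across: 30 # nm
grid_resolution: 1      # nm
n_resamples: 1000
out_dir: pelagostat_out
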