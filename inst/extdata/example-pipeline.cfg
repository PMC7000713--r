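# example configuration for run_full_pipeline()
seed = 1
n_plots = 200
stems_per_plot = 2500
noise_sd = 0.2
reference_phi = 4.4
loss_rate = 4.4e-6
n_thresholds = 8
mass_ratio = 10
extinction_exponent = 2.5
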