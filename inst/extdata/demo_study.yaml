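# Demo configuration for run_study(); synthetic study, desk scale.
# All omitted knobs keep their package defaults (see ?study_config).
n_genes: 1000
n_blanks: 100
samples: [UHRR, HBRR]
replicates_per_method: {non_amp: 5, amp1: 5, amp2: 3}
panel_size: 42
n_bias_susceptible: 17
seed: 42
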