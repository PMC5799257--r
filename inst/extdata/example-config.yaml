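# Example experiment configuration for run_experiment()/exec/diagsim diagnose.
# A small Diags-II (greedy) study over several initial-observation counts.
n_signs: 20
n_diseases: 5
n_steps: 12
n_initial: [0, 2, 4, 8]
lambda_P: 1.0
lambda_C: 0.0
p_th: 0.9
n_present: 2
expected_present: 2
n_realizations: 100
seed: 1
out_dir: diagsim-study
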