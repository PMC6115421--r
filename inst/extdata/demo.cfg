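# demo pipeline configuration (reduced trial counts; seconds-scale runtime)
out_dir: runs/demo
seed: 7
n_subjects: 12
n_nodes: 24
k_planted: 3
k_min: 2
k_max: 4
k_fits: 4
stage1_trials: 5
consensus_fits: 6
subject_fits: 2
gamma_lo: 0.5
gamma_hi: 2.5
gamma_step: 0.25
eval_replicates: 10
n_perm: 30
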