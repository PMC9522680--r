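# Default end-to-end pipeline configuration.
seed: 1
n_subjects: 32
product: C
out_dir: secondair-results
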