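# Canonical synthetic-data specification: a sparse gene-by-term matrix with
# 8 pathway labels, disjoint 25-term signatures, 1-3 labels per gene.
n_instances: 200
n_labels: 8
n_terms: 500
signature_terms_per_label: 25
labels_per_instance: [1, 2, 3]
signal_strength: 5.0
background_rate: 0.05
signature_overlap: 0.0
seed: 1
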