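# Demo pipeline configuration: a small synthetic cohort run end to end.
# The annotation is a synthetic demo table over the generator's accession
# space (see demo_annotation_synthetic.tsv).
cohort:
  n_donors: 20
  n_proteins: 40
alpha: 0.05
seed: 42
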