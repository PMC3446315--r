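# Bundled demo: a small fully synthetic MeDIP-seq study run end to end.
outdir: medipnet_demo
seed: 42
simulate:
  n_chroms: 2
  chrom_length: 200000
  genes_per_chrom: 12
  library_size: 100000
quantify:
  mode: rms
dmr:
  group_by: tissue_group
  top_k: 50
inddiff:
  ind_a: ind1
  ind_b: ind2
  n_perm: 500
network:
  beta: 6
  min_module_size: 15
  max_features: 400
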