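# Seeded demo: a desk-scale synthetic screen (100 genes x 8 shRNAs, 10
# planted resistance drivers, 5 acute-essential genes) plus a matched
# RNA-seq contrast, run through depletion scoring, acute subtraction,
# NB differential expression, overlay and enrichment.
seed: 20260923
stages: [simulate, screen, de, integrate, enrich]
simulate:
  n_genes: 100
  shrnas_per_gene: 8
  barcode_length: 18
  n_drivers: 10
  n_acute: 5
  driver_s: -0.75
  acute_s: -0.75
  active_fraction: 0.8
  weeks_selected: 4
  depth: 2000000
  screen_dispersion: 0.05
  replicates: 3
  rnaseq_replicates: 4
  rnaseq_dispersion: 0.1
  driver_de_effect: 2
  n_extra_de: 20
  extra_de_effect: 1.5
thresholds:
  pseudocount: 0.5
  lfc_threshold: -1
  abundance_floor: 5
  min_candidate: 2
  min_stringent: 4
  p_max: 0.05
  min_abs_lfc: 0.58
  use_fdr: false
  enrich_p: 0.05
enrich:
  n_random_sets: 10
  set_size: 15
  n_perm: 200
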