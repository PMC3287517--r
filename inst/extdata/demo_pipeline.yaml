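seed: 101
outdir: amplitag_demo_out
sample_sheet: samples.tsv
templates: synthetic_templates.fasta
refs: synthetic_refs_16s.fasta
simulate:
  enabled: yes
  error_model:
    sub_rate: 0.004
    hp_indel_base: 0.01
    hp_scale: 1.6
    len_mean: 430.0
    len_sd: 25.0
    rev_read_frac: 0.5
  profiles:
    O_salicicola:
      n_reads: 6073
      members:
        T_NARD_SAL: 0.9083
        MINOR01: 0.04
        MINOR02: 0.03
        MINOR03: 0.0217
    O_rugosostriatus:
      n_reads: 8584
      members:
        T_RICK_RUG: 0.9087
        MINOR04: 0.0513
        T_NARD_SAL: 0.03
        MINOR05: 0.01
    O_sulcatus:
      n_reads: 6412
      members:
        T_RICK_SUL: 0.9916
        MINOR06: 0.005
        MINOR07: 0.0034
    O_armadillo:
      n_reads: 6311
      members:
        T_NARD_ARM: 0.9349
        MINOR08: 0.03
        MINOR01: 0.02
        MINOR05: 0.0151
demux:
  min_mean_q: 20.0
  max_n: 0
  primer_mismatches: 0
assemble:
  min_seed_size: 200
  window_size: 60
  anchor_len_primer: 20
  max_bases: 500000
  min_window_identity: 1.0
  min_support: 2
otu:
  identity: 0.97
  count_mode: remap
  map_identity: 0.9
classify:
  enabled: yes
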