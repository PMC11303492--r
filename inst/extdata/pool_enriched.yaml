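# Simulation profile emulating a DT-co-selection-enriched edited iPSC pool:
# overwhelmingly precise knock-in, a sliver of indels and residual
# wild-type, read out as full-amplicon reads with a 0.1% per-base
# substitution error.
amplicon_config: tie2_l914f_synthetic.yaml
alleles:
  - kind: HDR
    proportion: 0.985
  - kind: INDEL
    proportion: 0.010
    position: 6
    delta: -4
  - kind: WT
    proportion: 0.005
n_reads: 20000
error_rate: 0.001
seed: 1
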