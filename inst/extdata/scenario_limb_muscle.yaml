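# Reference limb-muscle scenario: HR efficiency ~50%, assay-detectable
# ITR junction fraction calibrated to 4% of delivered units.
name: limb_muscle
seed: 1
sim:
  u5: 8.0
  u3: 12.0
  hr_fraction: 0.5
  concat_target: 0.04
  chain_length_p: 0.5
  orientation_weights: [1.0, 1.0, 1.0]
  host_genomes: 10000
reactions:
  vcn:
    digestion: SmaI
    mode: calls
    n_droplets: 20000
  junction:
    digestion: AleI
    mode: calls
    n_droplets: 20000
  rt:
    enabled: true
    leak_rate: 0.02
    expr_rate: 2.0
    n_droplets: 20000
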