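# Dual-antigen cross-labelling demonstration scene:
# a punctate structure with a single Alexa488-like label plus a
# filamentous structure carrying a FRET antibody pair (Alexa488-like
# donor cross-labelled with an Alexa555-like acceptor).
shape: [128, 128]
pixel_size_nm: 78
background: 0.005
seed: 1
structures:
  - kind: puncta
    params: {count: 90, radius: 1.8}
    label:
      type: fluorophore
      name: tom20_a488
      emission_center_nm: 519
      emission_sigma_nm: 14
      decay: [3.84]
      excitation: [1.0, 0.02]
  - kind: filaments
    params: {count: 7, thickness: 2, curvature: 0.12}
    label:
      type: fret_pair
      name: cytokeratin_fret
      efficiency: 0.171875
      sensitized_fraction: 0.5
      donor: {preset: alexa488}
      acceptor: {preset: alexa555}
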