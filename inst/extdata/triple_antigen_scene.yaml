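# Triple-antigen demonstration: three antigens encoded by two
# fluorophores — two single labels (Alexa488-like puncta, Alexa546-like
# blobs) and one FRET cross-labelled filament structure.
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
      acceptor: {preset: alexa546}
  - kind: blobs
    params: {count: 14, ax: 3, ay: 6}
    label:
      type: fluorophore
      name: golgin_a546
      emission_center_nm: 573
      emission_sigma_nm: 16
      decay: [4.0]
      excitation: [0.10, 0.90]
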