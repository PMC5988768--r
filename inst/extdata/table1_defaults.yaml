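grade: G0
config: XZ_indented
brc_mean: 3
brc_sd: 0.5
n_samples: 10
banding_asymmetry: 0.15

grade: G1
config: XZ_indented
brc_mean: 1.7
brc_sd: 0.4
n_samples: 8
banding_asymmetry: 0.15

grade: G2
config: XZ_indented
brc_mean: 1.8
brc_sd: 0.7
n_samples: 8
banding_asymmetry: 0.15

grade: G0
config: XZ_nonindented
brc_mean: 1.1
brc_sd: 0.5
n_samples: 10
banding_asymmetry: 0

grade: G1
config: XZ_nonindented
brc_mean: 1.2
brc_sd: 0.3
n_samples: 8
banding_asymmetry: 0

grade: G2
config: XZ_nonindented
brc_mean: 1.3
brc_sd: 0.5
n_samples: 8
banding_asymmetry: 0

grade: G0
config: XY
brc_mean: 5.2
brc_sd: 1
n_samples: 10
banding_asymmetry: 0

grade: G1
config: XY
brc_mean: 4.9
brc_sd: 1
n_samples: 8
banding_asymmetry: 0

grade: G2
config: XY
brc_mean: 5.4
brc_sd: 1.5
n_samples: 8
banding_asymmetry: 0

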