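roi,pib_ad,florbetapir_ad,pib_mciplus,florbetapir_mciplus
hippocampus,1.10,1.20,1.05,1.12
thalamus,1.25,1.05,1.18,1.02
parahippocampal,1.38,1.10,1.30,1.07
caudate,1.55,1.15,1.42,0.95
occipital,1.72,0.98,1.55,1.27
insula,1.80,1.35,1.64,1.22
temporal,1.92,1.31,1.74,1.17
parietal,2.00,1.26,1.82,1.31
putamen,2.08,1.46,1.90,1.41
posterior_cingulate,2.15,1.41,1.98,1.36
frontal,2.24,1.52,2.06,1.46
anterior_cingulate,2.35,1.58,2.15,1.52
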