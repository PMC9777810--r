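# pH-stat assay constants (defaults of the milk study)
normality = 0.5
alpha = 0.2
reaction_volume_l = 0.040
h_total = 10.7
protein_mass_g = 1.24
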