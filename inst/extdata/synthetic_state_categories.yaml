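programmed_cell_death: effective
senescence: effective
cell_cycle_arrest: effective
drug_resistance: ineffective
immune_escape: ineffective
malignant_progression: ineffective
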