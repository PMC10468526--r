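# name=senmayo_liver_panel
# Senescence-associated secretory-phenotype genes reported to correlate
# with age-associated markers in old hepatocytes; a small SenMayo-style
# panel for gene-set correlation screening.
Ang
C3
Ctsb
Ets2
Igfbp1
Cebpb
Angptl4
Ctnnb1
Cxcl10
Ptbp1
Vegfa
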