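label,peg_mw,protein_mg,activity_u
crude,0,6879.45,796890
PEG-1500,1500,96.71,588673.75
PEG-3000,3000,243.97,493823.36
PEG-4500,4500,312.73,328834.03
PEG-6000,6000,152.19,506459.74
PEG-7500,7500,453.96,234979.12
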