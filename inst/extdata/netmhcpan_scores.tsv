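HLA	Peptide	Aff(nM)
HLA-A*02:01	WLMPVIPAL	34.2
HLA-A*02:01	WLTPVIPAL	612.5
HLA-A*02:01	FLACHLFVI	101.3
HLA-A*02:01	FLVCHLFVI	355.8
HLA-A*02:01	YLQGALYYL	48.9
HLA-A*02:01	YLQGAPYYL	1204.0
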