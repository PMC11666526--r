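Peptide	Score
WLMPVIPAL	21
FLACHLFVI	17
YLQGALYYL	24
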