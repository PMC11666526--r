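allele,peptide,method,score
HLA-A*02:01,WLMPVIPAL,ba,41.7
HLA-A*02:01,FLACHLFVI,ba,120.5
HLA-A*02:01,YLQGALYYL,ba,52.3
HLA-A*02:01,WLMPVIPAL,el,0.93
HLA-A*02:01,FLACHLFVI,el,0.71
HLA-A*02:01,YLQGALYYL,el,0.88
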