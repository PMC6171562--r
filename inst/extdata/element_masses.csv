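element,nominal_mass,monoisotopic_mass,heavy_abundance
C,12,12.0,0.0107
H,1,1.0078250319,0.000115
N,14,14.0030740052,0.00364
O,16,15.9949146221,0.00038
P,31,30.97376151,0
S,32,31.97207069,0.0076
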