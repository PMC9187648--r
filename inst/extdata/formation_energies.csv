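species,phase,dg0f_kj_mol,source
methanol,aq,-175.4,"Thauer, Jungermann & Decker (1977) Bacteriol Rev 41:100-180, Table 2"
H2,g,0.0,"element reference state"
CO2,g,-394.36,"Thauer, Jungermann & Decker (1977) Bacteriol Rev 41:100-180, Table 2"
CH4,g,-50.75,"Thauer, Jungermann & Decker (1977) Bacteriol Rev 41:100-180, Table 2"
H2O,l,-237.18,"Thauer, Jungermann & Decker (1977) Bacteriol Rev 41:100-180, Table 2"
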