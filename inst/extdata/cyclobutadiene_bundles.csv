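config,bundle,valence_electrons,bond_energy_kjmol
D4h,C=C,2.668,597.9
D4h,C-C,2.668,597.9
D4h,C-H,2.291,305.8
D2h,C=C,3.416,1074.9
D2h,C-C,2.027,98.3
D2h,C-H,2.237,331.4
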