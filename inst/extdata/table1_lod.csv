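metal,lod
Ti,0.098
V,0.024
Cr,0.000
Mn,0.150
Fe,0.681
Co,0.025
Ni,0.000
Cu,1.516
Zn,2.033
As,0.049
Se,0.063
Mo,1.091
Ag,0.005
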