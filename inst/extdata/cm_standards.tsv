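element	cccf_ug_per_L
SO4	250000
Cl	230000
Al	87
As	150
Co	19
Cu	9.0
Fe	1000
Ni	52
Zn	120
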