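population,Tb,To,Tm
Arak,1,22,30
Bajestan,1,22,30
Eshkazer,1,22,30
Gardmiran,1,22,30
Khaf,1,22,30
Razan,1,22,30
Semirom,1,22,30
Tafresh,1,22,30
Zabol,1,22,30
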