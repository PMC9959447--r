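source,coefficient,unit,unit_class
pesticide,4.9341,kg/kg,mass
fertilizer,0.8956,kg/kg,mass
diesel,0.5927,kg/kg,mass
film,5.18,kg/kg,mass
irrigation,266.48,kg/hm2,area
tillage,312.6,kg/hm2,area
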