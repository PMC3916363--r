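composition,glycan_class,bisecting
HexNAc2Hex6,High mannose,FALSE
HexNAc2Hex7,High mannose,FALSE
HexNAc2Hex8,High mannose,FALSE
HexNAc2Hex9,High mannose,FALSE
HexNAc3Hex5,Hybrid,FALSE
HexNAc3Hex6,Hybrid,FALSE
HexNAc4Hex4Fuc1,Complex biantennary,FALSE
HexNAc4Hex5,Complex biantennary,FALSE
HexNAc4Hex5Fuc1,Complex biantennary,FALSE
HexNAc5Hex5,Bisecting,TRUE
HexNAc5Hex5Fuc1,Bisecting,TRUE
HexNAc5Hex5Fuc2,Complex biantennary,FALSE
HexNAc5Hex6,Triantennary,FALSE
HexNAc5Hex6Fuc1,Triantennary,FALSE
HexNAc6Hex6Fuc1,Bisecting,TRUE
HexNAc6Hex7Fuc1,Tetra-antennary,FALSE
HexNAc7Hex7Fuc1,Bisecting,TRUE
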