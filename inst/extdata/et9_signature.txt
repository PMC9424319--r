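ADGRG1
FIBCD1
GDPD5
SUSD2
CACNG4
CX3CL1
IGFBP5
MAP6
CCDC69
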