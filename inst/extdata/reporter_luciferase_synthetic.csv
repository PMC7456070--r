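condition,replicate,firefly,renilla
WT,1,100,100
WT,2,110,100
WT,3,95,105
TYW2_KO,1,50,100
TYW2_KO,2,55,110
TYW2_KO,3,48,95
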