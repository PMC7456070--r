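condition,replicate,dual_intensity,single_intensity
WT,1,5,95
WT,2,6,94
WT,3,4,96
TYW2_KO,1,12,88
TYW2_KO,2,13,87
TYW2_KO,3,11,89
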