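label,class,responders,n
kern1990_total,SR,115,222
kern1990_total,MR,16,101
kern1990_total,ER,1,127
kern1990_ovarian,SR,14,24
kern1990_ovarian,MR,0,11
kern1990_ovarian,ER,0,11
kern1990_single_agent,SR,72,151
kern1990_single_agent,MR,9,79
kern1990_single_agent,ER,1,115
kern1990_combination,SR,43,71
kern1990_combination,MR,7,22
kern1990_combination,ER,0,12
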