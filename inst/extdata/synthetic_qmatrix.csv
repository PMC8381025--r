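item,C1,C2,C3
item1,1,0,0
item2,1,0,0
item3,1,0,0
item4,1,0,0
item5,1,0,0
item6,1,0,0
item7,0,1,0
item8,0,1,0
item9,0,1,0
item10,0,1,0
item11,0,1,0
item12,0,1,0
item13,0,1,0
item14,0,1,0
item15,0,0,1
item16,0,0,1
item17,0,0,1
item18,0,0,1
item19,0,0,1
item20,0,0,1
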