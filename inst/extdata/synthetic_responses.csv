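person,item1,item2,item3,item4,item5,item6,item7,item8,item9,item10,item11,item12,item13,item14,item15,item16,item17,item18,item19,item20
person1,0,1,1,0,1,1,0,0,0,0,1,0,1,0,0,0,0,0,1,1
person2,1,1,1,0,1,1,1,0,1,1,1,0,1,1,0,1,1,0,1,1
person3,1,1,0,1,0,1,1,1,1,0,1,1,1,0,0,1,0,1,1,1
person4,1,1,0,1,0,0,1,0,1,0,0,1,1,0,0,0,0,0,1,1
person5,1,1,0,0,0,0,1,0,0,0,1,1,1,0,0,0,0,0,0,1
person6,1,1,0,1,1,0,0,0,1,0,1,0,1,0,0,1,0,0,1,1
person7,1,1,1,1,1,1,1,0,1,1,1,1,1,0,0,1,0,1,1,1
person8,1,0,0,0,0,1,1,0,1,0,1,0,1,0,0,1,0,0,1,1
person9,0,0,1,1,1,1,0,0,0,0,1,0,1,0,0,1,0,0,1,1
person10,1,1,0,0,0,0,0,0,0,1,1,0,1,0,0,0,0,0,1,0
person11,1,1,1,1,1,1,1,0,1,0,1,0,1,0,0,0,0,1,1,1
person12,1,0,0,0,0,0,1,0,0,0,1,0,1,0,0,1,0,0,1,1
person13,1,1,1,1,1,1,1,0,1,0,1,1,1,0,1,1,0,0,1,1
person14,1,1,1,0,0,1,1,0,0,1,1,0,1,0,0,1,0,0,1,1
person15,1,0,0,1,0,1,1,0,0,0,0,0,1,0,0,0,0,0,1,0
person16,1,1,0,0,0,1,1,0,0,0,1,0,1,0,0,0,0,1,1,1
person17,1,1,1,1,1,1,1,0,1,0,1,1,1,0,0,1,1,1,1,1
person18,1,1,1,0,0,1,1,1,0,0,1,0,1,0,0,0,0,0,0,1
person19,1,0,1,1,0,0,1,0,0,0,1,0,1,1,0,1,0,0,1,1
person20,1,1,1,1,1,1,1,0,1,1,1,0,1,0,0,1,0,1,1,1
person21,1,0,1,0,0,0,1,0,0,0,1,0,1,0,0,1,0,0,0,0
person22,0,0,1,0,0,0,1,0,1,0,1,0,1,0,0,1,0,0,1,1
person23,1,0,1,0,0,0,0,1,0,0,1,0,0,0,0,0,0,0,1,0
person24,1,1,1,0,0,0,1,0,1,0,1,0,1,0,0,0,1,0,1,0
person25,1,0,0,1,0,1,1,0,1,0,1,1,1,0,0,1,1,0,1,1
person26,1,1,1,1,1,1,1,0,0,0,0,0,1,0,0,0,1,0,0,1
person27,1,1,1,1,1,0,1,0,0,0,1,0,1,0,0,1,0,0,1,1
person28,1,0,0,1,0,1,1,0,0,0,1,0,1,0,0,1,0,0,1,0
person29,1,1,1,1,1,1,0,0,0,0,1,0,1,0,0,0,0,0,1,1
person30,1,1,1,1,0,1,1,1,0,1,1,0,1,0,1,1,0,0,1,1
person31,1,1,1,1,0,1,1,0,0,0,1,0,1,0,0,0,0,0,1,1
person32,1,1,1,1,0,1,1,0,0,0,1,0,1,1,0,1,0,0,1,1
person33,0,1,1,0,0,0,1,0,0,0,1,0,0,0,0,1,0,0,1,1
person34,1,1,0,1,0,1,1,0,0,0,1,0,1,0,0,1,0,0,1,0
person35,1,1,0,0,0,1,1,1,1,1,1,0,1,0,1,1,0,0,1,1
person36,1,1,1,1,1,1,1,0,0,0,1,0,1,0,0,0,0,0,1,1
person37,0,1,1,1,0,0,1,0,1,0,1,0,1,0,0,1,0,1,1,1
person38,1,1,0,0,0,1,1,0,0,0,1,0,1,1,0,0,0,0,0,1
person39,1,0,1,0,0,1,1,0,0,0,1,0,1,0,1,1,1,0,1,1
person40,1,0,0,1,0,1,1,0,1,1,1,0,1,0,0,0,1,0,1,1
person41,1,1,1,1,0,1,1,1,0,0,1,0,1,0,0,1,0,0,1,1
person42,1,1,1,1,1,1,1,1,1,1,1,0,1,1,0,0,0,0,1,1
person43,1,1,1,1,1,1,1,0,0,0,1,0,1,0,0,0,0,0,1,1
person44,1,1,1,1,0,0,1,0,1,0,1,0,1,1,0,0,0,0,1,1
person45,0,1,1,0,1,1,1,0,0,0,1,0,1,0,0,1,0,0,1,0
person46,1,1,1,1,1,1,1,0,0,1,1,0,1,0,1,1,0,0,1,1
person47,1,1,1,1,0,1,1,0,1,0,1,0,1,0,1,1,1,0,1,1
person48,1,0,1,1,0,1,1,0,0,0,1,0,1,0,0,1,0,0,1,1
person49,1,0,0,0,0,0,1,0,0,0,1,0,1,0,0,1,0,0,1,1
person50,1,1,1,1,0,1,1,0,1,0,1,0,1,0,0,1,0,0,1,0
person51,1,0,0,0,0,0,1,1,0,0,1,0,1,0,0,0,0,0,1,1
person52,1,1,1,1,0,0,1,0,1,1,1,0,1,0,0,1,0,0,1,1
person53,1,1,0,0,0,0,1,0,1,0,1,0,1,0,0,0,0,0,0,1
person54,1,1,1,1,1,1,1,1,1,0,1,0,1,0,0,1,1,0,1,1
person55,1,1,1,1,0,1,1,0,1,0,1,0,1,0,0,0,0,0,1,0
person56,1,1,1,0,1,1,1,0,1,0,1,0,1,0,0,1,1,0,1,1
person57,1,0,1,1,1,1,1,0,1,0,1,0,1,1,0,0,0,0,1,1
person58,1,1,1,0,0,1,1,0,1,0,1,0,1,0,0,1,0,0,1,1
person59,1,1,1,0,0,1,1,0,0,0,0,0,0,0,0,1,0,0,1,1
person60,1,1,1,1,1,1,1,0,1,0,1,0,0,0,0,1,0,0,1,1
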