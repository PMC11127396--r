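id,km,sc,hc
obs01,a1,A,u
obs02,a1,A,u
obs03,a2,A,u
obs04,a2,A,u
obs05,b1,B,v1
obs06,b1,B,v1
obs07,b1,B,v2
obs08,b1,B,v2
obs09,c1,C,w
obs10,c1,C,w
obs11,c2,C,w
obs12,c2,C,w
obs13,d1,D,x1
obs14,d1,D,x2
obs15,d1,D,x2
obs16,-1,D,x2
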