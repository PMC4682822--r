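pre,post,type,count
HS1,HI1,chem,3
HI1,HM1,chem,2
HM1,HS1,chem,1
TS1,TI1,chem,2
TI1,CM1,chem,1
HI1,TI1,chem,1
HS1,HM1,gap,2
HI1,CM1,gap,1
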