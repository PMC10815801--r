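aptamer,class,positive,total,intensity
AptaB1,adjacent,1,10,1
AptaB1,primary_tumor,7,50,3
AptaB1,metastatic,5,40,3
AptaB2,adjacent,1,10,1
AptaB2,primary_tumor,18,50,3
AptaB2,metastatic,5,40,2
AptaB3,adjacent,1,10,1
AptaB3,primary_tumor,3,50,3
AptaB3,metastatic,6,40,2
AptaB4,adjacent,4,10,1
AptaB4,primary_tumor,25,50,3
AptaB4,metastatic,15,40,3
AptaB5,adjacent,3,10,1
AptaB5,primary_tumor,20,50,3
AptaB5,metastatic,27,40,3
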