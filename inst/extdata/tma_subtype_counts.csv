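aptamer,subtype,positive,total
AptaB1,luminal,3,28
AptaB1,HER2,3,7
AptaB1,triple_negative,1,10
AptaB2,luminal,8,28
AptaB2,HER2,5,7
AptaB2,triple_negative,4,10
AptaB3,luminal,1,28
AptaB3,HER2,1,7
AptaB3,triple_negative,1,10
AptaB4,luminal,12,28
AptaB4,HER2,6,7
AptaB4,triple_negative,4,10
AptaB5,luminal,9,28
AptaB5,HER2,5,7
AptaB5,triple_negative,5,10
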