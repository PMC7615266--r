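sex,age_lo,age_hi,annual_rate
male,35,40,0.0025
male,40,45,0.0033
male,45,50,0.0046
male,50,55,0.0066
male,55,60,0.0095
male,60,65,0.0138
male,65,70,0.0196
male,70,75,0.0282
female,35,40,0.0014
female,40,45,0.0019
female,45,50,0.0027
female,50,55,0.0039
female,55,60,0.0057
female,60,65,0.0084
female,65,70,0.0123
female,70,75,0.0182
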