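country,category,mean,variance
NL,degree,25.65,2212.2
NL,locations,21.4,2057.6
NL,travel,4.2,80.8
NL,eating,7.3,106.5
NL,household,3.0,10.1
TH,degree,58.51,8601.9
TH,locations,40.9,4671.4
TH,travel,17.6,1346.9
TH,eating,11.8,225.0
TH,household,4.0,8.6
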