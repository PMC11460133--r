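currency,year,index
NZD,2019,100
AUD,2019,100
AUD,2020,106.276306114220
GBP,2019,100
EUR,2019,100
EUR,2021,102.427007953457
USD,2011,100
USD,2019,109.175259259259
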